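# Building blocks, the two networks, and the graph engine.

test_that("conv blocks preserve or halve spatial size as declared", {
  b <- build_block_model(make_conv_block(3, 32, stride = 1))
  m <- ret_instantiate(b, seed = 1)
  out <- ret_forward(m, rand_image_batch(64, 64))$out$out
  expect_equal(dim(out), c(64L, 64L, 32L, 1L))
  b2 <- build_block_model(make_conv_block(32, 64, stride = 2))
  m2 <- ret_instantiate(b2, seed = 1)
  set.seed(2)
  x <- array(runif(64 * 64 * 32), c(64, 64, 32, 1))
  expect_equal(dim(ret_forward(m2, x)$out$out), c(32L, 32L, 64L, 1L))
  expect_error(make_conv_block(3, 32, stride = 3), "stride")
})

test_that("bottleneck_csp honours its shape contract and residual
          identity", {
  for (r in c(1L, 3L)) {
    b <- build_block_model(make_bottleneck_csp(6, 10, repeats = r))
    m <- ret_instantiate(b, seed = r)
    set.seed(r)
    x <- array(runif(16 * 16 * 6), c(16, 16, 6, 1))
    expect_equal(dim(ret_forward(m, x)$out$out), c(16L, 16L, 10L, 1L))
  }
  expect_error(make_bottleneck_csp(8, 9), "even")
  # zeroing the bottleneck 3x3 convs makes path A collapse onto its 1x1
  # projection (the additive skip passes it through unchanged)
  b <- build_block_model(make_bottleneck_csp(4, 8, repeats = 2))
  m <- ret_instantiate(b, seed = 3)
  for (j in 1:2) {
    id <- paste0("blk.b", j, ".cv2.conv")
    p <- m$params[[id]]
    p$W[] <- 0
    m$params[[id]] <- p
  }
  set.seed(4)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  fw <- ret_forward(m, x)
  expect_equal(fw$acts[["blk.b2.add"]], fw$acts[["blk.cv1.act"]],
               tolerance = 1e-12)
})

test_that("bottleneck_csp parameter count matches a layer-by-layer hand
          count (in = out = 64, repeats = 1)", {
  # cv1 1x1 conv+BN: 64*32 + 2*32;  bottleneck 1x1 + 3x3 (+BN each);
  # shortcut 1x1 (no BN); concat BN on 64 ch; cv3 1x1 conv+BN.
  hand <- (64 * 32 + 64) +
    (32 * 32 + 64) + (9 * 32 * 32 + 64) +
    (64 * 32) +
    (2 * 64) +
    (64 * 64 + 128)
  spec <- build_block_model(make_bottleneck_csp(64, 64, repeats = 1))
  expect_identical(count_params(spec)$params, hand)
  expect_identical(ret_num_params(ret_instantiate(spec, 1)), hand)
})

test_that("ASPP preserves spatial size for all rates and exposes the
          declared receptive field", {
  b <- build_block_model(make_aspp(6, 8))
  m <- ret_instantiate(b, seed = 1)
  set.seed(5)
  x <- array(runif(40 * 40 * 6), c(40, 40, 6, 1))
  expect_equal(dim(ret_forward(m, x)$out$out), c(40L, 40L, 8L, 1L))
  # rate-18 branch: 3x3 kernel at dilation 18 spans 2*18+1 = 37 pixels
  n18 <- b$graph[["blk.r3_18.conv"]]
  expect_equal(n18$dil * (n18$k - 1) + 1, 37)
  # degenerate rates (1,1,1) are ordinary 3x3 convs
  b1 <- build_block_model(make_aspp(4, 4, rates = c(1, 1, 1)))
  dil <- vapply(b1$graph, function(n) {
    if (!is.na(n$dil)) n$dil else NA_integer_
  }, integer(1))
  expect_true(all(dil[!is.na(dil)] == 1L))
  expect_error(make_aspp(4, 4, rates = c(0, 6)), "positive")
})

test_that("upsample block doubles resolution; bilinear is exact on
          constants", {
  b <- build_block_model(make_upsample_block(6, 4))
  m <- ret_instantiate(b, seed = 1)
  set.seed(6)
  x <- array(runif(16 * 16 * 6), c(16, 16, 6, 1))
  expect_equal(dim(ret_forward(m, x)$out$out), c(32L, 32L, 4L, 1L))
  # the resampling op alone maps a constant field to the same constant
  cx <- array(0.37, c(8, 8, 2, 1))
  up <- retinet:::op_bilinear_resize_forward(cx, 16L, 16L)$out
  expect_equal(up, array(0.37, c(16, 16, 2, 1)), tolerance = 1e-12)
  # chaining two upsample blocks quadruples resolution
  expect_equal(dim(retinet:::op_bilinear_resize_forward(up, 32L, 32L)$out),
               c(32L, 32L, 2L, 1L))
})

test_that("CSP_UNet maps H x W input to an H x W probability map", {
  spec <- build_csp_unet(hyper = ret_tiny_hyper())
  m <- ret_instantiate(spec, seed = 2)
  for (s in c(64L, 96L)) {
    out <- ret_forward(m, rand_image_batch(s, s, seed = s))$out$seg
    expect_equal(dim(out), c(s, s, 1L, 1L))
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(ret_forward(m, rand_image_batch(100, 100)), "divisible")
})

test_that("MTNet yields a segmentation map and a 5-grade probability
          vector from one input", {
  m <- tiny_mtnet()
  fw <- ret_forward(m, rand_image_batch(64, 64, seed = 9),
                    outputs = c("seg", "grade"))
  expect_equal(dim(fw$out$seg), c(64L, 64L, 1L, 1L))
  expect_equal(dim(fw$out$grade), c(5L, 1L))
  expect_equal(sum(fw$out$grade), 1, tolerance = 1e-6)
  expect_true(all(fw$out$grade >= 0))
  gp <- grade_prediction(fw$out$grade[, 1])
  expect_true(gp$grade %in% 0:4)
})

test_that("forward on an all-zeros image is finite at random init", {
  m <- tiny_mtnet(seed = 31)
  x <- array(0, c(64, 64, 3, 1))
  fw <- ret_forward(m, x, outputs = c("seg", "grade"))
  expect_true(all(is.finite(fw$out$seg)))
  expect_true(all(is.finite(fw$out$grade)))
})

test_that("parameter groups are disjoint and additive; the encoder is
          shared by both branches", {
  spec <- build_mtnet(hyper = ret_tiny_hyper())
  total <- count_params(spec)$params
  parts <- vapply(c("shared", "branch1", "branch2"), function(g) {
    count_params(spec, groups = g)$params
  }, numeric(1))
  expect_identical(sum(parts), total)
  m <- ret_instantiate(spec, seed = 1)
  expect_identical(ret_num_params(m), total)
  expect_identical(sum(vapply(c("shared", "branch1", "branch2"),
                              function(g) ret_num_params(m, g),
                              numeric(1))), total)
  # every shared parameter node lies on both branches' active sub-graphs
  act_seg <- retinet:::active_node_ids(spec$graph, spec$outputs$seg)
  act_grd <- retinet:::active_node_ids(spec$graph, spec$outputs$grade)
  shared_ids <- names(spec$graph)[vapply(spec$graph, function(n) {
    n$group == "shared" && n$op %in% c("conv", "bn", "fc")
  }, logical(1))]
  expect_true(all(shared_ids %in% act_seg))
  expect_true(all(shared_ids %in% act_grd))
})

test_that("model specs round-trip through JSON (and YAML when available)", {
  spec <- build_mtnet(hyper = ret_tiny_hyper())
  tmp <- tempfile(fileext = ".json")
  ret_spec_write(spec, tmp)
  back <- ret_spec_read(tmp)
  expect_identical(back$name, spec$name)
  expect_identical(back$hyper, spec$hyper)
  expect_identical(count_params(back)$params, count_params(spec)$params)
  if (requireNamespace("yaml", quietly = TRUE)) {
    ty <- tempfile(fileext = ".yaml")
    ret_spec_write(spec, ty)
    expect_identical(ret_spec_read(ty)$hyper, spec$hyper)
  }
})

test_that("backpropagation matches finite differences through the whole
          graph", {
  m <- tiny_mtnet(seed = 13)
  set.seed(14)
  H <- 16L
  x <- array(runif(H * H * 3), c(H, H, 3, 1))
  y <- array((runif(H * H) > 0.7) * 1, c(H, H, 1, 1))
  label <- 2L
  loss_fn <- function(m) {
    fw <- ret_forward(m, x, outputs = c("seg", "grade_logits"),
                      training = TRUE)
    p <- fw$out$seg
    sm <- retinet:::op_softmax_forward(fw$out$grade_logits)$out
    list(loss = -log(sm[label + 1, 1]) + seg_ce(p, y) +
           dice_loss(p[, , 1, 1], y[, , 1, 1]),
         fw = fw, p = p, sm = sm)
  }
  r <- loss_fn(m)
  onehot <- matrix(0, 5, 1); onehot[label + 1, 1] <- 1
  g_sig <- array(dice_loss_grad(r$p[, , 1, 1], y[, , 1, 1]), dim(r$p))
  pg <- ret_backward(m, r$fw, list(
    grade_logits = r$sm - onehot,
    seg_logits = (r$p - y) / length(r$p),
    seg = g_sig))
  ids <- c("stem.conv2.conv", "enc1.csp.cv1.bn", "enc3.csp.cv2",
           "dec2.aspp.r2_12.conv", "dec4.up.cv.conv", "seg.conv",
           "head.conv1.conv", "head.fc")
  eps <- 1e-6
  grad_key <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  for (id in ids) {
    p0 <- m$params[[id]]
    for (f in intersect(names(p0), c("W", "gamma", "beta"))) {
      g_an_all <- pg[[id]][[grad_key[[f]]]]
      set.seed(nchar(id))
      for (k in sample(length(p0[[f]]), 2)) {
        pp <- p0; pp[[f]][k] <- pp[[f]][k] + eps
        m$params[[id]] <- pp
        lp <- loss_fn(m)$loss
        pp[[f]][k] <- pp[[f]][k] - 2 * eps
        m$params[[id]] <- pp
        lm <- loss_fn(m)$loss
        m$params[[id]] <- p0
        fd <- (lp - lm) / (2 * eps)
        an <- g_an_all[k]
        expect_equal(an, fd, tolerance = 1e-4,
                     label = paste("grad", id, f, k))
      }
    }
  }
})
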