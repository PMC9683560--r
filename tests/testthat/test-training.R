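# Optimiser schedule, checkpoint selection, and the staged protocol
# semantics (on small 64x64 synthetic data so each stage runs in seconds).

test_that("cosine schedule hits its stated endpoints and midpoint", {
  cfg <- train_config()
  expect_equal(cosine_lr(0, cfg), 1e-3)
  expect_equal(cosine_lr(1, cfg), 2e-7)
  expect_equal(cosine_lr(0.5, cfg), 2e-7 + 0.5 * (1e-3 - 2e-7),
               tolerance = 1e-12)
  expect_equal(cosine_lr(0.5, cfg), 5.001e-4, tolerance = 1e-7)
  expect_error(cosine_lr(-0.1, cfg), "\\[0, 1\\]")
  expect_error(cosine_lr(1.1, cfg), "\\[0, 1\\]")
  # epoch stepping: first epoch at lr_max, last at lr_min
  cfg60 <- train_config(epochs = 60)
  expect_equal(retinet:::epoch_lr(1, cfg60), 1e-3)
  expect_equal(retinet:::epoch_lr(60, cfg60), 2e-7)
  expect_equal(retinet:::epoch_lr(10, train_config(schedule = "constant")),
               1e-3)
})

test_that("best-checkpoint selection takes the minimum, earliest on
          ties", {
  hist <- lapply(seq_along(c(3, 2, 2, 4)), function(i) {
    list(epoch = i, loss = c(3, 2, 2, 4)[i], weights = list(id = i))
  })
  best <- select_best(hist)
  expect_equal(best$epoch, 2)
  # monotone decreasing -> last epoch
  hist2 <- lapply(1:4, function(i) list(epoch = i, loss = 5 - i,
                                        weights = NULL))
  expect_equal(select_best(hist2)$epoch, 4)
  expect_equal(select_best(hist2[1])$epoch, 1)
})

test_that("stage 1 learns, leaves branch II untouched, and is
          deterministic under a fixed seed", {
  dr <- tiny_dr_data()
  cfg <- train_config(epochs = 1, seed = 9, schedule = "constant",
                      monitor = "train")
  m <- tiny_mtnet(seed = 9)
  before_b2 <- retinet:::snapshot_weights(m)
  x0 <- retinet:::stack_images(dr$images, seq_along(dr$images))
  loss0 <- retinet:::dr_step(m, x0, dr$grades, fw_train = FALSE)$loss
  ck <- train_stage1(m, dr, cfg)
  loss1 <- retinet:::dr_step(m, x0, dr$grades, fw_train = FALSE)$loss
  expect_lt(loss1, loss0)   # one epoch reduces the training loss
  # branch2-exclusive parameters have no gradient path in stage 1
  b2_ids <- names(m$spec$graph)[vapply(m$spec$graph, function(n) {
    n$group == "branch2" && n$op %in% c("conv", "bn", "fc")
  }, logical(1))]
  for (id in b2_ids) {
    expect_identical(m$params[[id]]$W, before_b2[[id]]$W)
    expect_identical(m$params[[id]]$gamma, before_b2[[id]]$gamma)
  }
  # determinism: identical run -> bitwise identical history and weights
  m2 <- tiny_mtnet(seed = 9)
  ck2 <- train_stage1(m2, dr, cfg)
  expect_identical(ck$history, ck2$history)
  expect_identical(retinet:::snapshot_weights(m),
                   retinet:::snapshot_weights(m2))
})

test_that("stage 2 mirrors stage 1 for the segmentation branch", {
  vessel <- tiny_vessel_data()
  cfg <- train_config(epochs = 1, seed = 10, schedule = "constant",
                      monitor = "train")
  m <- tiny_mtnet(seed = 10)
  before <- retinet:::snapshot_weights(m)
  x0 <- retinet:::stack_images(vessel$images, seq_along(vessel$images))
  y0 <- retinet:::stack_masks(vessel$masks, seq_along(vessel$images))
  loss0 <- retinet:::seg_step(m, x0, y0, 1, fw_train = FALSE)$loss
  train_stage2(m, vessel, cfg)
  loss1 <- retinet:::seg_step(m, x0, y0, 1, fw_train = FALSE)$loss
  expect_lt(loss1, loss0)
  b1_ids <- names(m$spec$graph)[vapply(m$spec$graph, function(n) {
    n$group == "branch1" && n$op %in% c("conv", "bn", "fc")
  }, logical(1))]
  for (id in b1_ids) {
    expect_identical(m$params[[id]]$W, before[[id]]$W)
  }
  # shared encoder does update in stage 2
  expect_false(identical(m$params[["stem.conv1.conv"]]$W,
                         before[["stem.conv1.conv"]]$W))
})

test_that("stage 3 logs total = dr_ce + vessel at every step and
          alternates deterministically", {
  dr <- tiny_dr_data()
  vessel <- tiny_vessel_data()
  log1 <- tempfile(fileext = ".jsonl")
  cfg <- train_config(epochs = 2, seed = 11, schedule = "constant",
                      monitor = "train", log_path = log1)
  m <- tiny_mtnet(seed = 11)
  train_stage3_joint(m, dr, vessel, cfg)
  recs <- lapply(readLines(log1), jsonlite::fromJSON)
  expect_gt(length(recs), 0)
  for (r in recs) {
    expect_equal(r$total, r$dr_ce + r$vessel, tolerance = 1e-9)
  }
  # deterministic alternation: rerun gives the identical log
  log2 <- tempfile(fileext = ".jsonl")
  cfg2 <- cfg; cfg2$log_path <- log2
  m2 <- tiny_mtnet(seed = 11)
  train_stage3_joint(m2, dr, vessel, cfg2)
  expect_identical(readLines(log1), readLines(log2))
  empty <- structure(list(images = list(), masks = list(), grades = NULL),
                     class = "ret_dataset")
  expect_error(train_stage3_joint(m, dr, empty, cfg), "empty")
})

test_that("a zero-weight vessel loss leaves branch II unchanged in a
          joint step", {
  dr <- tiny_dr_data()
  vessel <- tiny_vessel_data()
  m <- tiny_mtnet(seed = 12)
  before <- retinet:::snapshot_weights(m)
  cfg <- train_config(epochs = 1, seed = 12, schedule = "constant",
                      monitor = "train",
                      loss_weights = vessel_loss_config(1, 1e-12))
  train_stage3_joint(m, dr, vessel, cfg)
  # with lambda ~ 0 the branch2-exclusive updates vanish to first order;
  # compare against a lambda = 1 run from the same init
  m1 <- tiny_mtnet(seed = 12)
  cfg1 <- train_config(epochs = 1, seed = 12, schedule = "constant",
                       monitor = "train")
  train_stage3_joint(m1, dr, vessel, cfg1)
  id <- "dec4.up.cv.conv"
  delta0 <- max(abs(m$params[[id]]$W - before[[id]]$W))
  delta1 <- max(abs(m1$params[[id]]$W - before[[id]]$W))
  expect_lt(delta0, delta1 * 1e-2)
})

test_that("fine-tuning freezes the shared encoder bitwise and merges a
          loadable checkpoint", {
  dr <- tiny_dr_data()
  vessel <- tiny_vessel_data()
  m <- tiny_mtnet(seed = 13)
  cfg <- train_config(epochs = 1, seed = 13, schedule = "constant",
                      monitor = "train")
  ck3 <- train_stage3_joint(m, dr, vessel, cfg)
  ck4 <- finetune_and_merge(ck3, dr, vessel, cfg)
  # shared trainable weights bitwise equal to the stage-3 checkpoint's
  for (id in names(ck4$weights)) {
    if (ck4$groups[[id]] == "shared") {
      expect_identical(ck4$weights[[id]]$W, ck3$weights[[id]]$W)
      expect_identical(ck4$weights[[id]]$gamma, ck3$weights[[id]]$gamma)
      expect_identical(ck4$weights[[id]]$beta, ck3$weights[[id]]$beta)
    }
  }
  # the merged checkpoint covers all three groups and runs forward
  expect_setequal(unique(unname(ck4$groups)),
                  c("shared", "branch1", "branch2"))
  m4 <- ret_load_checkpoint(ck4)
  fw <- ret_forward(m4, rand_image_batch(64, 64, seed = 1),
                    outputs = c("seg", "grade"))
  expect_true(all(is.finite(fw$out$seg)))
  # a checkpoint stripped of a group refuses to load
  ck_broken <- ck4
  drop <- names(ck_broken$groups)[ck_broken$groups == "branch1"]
  ck_broken$weights[drop] <- NULL
  ck_broken$groups <- ck_broken$groups[setdiff(names(ck_broken$groups),
                                               drop)]
  expect_error(ret_load_checkpoint(ck_broken), "missing parameter group")
})

test_that("fine-tuning a small set does not worsen the branch losses", {
  # overfit regime: 4 images per task, constant LR
  vessel <- memo("vessel64s", function() {
    generate_dataset(synth_config(size = 64L, n_images = 4L, seed = 301L),
                     "vessel")
  })
  dr <- memo("dr64s", function() {
    generate_dataset(synth_config(size = 64L, n_images = 4L, seed = 302L),
                     "dr")
  })
  m <- tiny_mtnet(seed = 14)
  cfg <- train_config(epochs = 3, seed = 14, schedule = "constant",
                      monitor = "train")
  ck3 <- train_stage3_joint(m, dr, vessel, cfg)
  m3 <- ret_load_checkpoint(ck3)
  xd <- retinet:::stack_images(dr$images, 1:4)
  xv <- retinet:::stack_images(vessel$images, 1:4)
  yv <- retinet:::stack_masks(vessel$masks, 1:4)
  dr0 <- retinet:::dr_step(m3, xd, dr$grades, fw_train = FALSE)$loss
  sg0 <- retinet:::seg_step(m3, xv, yv, 1, fw_train = FALSE)$loss
  cfg_ft <- train_config(epochs = 10, seed = 14, schedule = "constant",
                         monitor = "train")
  ck4 <- finetune_and_merge(ck3, dr, vessel, cfg_ft)
  m4 <- ret_load_checkpoint(ck4)
  dr1 <- retinet:::dr_step(m4, xd, dr$grades, fw_train = FALSE)$loss
  sg1 <- retinet:::seg_step(m4, xv, yv, 1, fw_train = FALSE)$loss
  expect_lte(dr1, dr0 + 1e-6)
  expect_lte(sg1, sg0 + 1e-6)
})

test_that("checkpoint parameter groups are disjoint and cover all
          trainable parameters", {
  m <- tiny_mtnet(seed = 15)
  cfg <- train_config(epochs = 1, seed = 15, schedule = "constant",
                      monitor = "train")
  ck <- train_stage1(m, tiny_dr_data(), cfg)
  per_group <- split(names(ck$groups), unname(ck$groups))
  expect_equal(sum(lengths(per_group)), length(ck$weights))
  counted <- sum(vapply(names(ck$weights), function(id) {
    sum(vapply(retinet:::param_arrays(ck$weights[[id]]), length,
               numeric(1)))
  }, numeric(1)))
  expect_identical(counted, count_params(m$spec)$params)
})
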