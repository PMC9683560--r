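# Confusion-count metrics and the binarization rule.

test_that("binarize applies the >= threshold rule, ties to vessel", {
  expect_equal(binarize(matrix(0.5, 3, 3), 0.5), matrix(1L, 3, 3))
  p <- matrix(c(0.9, 0.49, 0.1, 0.51), 2, 2)
  expect_equal(binarize(p), matrix(c(1L, 0L, 0L, 1L), 2, 2))
  # idempotent on masks for any threshold
  m <- matrix(c(0, 1, 1, 0, 1, 0), 2, 3)
  for (thr in c(0.1, 0.5, 0.9)) {
    expect_equal(binarize(m, thr), matrix(as.integer(m), 2, 3))
  }
  expect_error(binarize(matrix(NaN, 2, 2)), "non-finite")
  expect_error(binarize(matrix(0.5, 2, 2), threshold = 0), "threshold")
  expect_error(binarize(matrix(0.5, 2, 2), threshold = 1), "threshold")
})

test_that("confusion tallies the four cells and checks shapes", {
  pred <- matrix(c(1L, 0L, 1L, 0L), 2, 2)   # column-major
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  co <- confusion(pred, truth)
  expect_equal(co[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  # identity prediction
  set.seed(1)
  t2 <- matrix(rbinom(64, 1, 0.3), 8, 8)
  co2 <- confusion(t2, t2)
  expect_equal(co2$tp, sum(t2))
  expect_equal(co2$tn, 64 - sum(t2))
  expect_equal(co2$fp + co2$fn, 0L)
  # all-ones vs all-zeros
  co3 <- confusion(matrix(1L, 3, 3), matrix(0L, 3, 3))
  expect_equal(co3[c("tp", "fp", "tn", "fn")],
               list(tp = 0L, fp = 9L, tn = 0L, fn = 0L))
  err <- expect_error(confusion(matrix(0L, 2, 3), matrix(0L, 3, 2)))
  expect_match(conditionMessage(err), "2x3")
  expect_match(conditionMessage(err), "3x2")
})

test_that("swapping pred and truth swaps fp and fn, fixes tp and tn", {
  set.seed(7)
  for (i in 1:10) {
    a <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10, 10)
    b <- matrix(rbinom(100, 1, runif(1, 0.1, 0.9)), 10, 10)
    ab <- confusion(a, b)
    ba <- confusion(b, a)
    expect_identical(ab$tp, ba$tp)
    expect_identical(ab$tn, ba$tn)
    expect_identical(ab$fp, ba$fn)
    expect_identical(ab$fn, ba$fp)
  }
})

test_that("segmentation metrics follow the count formulas", {
  m <- segmentation_metrics(cc(1L, 1L, 1L, 1L))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$iou, 1 / 3)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  # perfect prediction
  mp <- segmentation_metrics(cc(10L, 0L, 90L, 0L))
  expect_equal(unlist(mp[c("accuracy", "iou", "precision", "recall",
                           "f1")]),
               c(accuracy = 1, iou = 1, precision = 1, recall = 1, f1 = 1))
  # degenerate 0/0 -> 0 with a warning, not NaN
  expect_warning(md <- segmentation_metrics(cc(0L, 0L, 25L, 0L)), "0/0")
  expect_equal(md$iou, 0)
  expect_equal(md$f1, 0)
  expect_true(all(c("iou", "precision", "recall") %in% md$degenerate))
  expect_error(segmentation_metrics(cc(0L, 0L, 0L, 0L)), "empty")
})

test_that("F1 equals 2*IoU/(1+IoU) on pooled counts, incl. the printed
          0.6674/0.8006 pair", {
  # counts engineered to print IoU 0.6674 at 4 d.p.
  co <- cc(66744L, 16628L, 400000L, 16628L)
  m <- segmentation_metrics(co)
  expect_equal(round(m$iou, 4), 0.6674)
  expect_equal(round(m$f1, 4), 0.8006)
  expect_equal(m$f1, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
  # property over random counts
  set.seed(42)
  for (i in 1:50) {
    co <- cc(sample(0:1000, 1), sample(0:1000, 1), sample(0:1000, 1),
             sample(0:1000, 1))
    if (co$tp + co$fp + co$fn == 0) next
    m <- suppressWarnings(segmentation_metrics(co))
    if (co$tp > 0) {
      expect_equal(m$f1, 2 * m$iou / (1 + m$iou), tolerance = 1e-9)
    }
    vals <- unlist(m[c("accuracy", "iou", "precision", "recall", "f1")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_gte(m$accuracy, m$iou)
  }
})

test_that("pooled dataset metrics equal metrics of summed counts", {
  set.seed(9)
  preds <- lapply(1:6, function(i) matrix(rbinom(144, 1, 0.3), 12, 12))
  truths <- lapply(1:6, function(i) matrix(rbinom(144, 1, 0.35), 12, 12))
  pooled <- evaluate_segmentation(preds, truths, average = "pooled")
  summed <- segmentation_metrics(confusion_pool(
    lapply(1:6, function(i) confusion(preds[[i]], truths[[i]]))))
  expect_equal(pooled[c("accuracy", "iou", "precision", "recall", "f1")],
               summed[c("accuracy", "iou", "precision", "recall", "f1")])
  # per-image averaging differs in general but stays in [0,1]
  peri <- evaluate_segmentation(preds, truths, average = "per_image")
  expect_true(all(unlist(peri[c("accuracy", "iou", "f1")]) >= 0))
})

test_that("fov mask restricts the counted pixels", {
  pred <- matrix(1L, 4, 4)
  truth <- matrix(0L, 4, 4)
  fov <- matrix(0L, 4, 4); fov[1:2, 1:2] <- 1L
  co <- confusion(pred, truth, fov = fov)
  expect_equal(co$fp, 4L)
  expect_equal(co$tp + co$fp + co$tn + co$fn, 4L)
})

test_that("grading accuracy is the exact-match fraction on grades 0..4", {
  expect_equal(grading_accuracy(c(0L, 1L, 2L, 3L, 4L),
                                c(0L, 1L, 2L, 3L, 4L)), 1)
  expect_equal(grading_accuracy(c(0L, 1L, 2L, 3L, 4L),
                                c(0L, 1L, 2L, 3L, 0L)), 0.8)
  expect_equal(grading_accuracy(c(1L, 1L), c(2L, 3L)), 0)
  expect_error(grading_accuracy(c(0L, 5L), c(0L, 1L)), "0..4")
  expect_error(grading_accuracy(integer(0), integer(0)), "length")
})

test_that("metric reports serialise to the fixed CSV order and JSON", {
  m <- segmentation_metrics(cc(6L, 2L, 10L, 2L))
  line <- metrics_csv_line(m)
  vals <- as.numeric(strsplit(line, ",")[[1]])
  expect_equal(vals, c(m$accuracy, m$iou, m$precision, m$recall, m$f1),
               tolerance = 1e-6)
  j <- jsonlite::fromJSON(metrics_json(m))
  expect_equal(j$iou, m$iou)
  tmp <- tempfile(fileext = ".csv")
  metrics_csv_line(m, tmp)
  expect_equal(readLines(tmp)[1], "accuracy,iou,precision,recall,f1")
})
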