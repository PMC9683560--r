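# Segmentation and grading evaluation.
#
# All segmentation metrics are confusion-count based:
#   Accuracy  = (TP + TN) / (TP + FN + TN + FP)
#   IoU       = TP / (TP + FP + FN)          (|R intersect R'| / |R union R'|)
#   Precision = TP / (TP + FP)
#   Recall    = TP / (TP + FN)
#   F1        = 2 * Precision * Recall / (Precision + Recall)
# For counts pooled into a single table, F1 == 2*IoU/(1+IoU) algebraically;
# the implementation preserves that identity to floating-point accuracy.
# Dataset-level metrics pool pixel counts over all images by default
# (per-image averaging is available but breaks the identity).

#' Binarize a probability map
#'
#' @param p Numeric matrix (or array) of probabilities in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1)`; a probability exactly
#'   equal to the threshold maps to vessel (the `>=` convention).
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (!is.numeric(p)) stop("probability map must be numeric")
  if (any(!is.finite(p))) stop("probability map contains non-finite values")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1), got ", threshold)
  }
  m <- p >= threshold
  storage.mode(m) <- "integer"
  m
}

assert_binary_mask <- function(m, what = "mask") {
  if (!all(m %in% c(0L, 1L))) stop(what, " must contain only 0/1 values")
  invisible(m)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth 0/1 matrices of identical shape (prediction and
#'   reference).
#' @param fov Optional 0/1 field-of-view mask; when given, only pixels with
#'   `fov == 1` are counted.  Default: all pixels count.
#' @return A `ret_confusion` list with integer fields `tp`, `fp`, `tn`,
#'   `fn` summing to the number of counted pixels.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  if (!identical(dim(pred), dim(truth))) {
    stop("shape mismatch: pred is ", paste(dim(pred), collapse = "x"),
         ", truth is ", paste(dim(truth), collapse = "x"))
  }
  assert_binary_mask(pred, "pred")
  assert_binary_mask(truth, "truth")
  if (!is.null(fov)) {
    keep <- fov == 1
    pred <- pred[keep]
    truth <- truth[keep]
  }
  p <- pred == 1L
  t <- truth == 1L
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "ret_confusion")
}

#' Sum confusion counts (dataset pooling)
#'
#' @param ... `ret_confusion` objects, or a single list of them.
#' @return Pooled `ret_confusion`.
#' @export
confusion_pool <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "ret_confusion")) xs <- xs[[1]]
  out <- list(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (x in xs) {
    stopifnot(inherits(x, "ret_confusion"))
    for (f in names(out)) out[[f]] <- out[[f]] + x[[f]]
  }
  structure(out, class = "ret_confusion")
}

safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, degenerate = TRUE)
  else list(value = num / den, degenerate = FALSE)
}

#' Segmentation metrics from confusion counts
#'
#' Any 0/0 ratio (e.g. empty prediction and empty truth) is defined as 0
#' and flagged in the `degenerate` field with a warning, which keeps
#' dataset pooling total.
#'
#' @param cc A `ret_confusion`.
#' @return A `ret_metrics` list: `accuracy`, `iou`, `precision`, `recall`,
#'   `f1`, plus `degenerate` (character vector of flagged metrics).
#' @export
segmentation_metrics <- function(cc) {
  stopifnot(inherits(cc, "ret_confusion"))
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  if (n <= 0) stop("confusion counts are empty")
  acc <- safe_ratio(cc$tp + cc$tn, n)
  iou <- safe_ratio(cc$tp, cc$tp + cc$fp + cc$fn)
  prec <- safe_ratio(cc$tp, cc$tp + cc$fp)
  rec <- safe_ratio(cc$tp, cc$tp + cc$fn)
  f1 <- if (prec$value + rec$value == 0) {
    list(value = 0, degenerate = TRUE)
  } else {
    list(value = 2 * prec$value * rec$value / (prec$value + rec$value),
         degenerate = FALSE)
  }
  parts <- list(accuracy = acc, iou = iou, precision = prec, recall = rec,
                f1 = f1)
  degen <- names(parts)[vapply(parts, `[[`, logical(1), "degenerate")]
  if (length(degen)) {
    warning("0/0 ratio(s) defined as 0 for: ",
            paste(degen, collapse = ", "))
  }
  structure(c(lapply(parts, `[[`, "value"), list(degenerate = degen)),
            class = "ret_metrics")
}

#' @export
print.ret_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  iou %.4f  precision %.4f  recall %.4f  f1 %.4f\n",
    x$accuracy, x$iou, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate predicted masks against reference masks
#'
#' @param preds,truths Lists of 0/1 matrices (same length and shapes).
#' @param average `"pooled"` (default: sum pixel counts over all images,
#'   then apply the metric formulas once) or `"per_image"` (mean of
#'   per-image metrics; breaks the F1/IoU identity).
#' @param fov Optional list of field-of-view masks.
#' @return A `ret_metrics` report.
#' @export
evaluate_segmentation <- function(preds, truths,
                                  average = c("pooled", "per_image"),
                                  fov = NULL) {
  average <- match.arg(average)
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  ccs <- lapply(seq_along(preds), function(i) {
    confusion(preds[[i]], truths[[i]], fov = fov[[i]])
  })
  if (average == "pooled") {
    segmentation_metrics(confusion_pool(ccs))
  } else {
    ms <- lapply(ccs, segmentation_metrics)
    fields <- c("accuracy", "iou", "precision", "recall", "f1")
    out <- lapply(fields, function(f) {
      mean(vapply(ms, `[[`, numeric(1), f))
    })
    names(out) <- fields
    structure(c(out, list(degenerate = unique(unlist(
      lapply(ms, `[[`, "degenerate"))))), class = "ret_metrics")
  }
}

#' Exact-match accuracy of grade predictions
#'
#' @param pred_grades,true_grades Equal-length integer vectors of grades in
#'   `0..4` (the five-step diabetic retinopathy scale).
#' @return Fraction of exact matches in `[0, 1]`.
#' @export
grading_accuracy <- function(pred_grades, true_grades) {
  if (length(pred_grades) != length(true_grades) || !length(pred_grades)) {
    stop("grade vectors must have equal positive length")
  }
  check_grades(pred_grades)
  check_grades(true_grades)
  mean(pred_grades == true_grades)
}

check_grades <- function(g) {
  if (any(!is.finite(g)) || any(g != as.integer(g)) || any(g < 0 | g > 4)) {
    stop("grades must be integers in 0..4")
  }
  invisible(g)
}

#' Serialise a metric report
#'
#' `metrics_csv_line()` renders the fixed-order CSV row
#' `accuracy,iou,precision,recall,f1`; `metrics_json()` the JSON object.
#'
#' @param x A `ret_metrics`.
#' @param path Optional file to write to.
#' @return The formatted string, invisibly when written to a file.
#' @export
metrics_csv_line <- function(x, path = NULL) {
  line <- paste(formatC(c(x$accuracy, x$iou, x$precision, x$recall, x$f1),
                        format = "f", digits = 6), collapse = ",")
  if (is.null(path)) return(line)
  writeLines(c("accuracy,iou,precision,recall,f1", line), path)
  invisible(line)
}

#' @rdname metrics_csv_line
#' @export
metrics_json <- function(x, path = NULL) {
  obj <- x[c("accuracy", "iou", "precision", "recall", "f1")]
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}
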