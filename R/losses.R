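# Loss functions.
#
# Segmentation is supervised by the sum of per-pixel binary cross-entropy
# and soft Dice loss, L = L_ce + L_dice; with deep supervision over n
# outputs the vessel loss is sum_k lambda_k (L_ce^k + L_dice^k).  Grading
# is supervised by categorical cross-entropy over the 5 class
# probabilities, and the joint multi-task loss is their plain sum
# L = L_dr_ce + L_vessel.  Probabilities are clipped to
# [1e-7, 1 - 1e-7] before logs for numerical stability.

LOSS_EPS <- 1e-7

clip01 <- function(p) pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)

check_pair <- function(p, y) {
  if (!identical(dim(p), dim(y))) {
    stop("shape mismatch: p is ", paste(dim(p), collapse = "x"),
         ", y is ", paste(dim(y), collapse = "x"))
  }
}

#' Per-pixel binary cross-entropy
#'
#' Mean over pixels of `-(y log p + (1-y) log(1-p))` between a sigmoid
#' probability map and a 0/1 reference mask.
#'
#' @param p Probability matrix/array in `[0, 1]`.
#' @param y 0/1 mask of the same shape.
#' @return Non-negative scalar.
#' @export
seg_ce <- function(p, y) {
  check_pair(p, y)
  pc <- clip01(p)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' @rdname seg_ce
#' @return `seg_ce_grad()`: gradient of the loss w.r.t. `p` (same shape).
#' @export
seg_ce_grad <- function(p, y) {
  check_pair(p, y)
  pc <- clip01(p)
  g <- (-y / pc + (1 - y) / (1 - pc)) / length(p)
  # clipped region has zero sensitivity to p
  g[p < LOSS_EPS | p > 1 - LOSS_EPS] <- 0
  if (!is.null(dim(p))) dim(g) <- dim(p)
  g
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p*y) + s) / (sum(p) + sum(y) + s)` on raw (un-binarized)
#' probabilities; the smoothing term `s` keeps the empty-empty case at 0
#' and the loss differentiable.
#'
#' @inheritParams seg_ce
#' @param smooth Smoothing constant, default 1.
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(p, y, smooth = 1) {
  check_pair(p, y)
  1 - (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
}

#' @rdname dice_loss
#' @return `dice_loss_grad()`: gradient of the loss w.r.t. `p`.
#' @export
dice_loss_grad <- function(p, y, smooth = 1) {
  check_pair(p, y)
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  g <- -(2 * y * den - num) / den^2
  if (!is.null(dim(p))) dim(g) <- dim(p)
  g
}

#' Vessel loss configuration (deep-supervision weights)
#'
#' @param n Number of supervised segmentation outputs (default 1: no deep
#'   supervision).
#' @param lambdas `n` positive weights, default all 1.
#' @return A `ret_vessel_loss_config`.
#' @export
vessel_loss_config <- function(n = 1L, lambdas = rep(1, n)) {
  stopifnot(n >= 1, length(lambdas) == n, all(lambdas > 0))
  structure(list(n = as.integer(n), lambdas = as.numeric(lambdas)),
            class = "ret_vessel_loss_config")
}

#' Weighted vessel segmentation loss
#'
#' `sum_k lambda_k * (ce_k + dice_k)` over the supervised outputs.  With
#' `n = 1`, `lambda = 1` this is exactly `seg_ce(p, y) + dice_loss(p, y)`.
#'
#' @param p,y A probability map and mask, or lists of `cfg$n` of them.
#' @param cfg A [vessel_loss_config()].
#' @return A `ret_seg_loss` breakdown: `ce`, `dice` (lambda-weighted sums)
#'   and `total == ce + dice`; `per_output` keeps the unweighted pairs.
#' @export
seg_loss <- function(p, y, cfg = vessel_loss_config()) {
  stopifnot(inherits(cfg, "ret_vessel_loss_config"))
  if (!is.list(p)) p <- list(p)
  if (!is.list(y)) y <- list(y)
  if (length(p) != cfg$n || length(y) != cfg$n) {
    stop("expected ", cfg$n, " supervised output(s), got ", length(p))
  }
  per <- lapply(seq_len(cfg$n), function(k) {
    list(ce = seg_ce(p[[k]], y[[k]]), dice = dice_loss(p[[k]], y[[k]]),
         lambda = cfg$lambdas[k])
  })
  ce <- sum(vapply(per, function(o) o$lambda * o$ce, numeric(1)))
  dice <- sum(vapply(per, function(o) o$lambda * o$dice, numeric(1)))
  structure(list(ce = ce, dice = dice, total = ce + dice, per_output = per),
            class = "ret_seg_loss")
}

#' Grading cross-entropy
#'
#' `-log(p[label + 1])`: categorical cross-entropy between a 5-class
#' probability vector and a one-hot grade label.
#'
#' @param probs Numeric probability vector (5 classes, sums to 1 within
#'   1e-6).
#' @param label Integer grade in `0..4`.
#' @return Non-negative scalar.
#' @export
dr_ce <- function(probs, label) {
  if (abs(sum(probs) - 1) > 1e-6) {
    stop("class probabilities must sum to 1 (got ", sum(probs), ")")
  }
  if (any(probs < 0)) stop("class probabilities must be non-negative")
  check_grades(label)
  -log(clip01(probs[label + 1L]))
}

#' @rdname dr_ce
#' @return `dr_ce_grad()`: gradient w.r.t. `probs` (same length).
#' @export
dr_ce_grad <- function(probs, label) {
  check_grades(label)
  g <- numeric(length(probs))
  g[label + 1L] <- -1 / clip01(probs[label + 1L])
  g
}

#' Joint multi-task loss
#'
#' @param dr Grading cross-entropy term (finite, non-negative).
#' @param vessel Vessel segmentation loss term (finite, non-negative), a
#'   scalar or a `ret_seg_loss` (its `total` is used).
#' @return A `ret_joint_loss` breakdown: `dr_ce`, `vessel`,
#'   `total == dr_ce + vessel`.
#' @export
joint_loss <- function(dr, vessel) {
  if (inherits(vessel, "ret_seg_loss")) vessel <- vessel$total
  stopifnot(is.finite(dr), is.finite(vessel))
  structure(list(dr_ce = dr, vessel = vessel, total = dr + vessel),
            class = "ret_joint_loss")
}
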