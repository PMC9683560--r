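# First-principles complexity accounting over a model spec.
#
# Counting rules (the standard profiler conventions):
#   conv:  params = k^2 * Cin * Cout (+ Cout if biased); a batch-norm that
#          follows contributes its own 2 * Cout scale/shift scalars and the
#          conv carries no bias.
#          MACs = k^2 * Cin * Cout * Hout * Wout.
#   fc:    params = Nin * Nout + Nout;  MACs = Nin * Nout.
#   batch-norm (inference-folded), activations, bilinear upsampling,
#   pooling, softmax: zero MACs.
# "GFLOPs" is reported as giga-MACs (1 MAC = 1 reported FLOP), the
# dominant convention among network profilers; `flops_per_mac` is the
# single knob that flips the convention globally should 2x counting ever
# be required.

node_params <- function(node) {
  switch(node$op,
    conv = node$k^2 * node$cin * node$cout + if (node$bias) node$cout else 0,
    bn = 2 * node$cout,
    fc = node$cin * node$cout + node$cout,
    0)
}

node_macs <- function(node, input_hw) {
  switch(node$op,
    conv = {
      hout <- input_hw[1] / node$div
      wout <- input_hw[2] / node$div
      node$k^2 * node$cin * node$cout * hout * wout
    },
    fc = node$cin * node$cout,
    0)
}

complexity_table <- function(spec, input_hw = NULL) {
  nodes <- spec$graph
  blocks <- vapply(nodes, function(n) n$block, character(1))
  groups <- vapply(nodes, function(n) n$group, character(1))
  params <- vapply(nodes, node_params, numeric(1))
  macs <- if (is.null(input_hw)) rep(0, length(nodes)) else
    vapply(nodes, node_macs, numeric(1), input_hw = input_hw)
  keep <- params > 0 | macs > 0
  df <- data.frame(block = blocks[keep], group = groups[keep],
                   params = params[keep], macs = macs[keep],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(params, macs) ~ block + group, df, sum)
  # preserve graph order of first appearance
  agg[order(match(agg$block, unique(blocks[keep]))), , drop = FALSE]
}

new_complexity_report <- function(spec, per_block, input_hw = NULL,
                                  flops_per_mac = 1) {
  params <- sum(per_block$params)
  macs <- sum(per_block$macs)
  structure(list(model = spec$name, params = params,
                 params_millions = round(params / 1e6, 1),
                 macs = macs,
                 gflops = round(flops_per_mac * macs / 1e9, 1),
                 flops_per_mac = flops_per_mac,
                 input_hw = input_hw, per_block = per_block),
            class = "ret_complexity")
}

#' Count trainable parameters of a model spec
#'
#' Exact integer arithmetic over the spec's layers (no instantiation);
#' [ret_num_params()] on an instantiated model is the brute-force
#' cross-check and must agree exactly.  The count is independent of the
#' input size for every fully-convolutional part of the model.
#'
#' @param spec A `ret_model_spec`.
#' @param groups Restrict to these parameter groups (default: all).
#' @return A `ret_complexity` report; `params` is the exact count,
#'   `params_millions` the count / 1e6 rounded to 1 decimal (the unit the
#'   architecture's printed budgets use).
#' @export
count_params <- function(spec, groups = NULL) {
  stopifnot(inherits(spec, "ret_model_spec"))
  pb <- complexity_table(spec)
  if (!is.null(groups)) pb <- pb[pb$group %in% groups, , drop = FALSE]
  new_complexity_report(spec, pb)
}

#' Count multiply-accumulate operations of a model spec
#'
#' @param spec A `ret_model_spec`.
#' @param input_hw Input height/width, each divisible by the spec's size
#'   divisor (16 for the full networks).
#' @param groups Restrict to these parameter groups (default: all).
#' @param flops_per_mac Reporting convention; 1 (default) reports
#'   giga-MACs as GFLOPs.
#' @return A `ret_complexity` report; `macs` is exact, `gflops` is
#'   `flops_per_mac * macs / 1e9` rounded to 1 decimal.
#' @export
count_macs <- function(spec, input_hw = c(512L, 512L), groups = NULL,
                       flops_per_mac = 1) {
  stopifnot(inherits(spec, "ret_model_spec"))
  if (length(input_hw) == 1L) input_hw <- rep(input_hw, 2L)
  if (any(input_hw %% spec$size_divisor != 0)) {
    stop("input_hw must be divisible by ", spec$size_divisor)
  }
  pb <- complexity_table(spec, input_hw = input_hw)
  if (!is.null(groups)) pb <- pb[pb$group %in% groups, , drop = FALSE]
  new_complexity_report(spec, pb, input_hw = input_hw,
                        flops_per_mac = flops_per_mac)
}

#' Parameter and computation savings from hard sharing
#'
#' Given the complexity of the two single-task networks and of the joint
#' network, the saving is `100 * (x1 + x2 - x_joint) / (x1 + x2)`,
#' evaluated on the reported (1-decimal) millions of parameters and
#' GFLOPs, i.e. the same arithmetic a reader would do on the printed
#' complexity tables.
#'
#' @param seg,cls,joint `ret_complexity` reports for the
#'   segmentation-only, grading-only and joint networks; parameter reports
#'   and MAC reports may be passed pairwise via `seg = list(params=, macs=)`
#'   style, or single reports carrying both sides.
#' @return Named numeric vector `c(param_saving_pct, flop_saving_pct)`
#'   (either entry NA when that side is absent from the reports).
#' @export
sharing_savings <- function(seg, cls, joint) {
  side <- function(field) {
    x1 <- seg[[field]]; x2 <- cls[[field]]; xj <- joint[[field]]
    if (is.null(x1) || is.null(x2) || is.null(xj)) return(NA_real_)
    if (field == "gflops" && (x1 == 0 && x2 == 0)) return(NA_real_)
    if (x1 + x2 == 0) stop("zero denominator in sharing_savings")
    100 * (x1 + x2 - xj) / (x1 + x2)
  }
  c(param_saving_pct = side("params_millions"),
    flop_saving_pct = side("gflops"))
}

#' @export
print.ret_complexity <- function(x, ...) {
  cat(sprintf("<ret_complexity> %s\n", x$model))
  if (!is.null(x$input_hw)) {
    cat(sprintf("  input %dx%d: %.1f GFLOPs (%.0f MACs)\n",
                x$input_hw[1], x$input_hw[2], x$gflops, x$macs))
  }
  if (x$params > 0) {
    cat(sprintf("  %.1f M parameters (%.0f exact)\n",
                x$params_millions, x$params))
  }
  invisible(x)
}

#' Per-block complexity profile of a model
#'
#' Convenience wrapper producing the block / parameters / MACs table the
#' `profile` command prints.
#'
#' @param spec A `ret_model_spec`.
#' @param input_hw Input size for the MAC side.
#' @return data.frame with columns block, group, params, macs, plus a
#'   final TOTAL row.
#' @export
profile_model <- function(spec, input_hw = c(512L, 512L)) {
  if (length(input_hw) == 1L) input_hw <- rep(input_hw, 2L)
  pb <- complexity_table(spec, input_hw = input_hw)
  rbind(pb, data.frame(block = "TOTAL", group = "",
                       params = sum(pb$params), macs = sum(pb$macs)))
}
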