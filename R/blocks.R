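# Building blocks: user-facing block specs and their lowering into
# primitive graph nodes.
#
# Block vocabulary (field conventions follow the CSP / DeepLab lineage):
#   conv_block      conv -> BatchNorm -> LeakyReLU(0.1); 3x3 pad 1 or 1x1
#   bottleneck_csp  cross-stage-partial block: the input is split through
#                   two half-width 1x1 convolutions; one path runs `repeats`
#                   residual bottlenecks (1x1 then 3x3, additive skip), the
#                   other is a plain 1x1 shortcut; the two are channel-
#                   concatenated, normalised, and fused by a final 1x1 conv
#   aspp            atrous spatial pyramid pooling: a 1x1 branch plus one
#                   3x3 dilated branch per rate (default 6/12/18), all
#                   shape-preserving (padding = dilation), concatenated and
#                   projected back by a 1x1 conv
#   upsample_block  bilinear x2 upsampling followed by a conv_block

#' Declare a convolution block
#'
#' A convolution (no bias) followed by batch normalisation and
#' LeakyReLU(0.1).  Stride 2 halves each spatial dimension exactly for
#' even inputs (kernel 3, padding 1).
#'
#' @param in_channels,out_channels Positive channel counts.
#' @param stride 1 or 2.
#' @param kernel Kernel size, 1 or 3.
#' @return A `ret_block_spec`.
#' @export
make_conv_block <- function(in_channels, out_channels, stride = 1L,
                            kernel = 3L) {
  stopifnot(in_channels >= 1, out_channels >= 1)
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2, got ", stride)
  if (!kernel %in% c(1L, 3L)) stop("kernel must be 1 or 3, got ", kernel)
  structure(list(kind = "conv_block", in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride), kernel = as.integer(kernel)),
            class = "ret_block_spec")
}

#' Declare a cross-stage-partial bottleneck block
#'
#' @param in_channels,out_channels Channel counts; `out_channels` must be
#'   even (the block splits it in half internally).
#' @param repeats Number of residual bottlenecks on the feature path.
#' @return A `ret_block_spec`.
#' @export
make_bottleneck_csp <- function(in_channels, out_channels, repeats = 1L) {
  stopifnot(in_channels >= 1, out_channels >= 1, repeats >= 1)
  if (out_channels %% 2L != 0L) {
    stop("bottleneck_csp out_channels must be even, got ", out_channels)
  }
  structure(list(kind = "bottleneck_csp",
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 repeats = as.integer(repeats)),
            class = "ret_block_spec")
}

#' Declare an atrous spatial pyramid pooling block
#'
#' @param in_channels,out_channels Channel counts.
#' @param rates Positive dilation rates for the three (or more) dilated
#'   3x3 branches, conventionally strictly increasing; default
#'   `c(6, 12, 18)`.  `rates = c(1, 1, 1)` degenerates to ordinary 3x3
#'   convolutions.
#' @return A `ret_block_spec`.
#' @export
make_aspp <- function(in_channels, out_channels, rates = c(6L, 12L, 18L)) {
  stopifnot(in_channels >= 1, out_channels >= 1, length(rates) >= 1)
  if (any(rates <= 0)) stop("dilation rates must be positive")
  structure(list(kind = "aspp", in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 rates = as.integer(rates)),
            class = "ret_block_spec")
}

#' Declare a bilinear upsampling block
#'
#' Bilinear x2 upsampling (half-pixel centres, no corner alignment)
#' followed by a 3x3 conv_block.
#'
#' @param in_channels,out_channels Channel counts.
#' @return A `ret_block_spec`.
#' @export
make_upsample_block <- function(in_channels, out_channels) {
  stopifnot(in_channels >= 1, out_channels >= 1)
  structure(list(kind = "upsample_block",
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "ret_block_spec")
}

# ---- lowering into graph nodes ------------------------------------------

emit_conv_bn_act <- function(gb, inp, cin, cout, prefix, group, div,
                             k = 3L, stride = 1L, dil = 1L, block = prefix) {
  pad <- dil * (k - 1L) %/% 2L
  div_out <- div * stride
  cv <- graph_add(gb, paste0(prefix, ".conv"), "conv", inp, cin = cin,
                  cout = cout, k = k, stride = stride, dil = dil, pad = pad,
                  bias = FALSE, div = div_out, block = block, group = group)
  bn <- graph_add(gb, paste0(prefix, ".bn"), "bn", cv, cout = cout,
                  div = div_out, block = block, group = group)
  graph_add(gb, paste0(prefix, ".act"), "lrelu", bn, cout = cout,
            div = div_out, block = block, group = group)
}

emit_conv_block <- function(gb, inp, blk, prefix, group, div) {
  emit_conv_bn_act(gb, inp, blk$in_channels, blk$out_channels, prefix,
                   group, div, k = blk$kernel, stride = blk$stride)
}

emit_bottleneck_csp <- function(gb, inp, blk, prefix, group, div) {
  cin <- blk$in_channels
  cout <- blk$out_channels
  h <- cout %/% 2L
  a <- emit_conv_bn_act(gb, inp, cin, h, paste0(prefix, ".cv1"), group, div,
                        k = 1L, block = prefix)
  for (j in seq_len(blk$repeats)) {
    b1 <- emit_conv_bn_act(gb, a, h, h, paste0(prefix, ".b", j, ".cv1"),
                           group, div, k = 1L, block = prefix)
    b2 <- emit_conv_bn_act(gb, b1, h, h, paste0(prefix, ".b", j, ".cv2"),
                           group, div, k = 3L, block = prefix)
    a <- graph_add(gb, paste0(prefix, ".b", j, ".add"), "add", c(a, b2),
                   cout = h, div = div, block = prefix, group = group)
  }
  shortcut <- graph_add(gb, paste0(prefix, ".cv2"), "conv", inp, cin = cin,
                        cout = h, k = 1L, stride = 1L, dil = 1L, pad = 0L,
                        bias = FALSE, div = div, block = prefix,
                        group = group)
  cat_id <- graph_add(gb, paste0(prefix, ".cat"), "concat", c(a, shortcut),
                      cout = 2L * h, div = div, block = prefix, group = group)
  bn <- graph_add(gb, paste0(prefix, ".catbn"), "bn", cat_id, cout = 2L * h,
                  div = div, block = prefix, group = group)
  act <- graph_add(gb, paste0(prefix, ".catact"), "lrelu", bn, cout = 2L * h,
                   div = div, block = prefix, group = group)
  emit_conv_bn_act(gb, act, 2L * h, cout, paste0(prefix, ".cv3"), group, div,
                   k = 1L, block = prefix)
}

emit_aspp <- function(gb, inp, blk, prefix, group, div) {
  cin <- blk$in_channels
  cout <- blk$out_channels
  branches <- emit_conv_bn_act(gb, inp, cin, cout, paste0(prefix, ".b0"),
                               group, div, k = 1L, block = prefix)
  for (i in seq_along(blk$rates)) {
    branches <- c(branches,
                  emit_conv_bn_act(gb, inp, cin, cout,
                                   paste0(prefix, ".r", i, "_",
                                          blk$rates[i]), group, div,
                                   k = 3L, dil = blk$rates[i],
                                   block = prefix))
  }
  cat_id <- graph_add(gb, paste0(prefix, ".cat"), "concat", branches,
                      cout = cout * (1L + length(blk$rates)), div = div,
                      block = prefix, group = group)
  emit_conv_bn_act(gb, cat_id, cout * (1L + length(blk$rates)), cout,
                   paste0(prefix, ".proj"), group, div, k = 1L,
                   block = prefix)
}

emit_upsample_block <- function(gb, inp, blk, prefix, group, div) {
  stopifnot(div %% 2L == 0L)
  up <- graph_add(gb, paste0(prefix, ".up"), "upsample2x", inp,
                  cout = blk$in_channels, div = div %/% 2L, block = prefix,
                  group = group)
  emit_conv_bn_act(gb, up, blk$in_channels, blk$out_channels,
                   paste0(prefix, ".cv"), group, div %/% 2L, k = 3L,
                   block = prefix)
}

emit_block <- function(gb, inp, blk, prefix, group, div) {
  switch(blk$kind,
    conv_block = emit_conv_block(gb, inp, blk, prefix, group, div),
    bottleneck_csp = emit_bottleneck_csp(gb, inp, blk, prefix, group, div),
    aspp = emit_aspp(gb, inp, blk, prefix, group, div),
    upsample_block = emit_upsample_block(gb, inp, blk, prefix, group, div),
    stop("unknown block kind: ", blk$kind))
}

#' Wrap a single block as a standalone runnable model
#'
#' Mostly a test instrument: lets a single declared block be instantiated,
#' run forward, and profiled in isolation.
#'
#' @param blk A `ret_block_spec`.
#' @return A `ret_model_spec` whose single output `"out"` is the block's
#'   output.
#' @export
build_block_model <- function(blk) {
  gb <- new_graph()
  div0 <- if (blk$kind == "upsample_block") 2L else 1L
  inp <- graph_add(gb, "in", "input", cout = blk$in_channels, div = div0,
                   block = "input")
  out <- emit_block(gb, inp, blk, "blk", "shared", div0)
  max_div <- max(vapply(gb$nodes, function(n) n$div, integer(1)), 1L)
  structure(list(name = paste0("block_", blk$kind),
                 in_channels = blk$in_channels,
                 size_divisor = max_div, graph = gb$nodes,
                 outputs = list(out = out), hyper = list(block = unclass(blk))),
            class = "ret_model_spec")
}
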