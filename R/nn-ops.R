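# Low-level tensor operations for the network engine.
#
# Tensors are base-R double arrays with dim = c(H, W, C, N) (column-major).
# Every forward op returns list(out, cache); the matching backward takes the
# upstream gradient and the cache and returns gradients w.r.t. inputs and
# parameters.  Convolution weights are stored as a (k*k*Cin) x Cout matrix
# whose row order matches nn_im2col's column order (ki fastest, then kj, c).

#' @useDynLib retinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

conv_out_extent <- function(sz, k, stride, dil, pad) {
  (sz + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
}

# Broadcast a per-channel vector over an (H, W, C, N) tensor.
bc_channel <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

# Sum an (H, W, C, N) tensor over H, W and N, one value per channel.
channel_sum <- function(x) {
  d <- dim(x)
  cs <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(cs, d[3], d[4]))
}

op_conv_forward <- function(x, W, b, k, stride, dil, pad) {
  d <- dim(x)
  cout <- ncol(W)
  hout <- conv_out_extent(d[1], k, stride, dil, pad)
  wout <- conv_out_extent(d[2], k, stride, dil, pad)
  cols <- nn_im2col(x, as.integer(d), as.integer(k), as.integer(stride),
                    as.integer(dil), as.integer(pad))
  out <- cols %*% W
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  y <- aperm(array(out, c(hout, wout, d[4], cout)), c(1L, 2L, 4L, 3L))
  list(out = y, cache = list(cols = cols, xdim = d, W = W, has_bias = !is.null(b),
                             k = k, stride = stride, dil = dil, pad = pad))
}

op_conv_backward <- function(g, cache) {
  gd <- dim(g)
  m <- gd[1] * gd[2] * gd[4]
  gm <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), m, gd[3])
  dW <- crossprod(cache$cols, gm)
  db <- if (cache$has_bias) colSums(gm) else NULL
  dx <- nn_col2im(gm %*% t(cache$W), as.integer(cache$xdim),
                  as.integer(cache$k), as.integer(cache$stride),
                  as.integer(cache$dil), as.integer(cache$pad))
  list(dx = dx, dW = dW, db = db)
}

BN_EPS <- 1e-5

op_bn_forward <- function(x, gamma, beta, running_mean, running_var,
                          training, momentum = 0.1) {
  d <- dim(x)
  if (training) {
    n_per_ch <- d[1] * d[2] * d[4]
    mu <- channel_sum(x) / n_per_ch
    xc <- x - bc_channel(mu, d)
    v <- channel_sum(xc * xc) / n_per_ch
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * bc_channel(invstd, d)
    unbias <- if (n_per_ch > 1) n_per_ch / (n_per_ch - 1) else 1
    new_rm <- (1 - momentum) * running_mean + momentum * mu
    new_rv <- (1 - momentum) * running_var + momentum * v * unbias
  } else {
    invstd <- 1 / sqrt(running_var + BN_EPS)
    xhat <- (x - bc_channel(running_mean, d)) * bc_channel(invstd, d)
    new_rm <- running_mean
    new_rv <- running_var
  }
  y <- xhat * bc_channel(gamma, d) + bc_channel(beta, d)
  dim(y) <- d
  list(out = y,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    training = training),
       running_mean = new_rm, running_var = new_rv)
}

op_bn_backward <- function(g, cache) {
  d <- dim(g)
  xhat <- cache$xhat
  dgamma <- channel_sum(g * xhat)
  dbeta <- channel_sum(g)
  dxhat <- g * bc_channel(cache$gamma, d)
  if (cache$training) {
    m <- d[1] * d[2] * d[4]
    s1 <- channel_sum(dxhat)
    s2 <- channel_sum(dxhat * xhat)
    dx <- (dxhat - bc_channel(s1 / m, d) - xhat * bc_channel(s2 / m, d)) *
      bc_channel(cache$invstd, d)
  } else {
    dx <- dxhat * bc_channel(cache$invstd, d)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

LRELU_SLOPE <- 0.1

op_lrelu_forward <- function(x, slope = LRELU_SLOPE) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(out = y, cache = list(neg = neg, slope = slope))
}

op_lrelu_backward <- function(g, cache) {
  dx <- g
  dx[cache$neg] <- cache$slope * g[cache$neg]
  dx
}

op_sigmoid_forward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(out = y, cache = list(y = y))
}

op_sigmoid_backward <- function(g, cache) {
  g * cache$y * (1 - cache$y)
}

# Column-wise softmax on a (C, N) matrix.
op_softmax_forward <- function(x) {
  z <- exp(sweep(x, 2L, apply(x, 2L, max), "-"))
  y <- sweep(z, 2L, colSums(z), "/")
  list(out = y, cache = list(y = y))
}

op_softmax_backward <- function(g, cache) {
  y <- cache$y
  y * sweep(g, 2L, colSums(g * y), "-")
}

# Dense interpolation matrix (n_out x n_in) for 1-D linear resampling with
# half-pixel centres (align_corners = FALSE).  Its transpose is the exact
# adjoint used by the backward pass.
interp_matrix_env <- new.env(parent = emptyenv())

interp_matrix <- function(n_in, n_out) {
  key <- paste0(n_in, "_", n_out)
  hit <- interp_matrix_env[[key]]
  if (!is.null(hit)) return(hit)
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  lo <- pmin(pmax(floor(src), 0), n_in - 1)
  hi <- pmin(lo + 1, n_in - 1)
  frac <- pmin(pmax(src - lo, 0), 1)
  idx <- seq_len(n_out)
  A[cbind(idx, lo + 1)] <- A[cbind(idx, lo + 1)] + (1 - frac)
  A[cbind(idx, hi + 1)] <- A[cbind(idx, hi + 1)] + frac
  interp_matrix_env[[key]] <- A
  A
}

# Apply row matrix A along H and B along W of an (H, W, C, N) tensor.
apply_separable <- function(x, A, B) {
  d <- dim(x)
  y <- A %*% matrix(x, d[1], d[2] * d[3] * d[4])
  h2 <- nrow(A)
  dim(y) <- c(h2, d[2], d[3], d[4])
  yp <- aperm(y, c(2L, 1L, 3L, 4L))
  z <- B %*% matrix(yp, d[2], h2 * d[3] * d[4])
  dim(z) <- c(nrow(B), h2, d[3], d[4])
  aperm(z, c(2L, 1L, 3L, 4L))
}

op_bilinear_resize_forward <- function(x, out_h, out_w) {
  d <- dim(x)
  A <- interp_matrix(d[1], out_h)
  B <- interp_matrix(d[2], out_w)
  list(out = apply_separable(x, A, B),
       cache = list(A = A, B = B))
}

op_bilinear_resize_backward <- function(g, cache) {
  apply_separable(g, t(cache$A), t(cache$B))
}

# Nearest-neighbour index map with the same half-pixel convention.
nearest_index <- function(n_in, n_out) {
  src <- floor((seq_len(n_out) - 0.5) * n_in / n_out)
  pmin(pmax(src, 0), n_in - 1) + 1
}

op_gap_forward <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  y <- matrix(colSums(matrix(x, hw, d[3] * d[4])) / hw, d[3], d[4])
  list(out = y, cache = list(xdim = d))
}

op_gap_backward <- function(g, cache) {
  d <- cache$xdim
  hw <- d[1] * d[2]
  dx <- array(rep(as.numeric(g), each = hw) / hw, d)
  dx
}

op_fc_forward <- function(x, W, b) {
  y <- crossprod(W, x)
  if (!is.null(b)) y <- y + b
  list(out = y, cache = list(x = x, W = W, has_bias = !is.null(b)))
}

op_fc_backward <- function(g, cache) {
  list(dx = cache$W %*% g,
       dW = cache$x %*% t(g),
       db = if (cache$has_bias) rowSums(g) else NULL)
}

op_add_forward <- function(a, b) {
  list(out = a + b, cache = NULL)
}

op_concat_forward <- function(inputs) {
  d1 <- dim(inputs[[1]])
  cs <- vapply(inputs, function(x) dim(x)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (x in inputs) {
    cx <- dim(x)[3]
    out[, , at + seq_len(cx), ] <- x
    at <- at + cx
  }
  list(out = out, cache = list(channels = cs))
}

op_concat_backward <- function(g, cache) {
  cs <- cache$channels
  at <- 0L
  out <- vector("list", length(cs))
  for (i in seq_along(cs)) {
    out[[i]] <- g[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}
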