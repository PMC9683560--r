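# Network graph engine.
#
# A model spec's graph is an ordered list of primitive nodes (the order is
# topological by construction).  Each node is a plain list with fields:
#   id      unique character key
#   op      one of input, conv, bn, lrelu, sigmoid, softmax, add, concat,
#           upsample2x, gap, fc
#   inputs  character vector of upstream node ids
#   cin/cout, k, stride, dil, pad, bias   shape metadata (conv / fc)
#   div     spatial downsampling divisor of the node's output w.r.t. input
#   block   human-readable block label (complexity reports group by it)
#   group   parameter group: "shared", "branch1" or "branch2"
# The same graph drives instantiation, forward/backward, and the complexity
# accountant, so the two can be cross-checked against each other.

new_graph <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb
}

graph_add <- function(gb, id, op, inputs = character(), cin = NA_integer_,
                      cout = NA_integer_, k = NA_integer_, stride = 1L,
                      dil = 1L, pad = NA_integer_, bias = FALSE,
                      div = NA_integer_, block = id, group = "shared") {
  if (!is.null(gb$nodes[[id]])) {
    stop("duplicate node id: ", id)
  }
  for (inp in inputs) {
    if (is.null(gb$nodes[[inp]])) stop("unknown input node: ", inp)
  }
  gb$nodes[[id]] <- list(id = id, op = op, inputs = inputs,
                         cin = as.integer(cin), cout = as.integer(cout),
                         k = as.integer(k), stride = as.integer(stride),
                         dil = as.integer(dil), pad = as.integer(pad),
                         bias = bias, div = as.integer(div), block = block,
                         group = group)
  id
}

graph_node <- function(graph, id) graph[[id]]

# Ancestor closure of the requested output ids (the nodes a forward pass
# must execute), preserving the graph's topological order.
active_node_ids <- function(graph, output_ids) {
  needed <- new.env(parent = emptyenv())
  stack <- as.list(output_ids)
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!is.null(needed[[id]])) next
    needed[[id]] <- TRUE
    for (inp in graph[[id]]$inputs) stack[[length(stack) + 1L]] <- inp
  }
  ids <- names(graph)
  ids[vapply(ids, function(i) !is.null(needed[[i]]), logical(1))]
}

# ---- parameter initialisation -------------------------------------------

# Kaiming fan-in init matched to the LeakyReLU(0.1) nonlinearity.
kaiming_sd <- function(fan_in) sqrt(2 / ((1 + LRELU_SLOPE^2) * fan_in))

init_node_params <- function(node) {
  switch(node$op,
    conv = {
      fan_in <- node$k * node$k * node$cin
      W <- matrix(stats::rnorm(fan_in * node$cout, sd = kaiming_sd(fan_in)),
                  fan_in, node$cout)
      list(W = W, b = if (node$bias) numeric(node$cout) else NULL)
    },
    fc = {
      W <- matrix(stats::rnorm(node$cin * node$cout,
                               sd = kaiming_sd(node$cin)),
                  node$cin, node$cout)
      list(W = W, b = numeric(node$cout))
    },
    bn = list(gamma = rep(1, node$cout), beta = numeric(node$cout),
              running_mean = numeric(node$cout),
              running_var = rep(1, node$cout)),
    NULL)
}

#' Instantiate a model from its spec
#'
#' Allocates and initialises every trainable array declared by the spec's
#' graph (Kaiming fan-in initialisation under the given seed) and returns a
#' model object that [ret_forward()] and the training stages operate on.
#'
#' @param spec A model spec from [build_csp_unet()] or [build_mtnet()].
#' @param seed Integer seed controlling the random initialisation.
#' @return A `ret_model` list with elements `spec`, `params` (an environment
#'   keyed by node id) and `seed`.
#' @export
ret_instantiate <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "ret_model_spec"))
  set.seed(seed)
  params <- new.env(parent = emptyenv())
  for (node in spec$graph) {
    p <- init_node_params(node)
    if (!is.null(p)) params[[node$id]] <- p
  }
  structure(list(spec = spec, params = params, seed = seed),
            class = "ret_model")
}

# ---- forward / backward --------------------------------------------------

#' Run a model forward
#'
#' Executes the sub-graph needed for the requested outputs on a batch of
#' images.  In training mode batch-norm uses batch statistics (and updates
#' the running estimates in place) and per-node caches are kept for
#' [ret_backward()].
#'
#' @param model A `ret_model` from [ret_instantiate()].
#' @param x Input tensor, dim `c(H, W, 3, N)` with values in `[0, 1]`.
#' @param outputs Character vector of output names declared by the spec
#'   (`"seg"`, `"grade"`, or both).
#' @param training Logical; batch-statistics mode plus gradient caches.
#' @return List with `out` (named list of output arrays), and when
#'   `training = TRUE` the `acts`/`caches`/`active` bookkeeping consumed by
#'   [ret_backward()].
#' @export
ret_forward <- function(model, x, outputs = names(model$spec$outputs),
                        training = FALSE) {
  spec <- model$spec
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L, dim(x)[3] == spec$in_channels)
  dvz <- spec$size_divisor
  if (dim(x)[1] %% dvz != 0L || dim(x)[2] %% dvz != 0L) {
    stop("input height and width must be divisible by ", dvz,
         " (got ", dim(x)[1], "x", dim(x)[2], ")")
  }
  out_ids <- unlist(spec$outputs[outputs], use.names = FALSE)
  active <- active_node_ids(spec$graph, out_ids)
  params <- model$params
  acts <- new.env(parent = emptyenv())
  caches <- if (training) new.env(parent = emptyenv()) else NULL
  for (id in active) {
    node <- spec$graph[[id]]
    r <- switch(node$op,
      input = list(out = x, cache = NULL),
      conv = {
        p <- params[[id]]
        op_conv_forward(acts[[node$inputs]], p$W, p$b, node$k, node$stride,
                        node$dil, node$pad)
      },
      bn = {
        p <- params[[id]]
        rr <- op_bn_forward(acts[[node$inputs]], p$gamma, p$beta,
                            p$running_mean, p$running_var, training)
        if (training) {
          p$running_mean <- rr$running_mean
          p$running_var <- rr$running_var
          params[[id]] <- p
        }
        rr
      },
      lrelu = op_lrelu_forward(acts[[node$inputs]]),
      sigmoid = op_sigmoid_forward(acts[[node$inputs]]),
      softmax = op_softmax_forward(acts[[node$inputs]]),
      add = op_add_forward(acts[[node$inputs[1]]], acts[[node$inputs[2]]]),
      concat = op_concat_forward(lapply(node$inputs, function(i) acts[[i]])),
      upsample2x = {
        xin <- acts[[node$inputs]]
        op_bilinear_resize_forward(xin, 2L * dim(xin)[1], 2L * dim(xin)[2])
      },
      gap = op_gap_forward(acts[[node$inputs]]),
      fc = {
        p <- params[[id]]
        op_fc_forward(acts[[node$inputs]], p$W, p$b)
      },
      stop("unknown op: ", node$op))
    acts[[id]] <- r$out
    if (training && !is.null(r$cache)) caches[[id]] <- r$cache
  }
  out <- lapply(spec$outputs[outputs], function(i) acts[[i]])
  list(out = out, acts = acts, caches = caches, active = active)
}

#' Backpropagate through a forward pass
#'
#' @param model A `ret_model`.
#' @param fw The value returned by `ret_forward(..., training = TRUE)`.
#' @param out_grads Named list mapping output names to gradient arrays of
#'   the loss w.r.t. that output.
#' @return Environment keyed by node id holding parameter gradients
#'   (`dW`/`db` or `dgamma`/`dbeta`).
#' @export
ret_backward <- function(model, fw, out_grads) {
  spec <- model$spec
  gacts <- new.env(parent = emptyenv())
  for (nm in names(out_grads)) {
    id <- spec$outputs[[nm]]
    g0 <- out_grads[[nm]]
    gacts[[id]] <- if (is.null(gacts[[id]])) g0 else gacts[[id]] + g0
  }
  pgrads <- new.env(parent = emptyenv())
  push <- function(id, g) {
    gacts[[id]] <- if (is.null(gacts[[id]])) g else gacts[[id]] + g
  }
  for (id in rev(fw$active)) {
    g <- gacts[[id]]
    if (is.null(g)) next
    node <- spec$graph[[id]]
    cache <- if (!is.null(fw$caches)) fw$caches[[id]] else NULL
    switch(node$op,
      input = NULL,
      conv = {
        r <- op_conv_backward(g, cache)
        pgrads[[id]] <- list(dW = r$dW, db = r$db)
        push(node$inputs, r$dx)
      },
      bn = {
        r <- op_bn_backward(g, cache)
        pgrads[[id]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
        push(node$inputs, r$dx)
      },
      lrelu = push(node$inputs, op_lrelu_backward(g, cache)),
      sigmoid = push(node$inputs, op_sigmoid_backward(g, cache)),
      softmax = push(node$inputs, op_softmax_backward(g, cache)),
      add = {
        push(node$inputs[1], g)
        push(node$inputs[2], g)
      },
      concat = {
        parts <- op_concat_backward(g, cache)
        for (i in seq_along(node$inputs)) push(node$inputs[i], parts[[i]])
      },
      upsample2x = push(node$inputs, op_bilinear_resize_backward(g, cache)),
      gap = push(node$inputs, op_gap_backward(g, cache)),
      fc = {
        r <- op_fc_backward(g, cache)
        pgrads[[id]] <- list(dW = r$dW, db = r$db)
        push(node$inputs, r$dx)
      },
      stop("unknown op: ", node$op))
    # free the activation gradient once consumed
    gacts[[id]] <- NULL
  }
  pgrads
}

# ---- parameter bookkeeping ----------------------------------------------

param_arrays <- function(p) {
  # trainable arrays only; batch-norm running stats are buffers
  p[names(p) %in% c("W", "b", "gamma", "beta")]
}

#' Enumerate every trainable array of an instantiated model
#'
#' Brute-force census of the allocated weight arrays, independent of the
#' analytic accountant in [count_params()]; the two must agree exactly.
#'
#' @param model A `ret_model`.
#' @param groups Restrict to these parameter groups (default: all).
#' @return Total number of trainable scalars (a double, exact integer).
#' @export
ret_num_params <- function(model, groups = NULL) {
  total <- 0
  for (node in model$spec$graph) {
    if (!is.null(groups) && !(node$group %in% groups)) next
    p <- model$params[[node$id]]
    if (is.null(p)) next
    for (a in param_arrays(p)) total <- total + length(a)
  }
  total
}

#' @return Named character vector mapping node id to parameter group, for
#'   nodes that own trainable parameters.
#' @noRd
ret_param_groups <- function(spec) {
  ids <- names(spec$graph)
  own <- vapply(spec$graph, function(n) n$op %in% c("conv", "bn", "fc"),
                logical(1))
  stats::setNames(vapply(spec$graph[own], function(n) n$group, character(1)),
                  ids[own])
}

# ---- Adam ----------------------------------------------------------------

new_adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st
}

#' One Adam update over selected parameter groups
#'
#' Standard Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8, no weight decay).
#' Only nodes whose `group` is in `groups` are updated, which is how the
#' staged protocol freezes the shared encoder or a branch.
#'
#' @param model A `ret_model` (updated in place via its params environment).
#' @param pgrads Gradients from [ret_backward()].
#' @param state Optimiser state from `new_adam_state()`; step count lives
#'   here so the bias correction is shared across calls.
#' @param lr Learning rate for this step.
#' @param groups Parameter groups to update.
#' @return Invisibly, the number of parameter tensors updated.
#' @export
ret_adam_step <- function(model, pgrads, state, lr,
                          groups = c("shared", "branch1", "branch2")) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  grad_key <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  n_upd <- 0L
  for (id in ls(pgrads)) {
    node <- model$spec$graph[[id]]
    if (!(node$group %in% groups)) next
    p <- model$params[[id]]
    g <- pgrads[[id]]
    sl <- state[[id]]
    if (is.null(sl)) sl <- list()
    for (nm in names(param_arrays(p))) {
      gv <- g[[grad_key[[nm]]]]
      if (is.null(gv)) next
      m <- sl[[paste0("m_", nm)]]
      v <- sl[[paste0("v_", nm)]]
      if (is.null(m)) { m <- gv * 0; v <- gv * 0 }
      m <- b1 * m + (1 - b1) * gv
      v <- b2 * v + (1 - b2) * gv * gv
      p[[nm]] <- p[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      sl[[paste0("m_", nm)]] <- m
      sl[[paste0("v_", nm)]] <- v
      n_upd <- n_upd + 1L
    }
    model$params[[id]] <- p
    state[[id]] <- sl
  }
  invisible(n_upd)
}
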