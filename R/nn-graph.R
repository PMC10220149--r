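# Static computation-graph engine: a network is an ordered list of nodes
# (conv / lrelu / add / concat / slice / upsample) evaluated forwards; the
# reverse sweep accumulates exact gradients for every conv weight and bias.

graph_builder <- function() {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb
}

gb_add <- function(gb, name, op, inputs, ...) {
  gb$nodes[[name]] <- c(list(name = name, op = op, inputs = inputs),
                        list(...))
  name
}

gb_conv <- function(gb, name, input, cin, cout, k = 3, act = "lrelu",
                    init_scale = 1) {
  gb_add(gb, name, "conv", input, k = k, cin = cin, cout = cout, act = act,
         init_scale = init_scale)
}

# Symmetric fan-in-scaled uniform initialisation. Rectified layers carry
# the leaky-ReLU variance gain 2 / (1 + alpha^2); linear layers (residual
# pre-add convs, output heads) use unit gain. Activation variance is then
# approximately preserved through the deep stack: a residual block sums
# two ~unit-variance paths and the post-sum rectifier halves the product
# back to ~1.
conv_param_init <- function(k, cin, cout, act = "lrelu", scale = 1) {
  fan_in <- k^3 * cin
  gain <- if (act == "lrelu") 2 / (1 + LRELU_ALPHA^2) else 0.5
  lim <- sqrt(6 * gain / fan_in)
  list(w = scale * matrix(runif(fan_in * cout, -lim, lim), fan_in, cout),
       b = numeric(cout))
}

init_graph_params <- function(nodes, seed) {
  set.seed(seed)
  params <- list()
  for (nd in nodes)
    if (nd$op == "conv")
      params[[nd$name]] <- conv_param_init(nd$k, nd$cin, nd$cout, nd$act,
                                           nd$init_scale %||% 1)
  params
}

nn_forward <- function(model, vel, mag, keep = FALSE) {
  vals <- new.env(parent = emptyenv())
  vals$in_vel <- ensure_batch(vel)
  vals$in_mag <- ensure_batch(mag)
  # reference counts so that, when not taping, intermediates are freed as
  # soon as their last consumer has run (keeps full-width prediction lean)
  refs <- list()
  for (nd in model$graph)
    for (i in nd$inputs) refs[[i]] <- (refs[[i]] %||% 0L) + 1L
  last <- NULL
  for (nd in model$graph) {
    out <- switch(nd$op,
      conv = {
        p <- model$params[[nd$name]]
        y <- conv3d_fwd_cpp(vals[[nd$inputs]], p$w, p$b, nd$k)
        if (nd$act == "lrelu") act_lrelu(y) else y
      },
      lrelu = act_lrelu(vals[[nd$inputs]]),
      add = {
        y <- vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]]
        dim(y) <- dim(vals[[nd$inputs[1]]])
        y
      },
      concat = concat_channels(lapply(nd$inputs, function(i) vals[[i]])),
      slice = vals[[nd$inputs]][, , , nd$range, , drop = FALSE],
      upsample = upsample_linear(vals[[nd$inputs]], nd$f),
      stop("unknown op: ", nd$op))
    vals[[nd$name]] <- out
    if (!keep)
      for (i in nd$inputs) {
        refs[[i]] <- refs[[i]] - 1L
        if (refs[[i]] == 0L) rm(list = i, envir = vals)
      }
    last <- nd$name
  }
  list(out = vals[[last]], tape = if (keep) vals else NULL, last = last)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_backward <- function(model, tape, dout) {
  g <- new.env(parent = emptyenv())
  gadd <- function(name, val) {
    cur <- g[[name]]
    g[[name]] <- if (is.null(cur)) val else cur + val
  }
  nodes <- model$graph
  g[[nodes[[length(nodes)]]$name]] <- dout
  grads <- list()
  for (nd in rev(nodes)) {
    gy <- g[[nd$name]]
    if (is.null(gy)) next
    switch(nd$op,
      conv = {
        if (nd$act == "lrelu") gy <- lrelu_grad(tape[[nd$name]], gy)
        r <- conv3d_bwd_cpp(tape[[nd$inputs]], model$params[[nd$name]]$w,
                            gy, nd$k)
        grads[[nd$name]] <- list(w = r$dw, b = r$db)
        gadd(nd$inputs, r$dx)
      },
      lrelu = gadd(nd$inputs, lrelu_grad(tape[[nd$name]], gy)),
      add = { gadd(nd$inputs[1], gy); gadd(nd$inputs[2], gy) },
      concat = {
        at <- 0
        for (i in nd$inputs) {
          ci <- dim(tape[[i]])[4]
          gi <- gy[, , , at + seq_len(ci), , drop = FALSE]
          dim(gi) <- dim(tape[[i]])
          gadd(i, gi)
          at <- at + ci
        }
      },
      slice = {
        gx <- array(0, dim(tape[[nd$inputs]]))
        gx[, , , nd$range, ] <- gy
        gadd(nd$inputs, gx)
      },
      upsample = gadd(nd$inputs, upsample_linear_bwd(gy, nd$f)))
    rm(list = nd$name, envir = g)
  }
  grads
}

# Passthrough-biased (re-)initialisation: threads each velocity component
# through the trunk as a +/- leaky-ReLU pair via identity centre taps, so
# the network starts as an attenuated interpolating upsampler instead of
# in the input-independent basin. Off-passthrough weights keep their
# symmetric draws at reduced scale. Architecture, loss and schedule are
# untouched; intended for short training schedules, which otherwise spend
# most of their step budget discovering the input pathway.
passthrough_init <- function(model, gain = 0.5, damp = 0.25) {
  C <- model$spec$channels
  if (C < 8) stop("passthrough initialisation needs at least 8 channels")
  a <- LRELU_ALPHA
  rowidx <- function(k, c) (k^3 + 1) / 2 + k^3 * (c - 1)  # centre tap
  ident <- function(nm, pairs, k = 3) {
    w <- model$params[[nm]]$w * damp
    for (p in pairs) w[rowidx(k, p[1]), p[2]] <- p[3]
    model$params[[nm]]$w <<- w
  }
  ident("pv1", c(lapply(1:3, function(j) c(j, j, 1)),
                 lapply(1:3, function(j) c(j, j + 3, -1))))
  ident("pv2", lapply(1:6, function(j) c(j, j, 1)))
  ident("c1", lapply(1:6, function(j) c(j, j, 1)), k = 1)
  ident("c2", lapply(1:6, function(j) c(j, j, 1)))
  for (nm in names(model$params))   # damp residual branches: skip dominates
    if (grepl("_c2$", nm)) model$params[[nm]]$w <- model$params[[nm]]$w * 0.2
  for (j in 1:3) {
    ident(paste0("h", j), list(c(j, j, 1), c(j + 3, j + 3, 1)))
    ident(paste0("o", j), list(c(j, 1, gain / (1 + a)),
                               c(j + 3, 1, -gain / (1 + a))))
  }
  model
}
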