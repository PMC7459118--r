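# Minimal static-graph engine for the fully convolutional networks.
#
# A network is a DAG of nodes evaluated in construction order. Activations are
# 4-d arrays dim (H, W, C, N). Convolutions use "same" zero padding and stride
# 1; downsampling is 2x2 max pooling; upsampling is a stride-2 transposed
# convolution composed from zero-insertion followed by a stride-1 convolution.
# Backpropagation is hand-written per node type; the heavy kernels live in C++.

nn_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$add <- function(node) {
    node$id <- length(env$nodes) + 1L
    env$nodes[[node$id]] <- node
    node$id
  }
  env
}

he_uniform <- function(k, cin, cout) {
  limit <- sqrt(6 / (k * k * cin))
  array(runif(k * k * cin * cout, -limit, limit), dim = c(k, k, cin, cout))
}

nn_conv <- function(b, input, k, cin, cout, act = c("relu", "linear")) {
  act <- match.arg(act)
  b$add(list(op = "conv", inputs = input, k = k, cin = cin, cout = cout,
             act = act, W = he_uniform(k, cin, cout), b = numeric(cout)))
}

nn_upconv <- function(b, input, cin, cout, k = 3L) {
  b$add(list(op = "upconv", inputs = input, k = k, cin = cin, cout = cout,
             W = he_uniform(k, cin, cout), b = numeric(cout)))
}

nn_pool <- function(b, input) b$add(list(op = "pool", inputs = input))

nn_concat <- function(b, inputs) b$add(list(op = "concat", inputs = inputs))

nn_softmax <- function(b, input) b$add(list(op = "softmax", inputs = input))

nn_input <- function(b) b$add(list(op = "input", inputs = integer()))

concat_channels <- function(arrs) {
  d <- dim(arrs[[1]])
  cs <- vapply(arrs, function(a) dim(a)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (a in arrs) {
    ca <- dim(a)[3]
    out[, , at + seq_len(ca), ] <- a
    at <- at + ca
  }
  out
}

softmax_channels <- function(x) {
  C <- dim(x)[3]
  m <- x[, , 1, , drop = FALSE]
  if (C > 1) for (ch in 2:C) m <- pmax(m, x[, , ch, , drop = FALSE])
  e <- exp(x - m[, , rep(1L, C), , drop = FALSE])
  s <- e[, , 1, , drop = FALSE]
  if (C > 1) for (ch in 2:C) s <- s + e[, , ch, , drop = FALSE]
  e / s[, , rep(1L, C), , drop = FALSE]
}

# Forward pass. Returns the output activation plus per-node caches needed for
# backprop (activations, pooling argmaxes, zero-stuffed upconv inputs).
nn_forward <- function(net, x, keep = TRUE) {
  nodes <- net$nodes
  acts <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (nd in nodes) {
    acts[[nd$id]] <- switch(nd$op,
      input = x,
      conv = {
        y <- conv2d_fwd_cpp(acts[[nd$inputs]], nd$W, nd$b)
        if (nd$act == "relu") y[y < 0] <- 0
        y
      },
      upconv = {
        z <- upsample2_zero_cpp(acts[[nd$inputs]])
        if (keep) caches[[nd$id]] <- z
        conv2d_fwd_cpp(z, nd$W, nd$b)
      },
      pool = {
        res <- maxpool2_fwd_cpp(acts[[nd$inputs]])
        if (keep) caches[[nd$id]] <- res$idx
        res$out
      },
      concat = concat_channels(acts[nd$inputs]),
      softmax = softmax_channels(acts[[nd$inputs]]),
      stopf("unknown op '%s'", nd$op)
    )
  }
  list(out = acts[[net$output_id]], acts = acts, caches = caches)
}

# Backward pass from a gradient w.r.t. the network output. Returns per-node
# parameter gradients (NULL for parameter-free nodes).
nn_backward <- function(net, fwd, dout) {
  nodes <- net$nodes
  dacts <- vector("list", length(nodes))
  pgrads <- vector("list", length(nodes))
  dacts[[net$output_id]] <- dout
  bump <- function(id, g) {
    dacts[[id]] <<- if (is.null(dacts[[id]])) g else dacts[[id]] + g
  }
  for (nd in rev(nodes)) {
    d <- dacts[[nd$id]]
    if (is.null(d) || nd$op == "input") next
    switch(nd$op,
      conv = {
        if (nd$act == "relu") d <- d * (fwd$acts[[nd$id]] > 0)
        gf <- conv2d_bwd_filter_cpp(fwd$acts[[nd$inputs]], d, nd$k)
        pgrads[[nd$id]] <- gf
        bump(nd$inputs, conv2d_bwd_data_cpp(d, nd$W))
      },
      upconv = {
        gf <- conv2d_bwd_filter_cpp(fwd$caches[[nd$id]], d, nd$k)
        pgrads[[nd$id]] <- gf
        dz <- conv2d_bwd_data_cpp(d, nd$W)
        bump(nd$inputs, downsample2_zero_cpp(dz))
      },
      pool = {
        din <- dim(fwd$acts[[nd$inputs]])
        bump(nd$inputs, maxpool2_bwd_cpp(d, fwd$caches[[nd$id]], din[1], din[2]))
      },
      concat = {
        at <- 0L
        for (inp in nd$inputs) {
          ci <- dim(fwd$acts[[inp]])[3]
          bump(inp, d[, , at + seq_len(ci), , drop = FALSE])
          at <- at + ci
        }
      },
      softmax = {
        p <- fwd$acts[[nd$id]]
        C <- dim(p)[3]
        pd <- p * d
        s <- pd[, , 1, , drop = FALSE]
        if (C > 1) for (ch in 2:C) s <- s + pd[, , ch, , drop = FALSE]
        bump(nd$inputs, pd - p * s[, , rep(1L, C), , drop = FALSE])
      }
    )
  }
  pgrads
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(net) {
  state <- list(t = 0L, m = vector("list", length(net$nodes)),
                v = vector("list", length(net$nodes)))
  for (nd in net$nodes) {
    if (!is.null(nd$W)) {
      state$m[[nd$id]] <- list(W = array(0, dim(nd$W)), b = numeric(length(nd$b)))
      state$v[[nd$id]] <- list(W = array(0, dim(nd$W)), b = numeric(length(nd$b)))
    }
  }
  state
}

adam_step <- function(net, pgrads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nd in net$nodes) {
    g <- pgrads[[nd$id]]
    if (is.null(g)) next
    id <- nd$id
    state$m[[id]]$W <- beta1 * state$m[[id]]$W + (1 - beta1) * g$dw
    state$v[[id]]$W <- beta2 * state$v[[id]]$W + (1 - beta2) * g$dw^2
    state$m[[id]]$b <- beta1 * state$m[[id]]$b + (1 - beta1) * g$db
    state$v[[id]]$b <- beta2 * state$v[[id]]$b + (1 - beta2) * g$db^2
    net$nodes[[id]]$W <- nd$W - lr * (state$m[[id]]$W / c1) /
      (sqrt(state$v[[id]]$W / c2) + eps)
    net$nodes[[id]]$b <- nd$b - lr * (state$m[[id]]$b / c1) /
      (sqrt(state$v[[id]]$b / c2) + eps)
  }
  list(net = net, state = state)
}
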