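# Shared fixtures: tiny phantom settings, tiny network specs, and random
# mask/probability generators. Everything is built in code at test time.

tiny_phantom <- function(...) {
  args <- utils::modifyList(list(n_slices = c(10, 14), inplane_size = 64,
                                 inplane_mm = 2), list(...))
  do.call(phantom_params, args)
}

tiny_spec <- function(dense_blocks = 2, widths = c(4, 8), input_size = 8,
                      growth = 2, n_classes = 3) {
  network_spec(stage_widths = widths, dense_blocks = dense_blocks,
               growth = growth, input_size = input_size, n_classes = n_classes)
}

rand_mask <- function(nr, nc, p = 0.3, min_pixels = 1) {
  repeat {
    m <- matrix(runif(nr * nc) < p, nr, nc)
    if (sum(m) >= min_pixels) return(m)
  }
}

# A blob mask (filled disc), guaranteed non-empty and connected.
blob_mask <- function(n, cy, cx, r) {
  y <- matrix(seq_len(n), n, n)
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

rand_prob_pair <- function(dims = c(6, 6, 3, 1)) {
  logits <- array(rnorm(prod(dims)), dims)
  pred <- exp(logits)
  s <- apply(pred, c(1, 2, 4), sum)
  dim(s) <- c(dims[1], dims[2], 1, dims[4])
  pred <- pred / s[, , rep(1, dims[3]), , drop = FALSE]
  cls <- array(sample(0:(dims[3] - 1), prod(dims[-3]), replace = TRUE),
               dims[-3])
  gt <- array(0, dims)
  for (ch in seq_len(dims[3])) gt[, , ch, ] <- cls == (ch - 1)
  list(pred = pred, gt = gt)
}
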