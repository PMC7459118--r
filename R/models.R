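#' Architecture hyperparameters for the U-net family
#'
#' Describes a classical U-net (`dense_blocks = 0`) or a Dense-X U-net
#' (`dense_blocks` in 1..3). The network has `length(stage_widths)` resolution
#' levels; the last entry is the bottleneck width. Spatial size halves between
#' consecutive levels (2x2 max pooling) and is restored by stride-2 transposed
#' convolutions, so `input_size` must be divisible by
#' `2^(length(stage_widths) - 1)`.
#'
#' The default full-scale geometry is six encoder/decoder stages with feature
#' widths 16 doubling to 1024 at the bottleneck (seven levels in total), 3x3
#' kernels and a 3-class softmax head (background, central zone, peripheral
#' zone).
#'
#' Dense blocks follow the DenseNet recipe: each block holds
#' `convs_per_block` 3x3 convolutions whose input is the channel concatenation
#' of the block input and all previous layer outputs in the block, each
#' emitting `growth` feature maps; a 1x1 transition convolution then
#' compresses the concatenation back to the stage width. With
#' `growth = "auto"` the per-stage growth rate is `min(width / 8, 26)`
#' (floored at 1), the convention calibrated so that the full-scale Dense-2
#' network totals 15.6 million trainable parameters.
#'
#' @param stage_widths integer vector of per-level feature-map counts,
#'   strictly increasing, bottleneck last.
#' @param dense_blocks number of dense blocks per stage (0 = classical U-net).
#' @param convs_per_block convolutions per dense block.
#' @param growth `"auto"` or a positive number / vector (one per level) of
#'   feature maps emitted by each dense-block convolution.
#' @param kernel spatial kernel size of the stage convolutions (odd).
#' @param n_classes number of output classes (softmax channels).
#' @param input_size expected square slice size in pixels.
#' @return An object of class `NetworkSpec`.
#' @export
#' @examples
#' network_spec(stage_widths = c(8, 16), dense_blocks = 0, input_size = 16)
network_spec <- function(stage_widths = 2^(4:10), dense_blocks = 2L,
                         convs_per_block = 4L, growth = "auto", kernel = 3L,
                         n_classes = 3L, input_size = 256L) {
  if (length(stage_widths) < 2) stopf("need at least 2 stage widths")
  if (any(diff(stage_widths) <= 0)) stopf("stage widths must be strictly increasing")
  if (any(stage_widths < 1) || any(stage_widths != round(stage_widths)))
    stopf("stage widths must be positive integers")
  if (!is_count(dense_blocks, 0) || dense_blocks > 3)
    stopf("dense_blocks must be 0, 1, 2 or 3")
  if (!is_count(convs_per_block)) stopf("convs_per_block must be a positive count")
  if (!is_count(kernel) || kernel %% 2 == 0) stopf("kernel must be a positive odd count")
  if (!is_count(n_classes)) stopf("n_classes must be a positive count")
  if (!is_count(input_size)) stopf("input_size must be a positive count")
  if (input_size %% 2^(length(stage_widths) - 1) != 0)
    stopf("input_size must be divisible by 2^%d", length(stage_widths) - 1)
  if (identical(growth, "auto")) {
    gv <- pmax(1, pmin(floor(stage_widths / 8), 26))
  } else {
    if (!is.numeric(growth) || any(growth < 1) || any(growth != round(growth)))
      stopf("growth must be \"auto\" or positive integer(s)")
    gv <- if (length(growth) == 1) rep(growth, length(stage_widths)) else growth
    if (length(gv) != length(stage_widths))
      stopf("growth must have length 1 or length(stage_widths)")
  }
  structure(list(stage_widths = as.integer(stage_widths),
                 dense_blocks = as.integer(dense_blocks),
                 convs_per_block = as.integer(convs_per_block),
                 growth = as.integer(gv), kernel = as.integer(kernel),
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size)),
            class = "NetworkSpec")
}

#' @export
print.NetworkSpec <- function(x, ...) {
  kind <- if (x$dense_blocks == 0) "classical U-net" else
    sprintf("Dense-%d U-net", x$dense_blocks)
  cat(sprintf("NetworkSpec: %s\n", kind))
  cat(sprintf("  levels: %s (bottleneck %d)\n",
              paste(x$stage_widths, collapse = ", "),
              x$stage_widths[length(x$stage_widths)]))
  if (x$dense_blocks > 0)
    cat(sprintf("  growth per level: %s\n", paste(x$growth, collapse = ", ")))
  cat(sprintf("  kernel %dx%d, %d classes, input %dx%d\n", x$kernel, x$kernel,
              x$n_classes, x$input_size, x$input_size))
  invisible(x)
}

# A stage of the classical U-net: two kxk conv+ReLU at the stage width.
classical_stage <- function(b, input, cin, w, k) {
  id <- nn_conv(b, input, k, cin, w)
  nn_conv(b, id, k, w, w)
}

# A Dense-X stage: X blocks of (convs_per_block dense convolutions + 1x1
# transition back to the stage width).
dense_stage <- function(b, input, cin, w, k, nblocks, nconvs, growth) {
  cur <- input
  ccur <- cin
  for (blk in seq_len(nblocks)) {
    members <- cur        # ids whose channel concat feeds the next layer
    widths <- ccur
    for (l in seq_len(nconvs)) {
      src <- if (length(members) == 1) members else nn_concat(b, members)
      id <- nn_conv(b, src, k, sum(widths), growth)
      members <- c(members, id)
      widths <- c(widths, growth)
    }
    allc <- nn_concat(b, members)
    cur <- nn_conv(b, allc, 1L, sum(widths), w)   # transition layer
    ccur <- w
  }
  cur
}

build_unet_graph <- function(spec) {
  b <- nn_builder()
  L <- length(spec$stage_widths)
  w <- spec$stage_widths
  stage <- function(input, cin, lev) {
    if (spec$dense_blocks == 0)
      classical_stage(b, input, cin, w[lev], spec$kernel)
    else
      dense_stage(b, input, cin, w[lev], spec$kernel, spec$dense_blocks,
                  spec$convs_per_block, spec$growth[lev])
  }
  input_id <- nn_input(b)
  skips <- integer(L - 1)
  cur <- input_id
  cin <- 1L
  for (lev in seq_len(L - 1)) {
    cur <- stage(cur, cin, lev)
    skips[lev] <- cur
    cur <- nn_pool(b, cur)
    cin <- w[lev]
  }
  cur <- stage(cur, cin, L)                       # bottleneck
  for (lev in (L - 1):1) {
    up <- nn_upconv(b, cur, w[lev + 1], w[lev])
    cat_id <- nn_concat(b, c(skips[lev], up))
    cur <- stage(cat_id, 2L * w[lev], lev)
  }
  head <- nn_conv(b, cur, 1L, w[1], spec$n_classes, act = "linear")
  out <- nn_softmax(b, head)
  structure(list(spec = spec, nodes = b$nodes, input_id = input_id,
                 output_id = out),
            class = "dunet_network")
}

#' Build the classical U-net baseline
#'
#' Six-stage (at the default full scale) encoder/decoder with two 3x3 conv+ReLU per
#' stage, 2x2 max pooling, stride-2 transposed convolutions that halve the
#' feature count, long skip concatenations between mirrored stages, and a 1x1
#' convolution + pixel-wise softmax head. Weights are He-uniform initialised
#' from the current RNG state; seed with [set.seed()] for reproducible
#' initialisation.
#'
#' @param spec a [network_spec()] with `dense_blocks = 0`.
#' @return A `dunet_network` object.
#' @export
#' @examples
#' net <- build_classical_unet(network_spec(c(4, 8), dense_blocks = 0,
#'                                          input_size = 16))
#' count_parameters(net)
build_classical_unet <- function(spec) {
  stopifnot(inherits(spec, "NetworkSpec"))
  if (spec$dense_blocks != 0)
    stopf("classical U-net requires dense_blocks = 0 (got %d)", spec$dense_blocks)
  build_unet_graph(spec)
}

#' Build a Dense-X U-net
#'
#' Same macro-structure as the classical U-net, but every stage is replaced by
#' `dense_blocks` DenseNet-style blocks of four densely concatenated 3x3
#' convolutions, each followed by a 1x1 transition convolution that compresses
#' the concatenated feature maps back to the stage width.
#'
#' @param spec a [network_spec()] with `dense_blocks` in 1..3.
#' @return A `dunet_network` object.
#' @export
#' @examples
#' net <- build_dense_unet(network_spec(c(4, 8), dense_blocks = 1, growth = 2,
#'                                      input_size = 16))
#' count_parameters(net)
build_dense_unet <- function(spec) {
  stopifnot(inherits(spec, "NetworkSpec"))
  if (spec$dense_blocks < 1)
    stopf("Dense U-net requires dense_blocks >= 1")
  build_unet_graph(spec)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights and biases). The
#' networks are fully convolutional, so the count is independent of
#' `input_size`.
#'
#' @param net a `dunet_network`.
#' @return Integer-valued parameter count (double to avoid 32-bit overflow).
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "dunet_network"))
  sum(vapply(net$nodes, function(nd)
    if (is.null(nd$W)) 0 else length(nd$W) + length(nd$b), numeric(1)))
}

#' @export
print.dunet_network <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  graph nodes: %d, trainable parameters: %s\n",
              length(x$nodes), format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Segment a single slice
#'
#' Runs one normalized slice through the network and returns the per-class
#' probability maps (softmax output, summing to one at every pixel).
#'
#' @param net a `dunet_network`.
#' @param s numeric matrix of size `input_size x input_size`.
#' @return Array dim `(input_size, input_size, n_classes)` of probabilities.
#' @export
predict_slice <- function(net, s) {
  stopifnot(inherits(net, "dunet_network"))
  sz <- net$spec$input_size
  if (!is.matrix(s) || nrow(s) != sz || ncol(s) != sz)
    stopf("slice must be a %dx%d matrix", sz, sz)
  x <- array(s, c(sz, sz, 1, 1))
  p <- nn_forward(net, x, keep = FALSE)$out
  array(p, dim(p)[1:3])
}
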