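# On-the-fly augmentation of (image, mask) slice pairs. Every operation
# applies the identical geometric transform to image (bilinear) and mask
# (nearest neighbour), so the mask label alphabet can never grow. All
# randomness is seeded.

#' Elastic deformation parameters
#'
#' The elastic recipe (Simard-style): a per-pixel displacement field is drawn
#' as uniform noise in `[-1, 1]`, smoothed by a Gaussian of width `sigma`
#' pixels, then scaled by `alpha` pixels. The protocol values are
#' `sigma = 512`, `alpha = 21`; with sigma far above the slice size the
#' smoothed field is nearly constant, giving gentle, large-scale warps.
#'
#' @param sigma Gaussian smoothing width in pixels (> 0).
#' @param alpha displacement scale in pixels (>= 0); 0 disables deformation.
#' @param seed integer seed for the noise draw.
#' @return An `ElasticParams` object.
#' @export
elastic_params <- function(sigma = 512, alpha = 21, seed = 1L) {
  if (!is.numeric(sigma) || sigma <= 0) stopf("sigma must be > 0")
  if (!is.numeric(alpha) || alpha < 0) stopf("alpha must be >= 0")
  structure(list(sigma = sigma, alpha = alpha, seed = as.integer(seed)),
            class = "ElasticParams")
}

#' Rigid transform parameters
#'
#' One of the four rigid augmentation ops. Unstated magnitudes default to
#' conservative draws: rotation in ±15 degrees, zoom in [0.9, 1.1],
#' translation in ±10 px, flip along a random axis.
#'
#' @param op `"flip"`, `"rotate"`, `"zoom"` or `"translate"`.
#' @param magnitude op-specific: flip axis (`"horizontal"`/`"vertical"`),
#'   rotation degrees, zoom factor (> 0), or integer `(dy, dx)` pixel shift.
#'   `NULL` draws a random magnitude under `seed`.
#' @param seed integer seed used when drawing a random magnitude.
#' @return A `RigidParams` object.
#' @export
rigid_params <- function(op = c("flip", "rotate", "zoom", "translate"),
                         magnitude = NULL, seed = 1L) {
  op <- tryCatch(match.arg(op), error = function(e)
    stopf("unknown rigid op '%s'", paste(op, collapse = ",")))
  if (!is.null(magnitude)) {
    if (op == "zoom" && (!is.numeric(magnitude) || magnitude <= 0))
      stopf("zoom factor must be > 0")
    if (op == "translate" && length(magnitude) != 2)
      stopf("translate magnitude must be (dy, dx)")
    if (op == "flip" && !magnitude %in% c("horizontal", "vertical"))
      stopf("flip magnitude must be 'horizontal' or 'vertical'")
  }
  structure(list(op = op, magnitude = magnitude, seed = as.integer(seed)),
            class = "RigidParams")
}

warp_pair <- function(image, mask, rows, cols) {
  list(image = sample_bilinear(image, rows, cols),
       mask = sample_nearest(mask, rows, cols))
}

#' Elastic deformation of an image/mask pair
#'
#' The same displacement field warps both inputs; the image is interpolated
#' bilinearly and the mask with nearest-neighbour sampling. `alpha = 0`
#' returns the inputs unchanged; fixed seeds reproduce outputs exactly.
#'
#' @param image numeric matrix.
#' @param mask same-shaped integer label matrix.
#' @param p an [elastic_params()].
#' @return `list(image, mask)`.
#' @export
elastic_deform <- function(image, mask, p = elastic_params()) {
  stopifnot(inherits(p, "ElasticParams"))
  if (!identical(dim(image), dim(mask)))
    stopf("image and mask shapes differ")
  if (p$alpha == 0) return(list(image = image, mask = mask))
  n_r <- nrow(image); n_c <- ncol(image)
  with_seed(p$seed, {
    dx <- p$alpha * smooth_field(matrix(runif(n_r * n_c, -1, 1), n_r, n_c), p$sigma)
    dy <- p$alpha * smooth_field(matrix(runif(n_r * n_c, -1, 1), n_r, n_c), p$sigma)
  })
  rows <- matrix(seq_len(n_r), n_r, n_c) + dy
  cols <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE) + dx
  warp_pair(image, mask, rows, cols)
}

#' Rigid transformation of an image/mask pair
#'
#' Applies one of flip / rotate / zoom / translate identically to image and
#' mask; output shape is preserved (out-of-bounds samples are zero-filled).
#'
#' @inheritParams elastic_deform
#' @param p a [rigid_params()].
#' @return `list(image, mask)`.
#' @export
rigid_transform <- function(image, mask, p) {
  stopifnot(inherits(p, "RigidParams"))
  if (!identical(dim(image), dim(mask)))
    stopf("image and mask shapes differ")
  n_r <- nrow(image); n_c <- ncol(image)
  mag <- p$magnitude
  if (is.null(mag))
    mag <- with_seed(p$seed, switch(p$op,
      flip = sample(c("horizontal", "vertical"), 1),
      rotate = runif(1, -15, 15),
      zoom = runif(1, 0.9, 1.1),
      translate = round(runif(2, -10, 10))))
  if (p$op == "flip") {
    if (mag == "horizontal") {
      return(list(image = image[, n_c:1, drop = FALSE],
                  mask = mask[, n_c:1, drop = FALSE]))
    }
    return(list(image = image[n_r:1, , drop = FALSE],
                mask = mask[n_r:1, , drop = FALSE]))
  }
  r0 <- matrix(seq_len(n_r), n_r, n_c)
  c0 <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  cy <- (n_r + 1) / 2; cx <- (n_c + 1) / 2
  if (p$op == "rotate") {
    th <- mag * pi / 180
    rows <- cy + cos(th) * (r0 - cy) - sin(th) * (c0 - cx)
    cols <- cx + sin(th) * (r0 - cy) + cos(th) * (c0 - cx)
  } else if (p$op == "zoom") {
    rows <- cy + (r0 - cy) / mag
    cols <- cx + (c0 - cx) / mag
  } else { # translate by (dy, dx): content moves by +mag
    rows <- r0 - mag[1]
    cols <- c0 - mag[2]
  }
  warp_pair(image, mask, rows, cols)
}

#' Augment a batch of image/mask pairs
#'
#' Expands a list of `list(image, mask)` pairs according to the augmentation
#' mode: `"none"` passes through, `"elastic"` appends `n_elastic` (default 5)
#' random elastic variants per pair, `"rigid"` appends the four rigid ops with
#' random magnitudes, `"both"` appends both families. Deterministic under
#' `seed`.
#'
#' @param pairs list of `list(image, mask)`.
#' @param config `"none"`, `"elastic"`, `"rigid"` or `"both"`.
#' @param seed integer seed.
#' @param sigma,alpha elastic parameters.
#' @param n_elastic number of elastic variants per pair.
#' @return Augmented list of pairs (originals first).
#' @export
augment_batch <- function(pairs, config = c("none", "elastic", "rigid", "both"),
                          seed = 1L, sigma = 512, alpha = 21, n_elastic = 5L) {
  config <- tryCatch(match.arg(config), error = function(e)
    stopf("invalid augmentation config '%s'", paste(config, collapse = ",")))
  if (config == "none") return(pairs)
  seeds <- derive_seeds(seed, length(pairs))
  out <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    out[[length(out) + 1L]] <- pr
    sub <- derive_seeds(seeds[i], n_elastic + 4L)
    if (config %in% c("elastic", "both")) {
      for (j in seq_len(n_elastic))
        out[[length(out) + 1L]] <-
          elastic_deform(pr$image, pr$mask, elastic_params(sigma, alpha, sub[j]))
    }
    if (config %in% c("rigid", "both")) {
      ops <- c("flip", "rotate", "zoom", "translate")
      for (j in seq_along(ops))
        out[[length(out) + 1L]] <-
          rigid_transform(pr$image, pr$mask,
                          rigid_params(ops[j], seed = sub[n_elastic + j]))
    }
  }
  out
}
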