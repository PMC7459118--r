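# Training losses. All losses take a prediction array (probabilities after the
# softmax head) and a same-shaped ground-truth array (one-hot for multi-class
# input, plain binary masks for single-channel input). Class channels are the
# third dimension when present; channel 1 is the background class.

CLIP_EPS <- 1e-7

check_pair <- function(pred, gt) {
  if (!identical(dim2(pred), dim2(gt)))
    stopf("prediction and ground truth shapes differ (%s vs %s)",
          paste(dim2(pred), collapse = "x"), paste(dim2(gt), collapse = "x"))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

clip01 <- function(a) pmin(pmax(a, CLIP_EPS), 1 - CLIP_EPS)

#' Loss configuration
#'
#' Selects the training loss compared in the loss-ablation protocol:
#' plain cross-entropy, focal, soft Dice, or the weighted combinations
#' Dice + cross-entropy and Dice + focal + cross-entropy.
#'
#' @param kind one of `"cross_entropy"`, `"focal"`, `"dice"`, `"dice+ce"`,
#'   `"dice+focal+ce"`.
#' @param focal_alpha class-balance factor of the focal loss (> 0).
#' @param focal_gamma focusing exponent of the focal loss (>= 0); `gamma = 0`
#'   with `alpha = 1` reduces the focal loss to cross-entropy.
#' @param weights per-term weights for combination losses (recycled; all-zero
#'   is rejected).
#' @return A `LossConfig` object.
#' @export
loss_config <- function(kind = c("cross_entropy", "focal", "dice", "dice+ce",
                                 "dice+focal+ce"),
                        focal_alpha = 1, focal_gamma = 2, weights = NULL) {
  kind <- match.arg(kind)
  terms <- switch(kind,
    cross_entropy = "ce", focal = "focal", dice = "dice",
    `dice+ce` = c("dice", "ce"),
    `dice+focal+ce` = c("dice", "focal", "ce"))
  if (is.null(weights)) weights <- rep(1, length(terms))
  weights <- rep_len(weights, length(terms))
  if (any(weights < 0) || all(weights == 0))
    stopf("combination weights must be >= 0 and not all zero")
  if (focal_alpha <= 0) stopf("focal_alpha must be > 0")
  if (focal_gamma < 0) stopf("focal_gamma must be >= 0")
  structure(list(kind = kind, terms = terms, weights = weights,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma),
            class = "LossConfig")
}

#' Pixel-wise binary cross-entropy loss
#'
#' Mean over all pixels and channels of
#' `-(b * log(a) + (1 - b) * log(1 - a))`, with `a` the predicted probability
#' and `b` the ground truth. Probabilities are clipped to `[1e-7, 1 - 1e-7]`
#' before the logarithms, so a perfect confident prediction scores (numerically)
#' zero.
#'
#' @param pred array of predicted probabilities.
#' @param gt same-shaped array of 0/1 ground truth.
#' @return Scalar loss (>= 0).
#' @export
cross_entropy <- function(pred, gt) {
  check_pair(pred, gt)
  a <- clip01(pred)
  mean(-(gt * log(a) + (1 - gt) * log(1 - a)))
}

cross_entropy_grad <- function(pred, gt) {
  a <- clip01(pred)
  g <- -(gt / a - (1 - gt) / (1 - a)) / length(pred)
  g[pred < CLIP_EPS | pred > 1 - CLIP_EPS] <- 0
  array(g, dim2(pred))
}

#' Focal loss
#'
#' Cross-entropy with modulating factors that down-weight easy examples:
#' mean of `-(alpha * (1-a)^gamma * b * log(a) + a^gamma * (1-b) * log(1-a))`.
#' With `alpha = 1`, `gamma = 0` this is exactly [cross_entropy()].
#'
#' @inheritParams cross_entropy
#' @param alpha class-balance factor (> 0).
#' @param gamma focusing exponent (>= 0).
#' @return Scalar loss (>= 0).
#' @export
focal <- function(pred, gt, alpha = 1, gamma = 2) {
  check_pair(pred, gt)
  if (alpha <= 0) stopf("alpha must be > 0")
  if (gamma < 0) stopf("gamma must be >= 0")
  a <- clip01(pred)
  mean(-(alpha * (1 - a)^gamma * gt * log(a) +
           a^gamma * (1 - gt) * log(1 - a)))
}

focal_grad <- function(pred, gt, alpha = 1, gamma = 2) {
  a <- clip01(pred)
  if (gamma == 0) {
    g <- -(alpha * gt / a - (1 - gt) / (1 - a)) / length(pred)
  } else {
    t1 <- alpha * gt * (-gamma * (1 - a)^(gamma - 1) * log(a) + (1 - a)^gamma / a)
    t2 <- (1 - gt) * (gamma * a^(gamma - 1) * log(1 - a) - a^gamma / (1 - a))
    g <- -(t1 + t2) / length(pred)
  }
  g[pred < CLIP_EPS | pred > 1 - CLIP_EPS] <- 0
  array(g, dim2(pred))
}

# Identify the foreground class slabs of a prediction/target pair. For arrays
# with a class dimension (3rd) of size >= 2, channel 1 is background and is
# excluded; plain matrices/vectors are a single foreground channel.
fg_channels <- function(x) {
  d <- dim(x)
  if (!is.null(d) && length(d) >= 3 && d[3] >= 2) {
    lapply(2:d[3], function(ch) {
      idx <- rep(list(quote(expr = )), length(d))
      idx[[3]] <- ch
      do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    })
  } else list(x)
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(a*b) / (sum(a) + sum(b))` averaged over foreground classes,
#' with a small epsilon in the denominator so empty masks are handled. Equals
#' `1 - dice_score(a, b)` when `a` is a binarized mask.
#'
#' @inheritParams cross_entropy
#' @param eps denominator smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, gt, eps = 1e-7) {
  check_pair(pred, gt)
  pa <- fg_channels(pred)
  ga <- fg_channels(gt)
  d <- mapply(function(a, b) 2 * sum(a * b) / (sum(a) + sum(b) + eps), pa, ga)
  1 - mean(d)
}

dice_loss_grad <- function(pred, gt, eps = 1e-7) {
  d <- dim2(pred)
  g <- array(0, d)
  pa <- fg_channels(pred)
  ga <- fg_channels(gt)
  K <- length(pa)
  if (!is.null(dim(pred)) && length(dim(pred)) >= 3 && dim(pred)[3] >= 2) {
    for (ch in seq_len(K)) {
      a <- pa[[ch]]; b <- ga[[ch]]
      den <- sum(a) + sum(b) + eps
      idx <- rep(list(quote(expr = )), length(d))
      idx[[3]] <- ch + 1L
      grad_ch <- -(2 * b * den - 2 * sum(a * b)) / den^2 / K
      g <- do.call(`[<-`, c(list(g), idx, list(grad_ch)))
    }
  } else {
    a <- pred; b <- gt
    den <- sum(a) + sum(b) + eps
    g[] <- -(2 * b * den - 2 * sum(a * b)) / den^2
  }
  g
}

#' Combined segmentation loss
#'
#' Weighted sum of the terms selected by a [loss_config()]. With a single term
#' and weight one this equals that term exactly.
#'
#' @inheritParams cross_entropy
#' @param cfg a [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(pred, gt, cfg) {
  stopifnot(inherits(cfg, "LossConfig"))
  check_pair(pred, gt)
  vals <- vapply(cfg$terms, function(tm) switch(tm,
    ce = cross_entropy(pred, gt),
    focal = focal(pred, gt, cfg$focal_alpha, cfg$focal_gamma),
    dice = dice_loss(pred, gt)), numeric(1))
  sum(cfg$weights * vals)
}

combined_loss_grad <- function(pred, gt, cfg) {
  g <- array(0, dim2(pred))
  for (i in seq_along(cfg$terms)) {
    gi <- switch(cfg$terms[i],
      ce = cross_entropy_grad(pred, gt),
      focal = focal_grad(pred, gt, cfg$focal_alpha, cfg$focal_gamma),
      dice = dice_loss_grad(pred, gt))
    g <- g + cfg$weights[i] * gi
  }
  g
}
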