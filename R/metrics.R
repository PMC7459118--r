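# Evaluation metrics: Dice, relative absolute volume difference, Hausdorff
# and mean surface distance (mm, spacing-aware), sensitivity/specificity,
# regional apex/mid/base scoring, cohort summaries and the paired t-test.

as_mask3 <- function(m) {
  if (is.logical(m)) m <- m * 1L
  if (is.matrix(m)) dim(m) <- c(1L, dim(m))
  if (!is.array(m) || length(dim(m)) != 3)
    stopf("mask must be a matrix or 3-d array")
  m != 0
}

norm_spacing <- function(spacing, was_2d) {
  if (is.null(spacing)) return(c(1, 1, 1))
  if (length(spacing) == 2 && was_2d) return(c(1, spacing))
  if (length(spacing) == 3) return(as.numeric(spacing))
  stopf("spacing must have length 2 (2-d masks) or 3")
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks score 1 (perfect agreement on
#' absence); one empty mask scores 0.
#'
#' @param A,B binary masks (logical or 0/1 numeric) of identical shape.
#' @return Dice fraction in `[0, 1]`.
#' @export
dice_score <- function(A, B) {
  if (!identical(dim2(A), dim2(B))) stopf("mask shapes differ")
  a <- A != 0; b <- B != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Relative volume difference (percent)
#'
#' `(|B|/|A| - 1) * 100` with `A` the ground truth and `B` the prediction;
#' positive values indicate oversegmentation. Cohort summaries aggregate the
#' absolute value (MRAVD).
#'
#' @param A ground-truth mask (must be non-empty).
#' @param B predicted mask.
#' @return Signed percent difference.
#' @export
ravd <- function(A, B) {
  if (!identical(dim2(A), dim2(B))) stopf("mask shapes differ")
  sa <- sum(A != 0)
  if (sa == 0) stopf("RAVD undefined: ground-truth mask is empty")
  (sum(B != 0) / sa - 1) * 100
}

# Boundary voxels: inside the mask with at least one face neighbour outside.
# Out-of-grid counts as outside; singleton axes are skipped so 2-d masks use
# in-plane connectivity.
surface_voxels <- function(m) {
  d <- dim(m)
  surf <- array(FALSE, d)
  shifted_outside <- function(axis, dir) {
    out <- array(TRUE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (dir > 0) { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    else { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(!do.call(`[`, c(list(m), idx_src, list(drop = FALSE))))))
    out
  }
  for (axis in which(d > 1)) {
    surf <- surf | (m & shifted_outside(axis, +1)) | (m & shifted_outside(axis, -1))
  }
  if (all(d == 1)) surf <- m
  surf
}

surface_distances <- function(from, to, spacing) {
  d2 <- sedt3_cpp(array(as.integer(to), dim(to)), spacing)
  sqrt(d2[from])
}

#' Hausdorff distance (mm)
#'
#' Maximal surface-to-surface distance between two masks, spacing-aware.
#' `"directed"` (default, matching the reporting convention: prediction `A`
#' against ground truth `B`) is the maximum over A-surface voxels of the
#' distance to the nearest B-surface voxel; `"symmetric"` takes the larger of
#' the two directed values.
#'
#' @param A,B non-empty binary masks (2-d or 3-d) of identical shape.
#' @param spacing voxel spacing in mm (`(y, x)` for 2-d, `(z, y, x)` for 3-d).
#' @param mode `"directed"` or `"symmetric"`.
#' @return Distance in mm.
#' @export
hausdorff <- function(A, B, spacing = NULL, mode = c("directed", "symmetric")) {
  mode <- match.arg(mode)
  if (!identical(dim2(A), dim2(B))) stopf("mask shapes differ")
  was_2d <- is.matrix(A) || (is.array(A) && length(dim(A)) == 2)
  a <- as_mask3(A); b <- as_mask3(B)
  if (!any(a) || !any(b)) stopf("Hausdorff distance undefined for empty masks")
  sp <- norm_spacing(spacing, was_2d)
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  dab <- max(surface_distances(sa, sb, sp))
  if (mode == "directed") return(dab)
  max(dab, max(surface_distances(sb, sa, sp)))
}

#' Mean surface distance (mm)
#'
#' Symmetric mean of nearest-surface distances pooled over both mask
#' boundaries; always `<=` the symmetric Hausdorff distance.
#'
#' @inheritParams hausdorff
#' @return Distance in mm.
#' @export
mean_surface_distance <- function(A, B, spacing = NULL) {
  if (!identical(dim2(A), dim2(B))) stopf("mask shapes differ")
  was_2d <- is.matrix(A) || (is.array(A) && length(dim(A)) == 2)
  a <- as_mask3(A); b <- as_mask3(B)
  if (!any(a) || !any(b)) stopf("mean surface distance undefined for empty masks")
  sp <- norm_spacing(spacing, was_2d)
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  dab <- surface_distances(sa, sb, sp)
  dba <- surface_distances(sb, sa, sp)
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

#' Voxel-wise sensitivity and specificity
#'
#' @param A ground-truth mask.
#' @param B predicted mask.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(A, B) {
  if (!identical(dim2(A), dim2(B))) stopf("mask shapes differ")
  a <- A != 0; b <- B != 0
  tp <- sum(a & b); fn <- sum(a & !b)
  tn <- sum(!a & !b); fp <- sum(!a & b)
  if (tp + fn == 0) stopf("sensitivity undefined: no positive voxels in ground truth")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Regional (apex / mid-gland / base) whole-prostate Dice
#'
#' Splits the prostate-containing slice range of the ground truth 25/50/25
#' (boundaries at `floor(0.25 n)` and `floor(0.75 n)`; the first-index block
#' is the apex) and computes the whole-prostate Dice within each sub-stack.
#'
#' @param gt,pred [LabelVolume()]s (or integer arrays) of identical shape.
#' @return Named vector `c(apex, mid, base)`.
#' @export
regional_dice <- function(gt, pred) {
  g <- if (inherits(gt, "LabelVolume")) gt$labels else gt
  p <- if (inherits(pred, "LabelVolume")) pred$labels else pred
  if (!identical(dim(g), dim(p))) stopf("volume shapes differ")
  has <- apply(g > 0, 1, any)
  sl <- which(has)
  if (length(sl) < 4) stopf("regional Dice needs >= 4 prostate-containing slices")
  sl <- min(sl):max(sl)
  n <- length(sl)
  a <- floor(0.25 * n); b <- floor(0.75 * n)
  parts <- list(apex = sl[seq_len(a)], mid = sl[(a + 1):b],
                base = sl[(b + 1):n])
  vapply(parts, function(ix)
    dice_score(g[ix, , , drop = FALSE] > 0, p[ix, , , drop = FALSE] > 0),
    numeric(1))
}

#' Summarize per-case metrics over a cohort
#'
#' Aggregates a per-case metric table into the cohort summary statistics used
#' in the results tables: mean Dice (MDS, %), 95% CI half-width
#' (normal approximation `1.96 * sd / sqrt(n)`), standard deviation, median
#' Dice (MeDS), mean absolute RAVD (MRAVD), mean Hausdorff (MHD, mm), mean
#' surface distance (MSD, mm) and mean sensitivity/specificity (%).
#'
#' @param cases data frame with columns `dice`, `ravd`, `hausdorff`, `msd`,
#'   `sensitivity`, `specificity` and optionally `structure` (summaries are
#'   then per structure). At least 2 cases per group.
#' @return Data frame of cohort summary rows.
#' @export
summarize_cohort <- function(cases) {
  if (!is.data.frame(cases) || nrow(cases) == 0)
    stopf("cases must be a non-empty data frame")
  groups <- if ("structure" %in% names(cases)) split(cases, cases$structure)
  else list(all = cases)
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    if (nrow(g) < 2) stopf("need >= 2 cases per structure (got %d for %s)",
                           nrow(g), gname)
    dice <- g$dice
    mn <- function(x) if (is.null(x)) NA_real_ else mean(x, na.rm = TRUE)
    data.frame(
      structure = gname, n = nrow(g),
      MDS = 100 * mean(dice), CI95 = 100 * 1.96 * sd(dice) / sqrt(length(dice)),
      StD = 100 * sd(dice), MeDS = 100 * median(dice),
      MRAVD = mn(abs(g$ravd)), MHD = mn(g$hausdorff), MSD = mn(g$msd),
      Sen = 100 * mn(g$sensitivity), Spc = 100 * mn(g$specificity),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired two-sided t-test on matched per-case scores
#'
#' Cases are matched across the two models. Degenerate zero-variance
#' differences are handled explicitly: p = 1 when the two score vectors are
#' identical, p = 0 when they differ by a nonzero constant.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2).
#' @return Two-sided p-value.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stopf("score vectors must have equal length")
  if (length(scores_a) < 2) stopf("need >= 2 matched cases")
  d <- scores_a - scores_b
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  t.test(scores_a, scores_b, paired = TRUE)$p.value
}
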