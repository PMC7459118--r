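# Synthetic prostate phantoms: nested superellipse cross-sections with a
# central-zone core and a posterior-weighted peripheral-zone rim, per-slice
# apex/base taper, smooth intra-gland heterogeneity and additive noise.
# Everything is deterministic under (params, seed).

#' Phantom generator parameters
#'
#' Defaults emulate the acquisition geometry of the axial T2-weighted protocol
#' the models target: ~20 slices of 3.6 mm, 256 x 256 pixels at 0.5 mm, a
#' prostate a few cm across with a bright peripheral-zone rim (T2
#' hyperintense), a darker central gland, intra-gland heterogeneity and
#' additive noise. Optional anatomy-altering toggles (a TURP-like dark cavity,
#' a bright bladder abutting the gland) reproduce known failure modes
#' qualitatively and are off by default.
#'
#' @param n_slices integer range `(min, max)` of axial slices per case.
#' @param inplane_size square slice size in pixels.
#' @param inplane_mm in-plane pixel size in mm.
#' @param slice_mm slice thickness in mm.
#' @param radii_x_mm,radii_y_mm in-plane gland semi-axis ranges in mm
#'   (x = left-right, y = anterior-posterior).
#' @param pz_rim_fraction fraction of the gland radius occupied by the
#'   peripheral-zone rim, in (0, 1).
#' @param intensity named mean intensities for `background`, `cz`, `pz`.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param heterogeneity_scale amplitude of the smooth intra-gland intensity
#'   field (intensity units).
#' @param superellipse_exp range of the superellipse exponent (2 = ellipse).
#' @param motion_blur_prob probability that a case receives motion blur.
#' @param motion_strength blur extent in pixels when motion is applied.
#' @param turp_cavity,bladder logical failure-mode toggles.
#' @param seed default master seed for [generate_cohort()].
#' @return A `PhantomParams` object.
#' @export
phantom_params <- function(n_slices = c(14, 26), inplane_size = 256,
                           inplane_mm = 0.5, slice_mm = 3.6,
                           radii_x_mm = c(17, 26), radii_y_mm = c(13, 20),
                           pz_rim_fraction = 0.35,
                           intensity = c(background = 0.25, cz = 0.55, pz = 0.75),
                           noise_sigma = 0.05, heterogeneity_scale = 0.08,
                           superellipse_exp = c(2, 2.5),
                           motion_blur_prob = 0, motion_strength = 6,
                           turp_cavity = FALSE, bladder = FALSE, seed = 1L) {
  if (length(n_slices) != 2 || any(n_slices < 3) || n_slices[1] > n_slices[2])
    stopf("n_slices must be an increasing range with min >= 3")
  if (!is_count(inplane_size, 8)) stopf("inplane_size must be a count >= 8")
  if (inplane_mm <= 0 || slice_mm <= 0) stopf("pixel sizes must be positive")
  if (any(radii_x_mm <= 0) || any(radii_y_mm <= 0) ||
      radii_x_mm[1] > radii_x_mm[2] || radii_y_mm[1] > radii_y_mm[2])
    stopf("radius ranges must be positive and increasing")
  if (pz_rim_fraction <= 0 || pz_rim_fraction >= 1)
    stopf("pz_rim_fraction must be in (0, 1)")
  if (!all(c("background", "cz", "pz") %in% names(intensity)))
    stopf("intensity must name background, cz and pz levels")
  if (noise_sigma < 0 || heterogeneity_scale < 0)
    stopf("noise and heterogeneity scales must be >= 0")
  if (motion_blur_prob < 0 || motion_blur_prob > 1)
    stopf("motion_blur_prob must be in [0, 1]")
  if (motion_strength < 0) stopf("motion_strength must be >= 0")
  structure(list(n_slices = as.integer(n_slices), inplane_size = as.integer(inplane_size),
                 inplane_mm = inplane_mm, slice_mm = slice_mm,
                 radii_x_mm = radii_x_mm, radii_y_mm = radii_y_mm,
                 pz_rim_fraction = pz_rim_fraction, intensity = intensity,
                 noise_sigma = noise_sigma,
                 heterogeneity_scale = heterogeneity_scale,
                 superellipse_exp = superellipse_exp,
                 motion_blur_prob = motion_blur_prob,
                 motion_strength = motion_strength,
                 turp_cavity = isTRUE(turp_cavity), bladder = isTRUE(bladder),
                 seed = as.integer(seed)),
            class = "PhantomParams")
}

# Superellipse membership on the pixel grid: (|x-cx|/rx)^e + (|y-cy|/ry)^e <= 1
superellipse_mask <- function(n, cx, cy, rx, ry, e) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  (abs(x - cx) / rx)^e + (abs(y - cy) / ry)^e <= 1
}

#' Generate one synthetic case
#'
#' Builds a `(Volume, LabelVolume)` pair: a simply connected central-zone core
#' (label 1) surrounded by a posterior-weighted peripheral-zone rim (label 2),
#' tapering toward the apex and base slices, with per-class mean intensities,
#' a smooth intra-gland heterogeneity field and additive Gaussian noise. Fully
#' determined by `(p, case_seed)`.
#'
#' @param p a [phantom_params()].
#' @param case_seed integer seed for this case.
#' @param case_id identifier stored on the outputs.
#' @return `list(volume = Volume, labels = LabelVolume)`.
#' @export
generate_case <- function(p, case_seed, case_id = sprintf("case_s%d", case_seed)) {
  stopifnot(inherits(p, "PhantomParams"))
  with_seed(case_seed, {
    n <- p$inplane_size
    nz <- if (p$n_slices[1] == p$n_slices[2]) p$n_slices[1] else
      sample(p$n_slices[1]:p$n_slices[2], 1)
    rx <- runif(1, p$radii_x_mm[1], p$radii_x_mm[2]) / p$inplane_mm
    ry <- runif(1, p$radii_y_mm[1], p$radii_y_mm[2]) / p$inplane_mm
    e <- runif(1, p$superellipse_exp[1], p$superellipse_exp[2])
    cx <- n / 2 + runif(1, -0.04, 0.04) * n
    cy <- n / 2 + runif(1, -0.04, 0.04) * n
    zc <- (nz + 1) / 2
    half <- 0.58 * nz
    labels <- array(0L, c(nz, n, n))
    for (k in seq_len(nz)) {
      s <- sqrt(max(0.12, 1 - ((k - zc) / half)^2))
      gland <- superellipse_mask(n, cx, cy, rx * s, ry * s, e)
      lab <- matrix(0L, n, n)
      lab[gland] <- 2L                       # default rim
      if (s > 0.45) {
        # CZ core: shrunken superellipse shifted anteriorly (toward low y),
        # which makes the posterior rim thicker
        shrink <- 1 - p$pz_rim_fraction
        core <- superellipse_mask(n, cx, cy - 0.45 * p$pz_rim_fraction * ry * s,
                                  rx * s * shrink, ry * s * shrink, e)
        lab[gland & core] <- 1L
      }
      labels[k, , ] <- lab
    }
    img <- array(p$intensity[["background"]], c(nz, n, n))
    img[labels == 1L] <- p$intensity[["cz"]]
    img[labels == 2L] <- p$intensity[["pz"]]
    if (p$heterogeneity_scale > 0) {
      for (k in seq_len(nz)) {
        field <- smooth_field(matrix(rnorm(n * n), n, n), sigma = n / 10)
        field <- field / max(sd(as.vector(field)), 1e-12) * p$heterogeneity_scale
        sl <- img[k, , ]
        inside <- labels[k, , ] > 0
        sl[inside] <- sl[inside] + field[inside]
        img[k, , ] <- sl
      }
    }
    if (p$turp_cavity) {
      mid <- round(zc)
      for (k in max(1, mid - 1):min(nz, mid + 1)) {
        cav <- superellipse_mask(n, cx, cy - 0.2 * ry, 0.25 * rx, 0.2 * ry, 2)
        sl <- img[k, , ]
        sl[cav & labels[k, , ] == 1L] <- p$intensity[["background"]] * 0.4
        img[k, , ] <- sl
      }
    }
    if (p$bladder) {
      for (k in seq_len(nz)) {
        s <- sqrt(max(0.12, 1 - ((k - zc) / half)^2))
        bl <- superellipse_mask(n, cx, cy - ry * s - 0.55 * ry, 0.7 * rx, 0.5 * ry, 2)
        sl <- img[k, , ]
        sl[bl & labels[k, , ] == 0L] <- p$intensity[["pz"]] * 1.15
        img[k, , ] <- sl
      }
    }
    if (p$noise_sigma > 0) img <- img + rnorm(length(img), 0, p$noise_sigma)
    spacing <- c(p$slice_mm, p$inplane_mm, p$inplane_mm)
    vol <- Volume(img, spacing, case_id)
    if (p$motion_blur_prob > 0 && runif(1) < p$motion_blur_prob)
      vol <- add_motion_artifact(vol, p$motion_strength,
                                 seed = sample.int(2^30, 1))
    list(volume = vol, labels = LabelVolume(labels, spacing, case_id))
  })
}

#' Generate a cohort of synthetic cases
#'
#' Per-case seeds are derived deterministically from the master seed, so the
#' cohort is reproducible case-by-case and exhibits shape/size variability
#' across cases.
#'
#' @param p a [phantom_params()].
#' @param n_cases number of cases (>= 1).
#' @param seed master seed; defaults to `p$seed`.
#' @return List of `list(volume, labels)` pairs.
#' @export
generate_cohort <- function(p, n_cases, seed = p$seed) {
  stopifnot(inherits(p, "PhantomParams"))
  if (!is_count(n_cases)) stopf("n_cases must be >= 1")
  seeds <- derive_seeds(seed, n_cases)
  lapply(seq_len(n_cases), function(i)
    generate_case(p, seeds[i], case_id = sprintf("case_%03d", i)))
}

#' Apply a directional motion-blur artifact
#'
#' Convolves every slice with a normalized line kernel along a random
#' direction, emulating the motion artifacts that blur prostate borders.
#' Strength 0 is the identity.
#'
#' @param v a [Volume()].
#' @param strength blur half-extent in pixels (>= 0).
#' @param seed seed controlling the blur direction.
#' @return A blurred [Volume()].
#' @export
add_motion_artifact <- function(v, strength, seed = 1L) {
  stopifnot(inherits(v, "Volume"))
  if (!is.numeric(strength) || length(strength) != 1 || strength < 0)
    stopf("strength must be a single value >= 0")
  if (strength == 0) return(v)
  with_seed(seed, {
    theta <- runif(1, 0, pi)
    ts <- seq(-strength, strength, length.out = 2 * ceiling(strength) + 1)
    wts <- rep(1 / length(ts), length(ts))
    d <- dim(v$voxels)
    n_r <- d[2]; n_c <- d[3]
    rows0 <- matrix(seq_len(n_r), n_r, n_c)
    cols0 <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
    out <- v$voxels
    for (k in seq_len(d[1])) {
      sl <- v$voxels[k, , ]
      acc <- matrix(0, n_r, n_c)
      for (i in seq_along(ts)) {
        r <- pmin(pmax(rows0 + ts[i] * sin(theta), 1), n_r)
        c <- pmin(pmax(cols0 + ts[i] * cos(theta), 1), n_c)
        acc <- acc + wts[i] * sample_bilinear(sl, r, c)
      }
      out[k, , ] <- acc
    }
    Volume(out, v$spacing, v$case_id)
  })
}

#' Export a cohort to disk with a CSV manifest
#'
#' Writes one image and one mask file per case plus a `manifest.csv` with
#' columns `case_id`, `image`, `mask` (paths relative to the directory).
#'
#' @param cohort list of `list(volume, labels)` pairs.
#' @param dir output directory (created if missing).
#' @param format `"nii"`, `"nii.gz"`, `"mha"` or `"mhd"`.
#' @return Path to the manifest, invisibly.
#' @export
export_cohort <- function(cohort, dir, format = c("nii", "nii.gz", "mha", "mhd")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(cs) {
    id <- cs$volume$case_id
    img <- sprintf("%s_image.%s", id, format)
    msk <- sprintf("%s_mask.%s", id, format)
    write_volume(cs$volume, file.path(dir, img))
    write_mask(cs$labels, file.path(dir, msk))
    data.frame(case_id = id, image = img, mask = msk, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' @param manifest path to a `manifest.csv` written by [export_cohort()].
#' @return List of `list(volume, labels)` pairs.
#' @export
load_cohort <- function(manifest) {
  if (!file.exists(manifest)) stopf("manifest not found: '%s'", manifest)
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  lapply(seq_len(nrow(df)), function(i)
    list(volume = read_volume(file.path(base, df$image[i]), df$case_id[i]),
         labels = read_mask(file.path(base, df$mask[i]), df$case_id[i])))
}
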