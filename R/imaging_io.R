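# Volume containers and I/O. Axis order everywhere is (slice z, row y, col x);
# spacing is (z, y, x) in mm. NIfTI files go through RNifti; MetaImage
# (.mha/.mhd) support is a minimal uncompressed reader/writer since no
# installed package handles that format.

#' MR-like image volume
#'
#' A 3-d scalar grid with per-axis voxel spacing in mm, stored in
#' `(slice z, row y, col x)` order.
#'
#' @param voxels 3-d numeric array `(nz, ny, nx)` of finite intensities.
#' @param spacing numeric length-3 `(z, y, x)` spacing in mm, all > 0.
#' @param case_id case identifier string.
#' @return A `Volume` object.
#' @export
Volume <- function(voxels, spacing, case_id = "case") {
  if (!is.array(voxels) || length(dim(voxels)) != 3 || any(dim(voxels) < 1))
    stopf("voxels must be a non-empty 3-d array")
  if (!all(is.finite(voxels))) stopf("voxel intensities must be finite")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite values (z, y, x)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 case_id = as.character(case_id)), class = "Volume")
}

#' Integer label volume
#'
#' Labels aligned 1:1 with a [Volume()]: 0 = background, 1 = central zone,
#' 2 = peripheral zone. The whole-prostate mask is the union of labels 1 and 2.
#'
#' @param labels 3-d array of integer values in `{0, 1, 2}`.
#' @inheritParams Volume
#' @return A `LabelVolume` object.
#' @export
LabelVolume <- function(labels, spacing, case_id = "case") {
  if (!is.array(labels) || length(dim(labels)) != 3 || any(dim(labels) < 1))
    stopf("labels must be a non-empty 3-d array")
  if (any(labels != round(labels)) || any(labels < 0) || any(labels > 2))
    stopf("labels must be integers in {0, 1, 2}")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite values (z, y, x)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 case_id = as.character(case_id)), class = "LabelVolume")
}

#' @export
print.Volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Volume '%s': %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g mm\n",
              x$case_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "LabelVolume '%s': %d x %d x %d (z,y,x), labels {%s}, spacing %.3g/%.3g/%.3g mm\n",
    x$case_id, d[1], d[2], d[3],
    paste(sort(unique(as.vector(x$labels))), collapse = ","),
    x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

file_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.mha$", lp)) "mha"
  else if (grepl("\\.mhd$", lp)) "mhd"
  else stopf("unsupported volume format: '%s' (expected .nii, .nii.gz, .mha or .mhd)",
             basename(path))
}

# ---- MetaImage ----

mha_type <- c(MET_UCHAR = "integer", MET_CHAR = "integer", MET_SHORT = "integer",
              MET_USHORT = "integer", MET_INT = "integer", MET_UINT = "integer",
              MET_FLOAT = "double", MET_DOUBLE = "double")
mha_size <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
              MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_meta_image <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, 1, warn = FALSE)
    if (length(line) == 0) stopf("truncated MetaImage header in '%s'", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("malformed MetaImage header line: '%s'", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3")) stopf("only 3-d MetaImage volumes are supported")
  if (identical(hdr$CompressedData, "True")) stopf("compressed MetaImage not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])   # (nx, ny, nz)
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  et <- hdr$ElementType
  if (is.na(mha_size[et])) stopf("unsupported MetaImage element type '%s'", et)
  swap <- identical(hdr$ElementByteOrderMSB, "True") ||
    identical(hdr$BinaryDataByteOrderMSB, "True")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  signed <- !et %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(raw_con, what = mha_type[[et]], n = n, size = mha_size[[et]],
                  signed = if (mha_size[[et]] < 4) signed else TRUE,
                  endian = if (swap) "big" else "little")
  if (length(vals) != n) stopf("MetaImage data shorter than DimSize in '%s'", path)
  arr <- aperm(array(vals, dim = dims), c(3, 2, 1))   # (nz, ny, nx)
  list(voxels = arr, spacing = rev(sp), integer = mha_type[[et]] == "integer")
}

write_meta_image <- function(arr, spacing, path, element_type) {
  fmt <- file_format(path)
  d <- dim(arr)                                      # (nz, ny, nx)
  data_file <- if (fmt == "mha") "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   spacing[3], spacing[2], spacing[1]),
           sprintf("ElementType = %s", element_type),
           sprintf("ElementDataFile = %s", data_file))
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (fmt == "mha") {
    writeBin(vals, con, size = mha_size[[element_type]])
  } else {
    rcon <- file(file.path(dirname(path), data_file), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(vals, rcon, size = mha_size[[element_type]])
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- public I/O ----

#' Read an image volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or uncompressed MetaImage (`.mha`, `.mhd`)
#' files; voxel spacing is taken from the header and intensities are returned
#' unmodified.
#'
#' @param path file path.
#' @param case_id case identifier; defaults to the file base name.
#' @return A [Volume()].
#' @export
read_volume <- function(path, case_id = NULL) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  fmt <- file_format(path)
  case_id <- case_id %||% sub("\\.(nii(\\.gz)?|mha|mhd)$", "", basename(path),
                              ignore.case = TRUE)
  if (fmt == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stopf("not a readable NIfTI file: '%s' (%s)",
                                              path, conditionMessage(e)))
    arr <- as.array(img)
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3) stopf("expected a 3-d NIfTI volume")
    sp <- rev(RNifti::pixdim(img)[1:3])
    vox <- aperm(arr, c(3, 2, 1))
  } else {
    mi <- tryCatch(read_meta_image(path),
                   error = function(e) stopf("not a readable MetaImage file: '%s' (%s)",
                                             path, conditionMessage(e)))
    vox <- mi$voxels
    sp <- mi$spacing
  }
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("non-positive voxel spacing in header of '%s'", path)
  storage.mode(vox) <- "double"
  Volume(vox, sp, case_id)
}

#' Read a label volume
#'
#' As [read_volume()] but validates that the voxel values are integer labels
#' in `{0, 1, 2}`.
#'
#' @inheritParams read_volume
#' @return A [LabelVolume()].
#' @export
read_mask <- function(path, case_id = NULL) {
  v <- read_volume(path, case_id)
  LabelVolume(v$voxels, v$spacing, v$case_id)
}

#' Write an image volume
#'
#' Writes in the format implied by the file extension. NIfTI images are stored
#' as float64 so write/read round-trips are lossless.
#'
#' @param v a [Volume()].
#' @param path destination (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @return The path, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "Volume"))
  fmt <- file_format(path)
  if (fmt == "nifti") {
    arr <- aperm(v$voxels, c(3, 2, 1))
    attr(arr, "pixdim") <- rev(v$spacing)
    RNifti::writeNifti(arr, path, datatype = "double")
  } else {
    write_meta_image(v$voxels, v$spacing, path, "MET_DOUBLE")
  }
  invisible(path)
}

#' Write a label volume
#'
#' Stores masks with an integer element type so labels round-trip exactly.
#' Float-valued input is rejected.
#'
#' @param m a [LabelVolume()] (or an integer-valued Volume).
#' @param path destination (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @return The path, invisibly.
#' @export
write_mask <- function(m, path) {
  if (inherits(m, "Volume")) {
    if (any(m$voxels != round(m$voxels)))
      stopf("mask voxels must be integer-valued")
    m <- LabelVolume(m$voxels, m$spacing, m$case_id)
  }
  stopifnot(inherits(m, "LabelVolume"))
  fmt <- file_format(path)
  if (fmt == "nifti") {
    arr <- aperm(m$labels, c(3, 2, 1))
    storage.mode(arr) <- "integer"
    attr(arr, "pixdim") <- rev(m$spacing)
    RNifti::writeNifti(arr, path, datatype = "int16")
  } else {
    write_meta_image(m$labels, m$spacing, path, "MET_SHORT")
  }
  invisible(path)
}

# ---- preprocessing ----

resample_grid <- function(n_in, n_out, sp_in, sp_out) {
  # output pixel centre j (1-based) sits at physical (j - 0.5) * sp_out;
  # map back into input pixel coordinates
  (seq_len(n_out) - 0.5) * (sp_out / sp_in) + 0.5
}

#' Resample to a common in-plane resolution
#'
#' Resamples every axial slice to `target` mm pixels (default 0.5 mm, the
#' common resolution of the training protocol). Slice count and slice spacing
#' are unchanged. Image volumes are interpolated bilinearly, label volumes with
#' nearest-neighbour sampling so the label alphabet is preserved.
#'
#' @param v a [Volume()] or [LabelVolume()].
#' @param target in-plane pixel size in mm (> 0).
#' @return The resampled object of the same class.
#' @export
resample_inplane <- function(v, target = 0.5) {
  if (!is.numeric(target) || length(target) != 1 || !is.finite(target) || target <= 0)
    stopf("target spacing must be a single positive number")
  UseMethod("resample_inplane")
}

resample_core <- function(arr, spacing, target, sampler) {
  d <- dim(arr)
  if (spacing[2] == target && spacing[3] == target) return(arr)
  ny <- max(1L, as.integer(round(d[2] * spacing[2] / target)))
  nx <- max(1L, as.integer(round(d[3] * spacing[3] / target)))
  ry <- resample_grid(d[2], ny, spacing[2], target)
  rx <- resample_grid(d[3], nx, spacing[3], target)
  rows <- matrix(ry, ny, nx)
  cols <- matrix(rx, ny, nx, byrow = TRUE)
  out <- array(0, c(d[1], ny, nx))
  for (k in seq_len(d[1])) out[k, , ] <- sampler(arr[k, , ], rows, cols)
  out
}

#' @export
resample_inplane.Volume <- function(v, target = 0.5) {
  # clamp sampling to the grid so border pixels replicate instead of fading
  sampler <- function(img, r, c)
    sample_bilinear(img, pmin(pmax(r, 1), nrow(img)), pmin(pmax(c, 1), ncol(img)))
  Volume(resample_core(v$voxels, v$spacing, target, sampler),
         c(v$spacing[1], target, target), v$case_id)
}

#' @export
resample_inplane.LabelVolume <- function(v, target = 0.5) {
  sampler <- function(img, r, c)
    sample_nearest(img, pmin(pmax(r, 1), nrow(img)), pmin(pmax(c, 1), ncol(img)))
  out <- resample_core(v$labels, v$spacing, target, sampler)
  LabelVolume(out, c(v$spacing[1], target, target), v$case_id)
}

crop_axis <- function(n, size) {
  # returns source index range and destination offset for one axis
  if (n >= size) {
    off <- floor((n - size) / 2)
    list(src = (off + 1):(off + size), dst = seq_len(size))
  } else {
    off <- floor((size - n) / 2)
    list(src = seq_len(n), dst = (off + 1):(off + n))
  }
}

#' Centered in-plane crop (with symmetric zero padding)
#'
#' Crops every slice to `size x size` pixels with the window centred on the
#' slice (ties broken toward the lower index). Inputs smaller than the window
#' are symmetrically zero-padded.
#'
#' @param v a [Volume()] or [LabelVolume()].
#' @param size window size in pixels (default 256).
#' @return Object of the same class with in-plane dims `size x size`.
#' @export
center_crop <- function(v, size = 256) {
  if (!is_count(size)) stopf("crop size must be a positive count")
  arr <- if (inherits(v, "Volume")) v$voxels else if (inherits(v, "LabelVolume"))
    v$labels else stopf("center_crop expects a Volume or LabelVolume")
  d <- dim(arr)
  ay <- crop_axis(d[2], size)
  ax <- crop_axis(d[3], size)
  out <- array(if (is.integer(arr)) 0L else 0, c(d[1], size, size))
  out[, ay$dst, ax$dst] <- arr[, ay$src, ax$src, drop = FALSE]
  if (inherits(v, "Volume")) Volume(out, v$spacing, v$case_id)
  else LabelVolume(out, v$spacing, v$case_id)
}

#' Per-slice intensity normalization
#'
#' Z-scores one slice to zero mean and unit (sample) standard deviation, the
#' on-the-fly normalization applied before every network input. A constant
#' slice maps to all zeros.
#'
#' @param s numeric matrix.
#' @return Matrix of the same size.
#' @export
normalize_slice <- function(s) {
  if (!is.matrix(s) || !all(is.finite(s))) stopf("slice must be a finite numeric matrix")
  sdv <- sd(as.vector(s))
  if (sdv == 0) return(array(0, dim(s)))
  (s - mean(s)) / sdv
}

#' Export one slice as PNG (visualization helper)
#'
#' @param v a [Volume()] or [LabelVolume()].
#' @param slice slice index.
#' @param path output `.png` path.
#' @return The path, invisibly.
#' @export
export_slice_png <- function(v, slice, path) {
  arr <- if (inherits(v, "Volume")) v$voxels else v$labels
  s <- arr[slice, , ]
  rng <- range(s)
  img <- if (diff(rng) == 0) array(0, dim(s)) else (s - rng[1]) / diff(rng)
  png::writePNG(img, path)
  invisible(path)
}
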