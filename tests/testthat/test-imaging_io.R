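test_that("volumes round-trip losslessly through NIfTI and MetaImage", {
  set.seed(101)
  cs <- generate_case(tiny_phantom(n_slices = c(6, 6)), 101)
  for (ext in c("nii", "nii.gz", "mha", "mhd")) {
    f <- file.path(tempdir(), paste0("rt_vol.", ext))
    write_volume(cs$volume, f)
    back <- read_volume(f)
    expect_identical(back$voxels, cs$volume$voxels, label = ext)
    expect_equal(back$spacing, cs$volume$spacing, tolerance = 1e-6)
    fm <- file.path(tempdir(), paste0("rt_mask.", ext))
    write_mask(cs$labels, fm)
    mback <- read_mask(fm)
    expect_identical(mback$labels, cs$labels$labels, label = ext)
    expect_setequal(unique(as.vector(mback$labels)), c(0L, 1L, 2L))
  }
})

test_that("header spacing is honoured and invalid inputs are rejected", {
  v <- Volume(array(rnorm(4 * 8 * 8), c(4, 8, 8)), c(3.6, 0.5, 0.5), "sp")
  f <- file.path(tempdir(), "spacing.nii.gz")
  write_volume(v, f)
  expect_equal(read_volume(f)$spacing, c(3.6, 0.5, 0.5), tolerance = 1e-6)

  txt <- file.path(tempdir(), "notavolume.txt")
  writeLines("hello", txt)
  expect_error(read_volume(txt), "unsupported")
  bad <- file.path(tempdir(), "bad.mha")
  writeLines("this is not a metaimage header", bad)
  expect_error(read_volume(bad), "not a readable")
  expect_error(read_volume(file.path(tempdir(), "missing.nii")), "not found")

  # float-typed data is not a mask
  fv <- Volume(array(0.5, c(2, 4, 4)), c(1, 1, 1))
  expect_error(write_mask(fv, file.path(tempdir(), "f.nii")), "integer")
  expect_error(Volume(array(1, c(2, 2, 2)), c(0, 1, 1)), "spacing")
  expect_error(LabelVolume(array(3L, c(2, 2, 2)), c(1, 1, 1)), "labels")
})

test_that("in-plane resampling follows size = round(n * old / new) and is idempotent", {
  v <- Volume(array(rnorm(3 * 128 * 128), c(3, 128, 128)), c(3.6, 1, 1))
  r <- resample_inplane(v, 0.5)
  expect_equal(dim(r$voxels), c(3, 256, 256))
  expect_equal(r$spacing, c(3.6, 0.5, 0.5))
  # already at target: bit-identical no-op
  v2 <- Volume(array(rnorm(2 * 32 * 32), c(2, 32, 32)), c(3.6, 0.5, 0.5))
  expect_identical(resample_inplane(v2, 0.5)$voxels, v2$voxels)
  # idempotence to interpolation tolerance
  rr <- resample_inplane(r, 0.5)
  expect_identical(rr$voxels, r$voxels)
  expect_error(resample_inplane(v, -1), "positive")

  # labels: nearest neighbour preserves the alphabet
  lab <- LabelVolume(array(sample(0:2, 3 * 40 * 40, TRUE), c(3, 40, 40)), c(3.6, 1, 1))
  rl <- resample_inplane(lab, 0.5)
  expect_equal(dim(rl$labels), c(3, 80, 80))
  expect_true(all(rl$labels %in% 0:2))
  expect_true(is.integer(rl$labels))
})

test_that("center crop uses floor((n - size)/2) offsets, pads small inputs, and is idempotent", {
  arr <- array(0, c(2, 300, 300))
  arr[1, , ] <- matrix(seq_len(300), 300, 300)        # value = row index
  v <- Volume(arr, c(3.6, 0.5, 0.5))
  cr <- center_crop(v, 256)
  expect_equal(dim(cr$voxels), c(2, 256, 256))
  expect_equal(cr$voxels[1, 1, 1], 23)                 # offset floor(44/2) = 22
  expect_equal(cr$voxels[1, 256, 1], 278)
  # identity when already at size
  v2 <- Volume(array(rnorm(2 * 256 * 256), c(2, 256, 256)), c(3.6, 0.5, 0.5))
  expect_identical(center_crop(v2, 256)$voxels, v2$voxels)
  # pad-then-crop for small inputs
  sm <- Volume(array(1, c(2, 200, 200)), c(3.6, 0.5, 0.5))
  pc <- center_crop(sm, 256)
  expect_equal(dim(pc$voxels), c(2, 256, 256))
  expect_equal(sum(pc$voxels), 2 * 200 * 200)
  expect_equal(pc$voxels[1, 28, 28], 0)
  expect_equal(pc$voxels[1, 29, 29], 1)
  # idempotent
  expect_identical(center_crop(cr, 256)$voxels, cr$voxels)
  expect_error(center_crop(v, 0), "positive")
})

test_that("slice normalization is a per-slice z-score, safe on constants, affine-invariant", {
  set.seed(7)
  s <- matrix(rnorm(32 * 32, 5, 3), 32, 32)
  z <- normalize_slice(s)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(as.vector(z)) - 1), 1e-6)
  expect_identical(normalize_slice(matrix(0, 8, 8)), array(0, c(8, 8)))
  expect_identical(normalize_slice(matrix(4.2, 8, 8)), array(0, c(8, 8)))
  z2 <- normalize_slice(2.5 * s + 11)
  expect_lt(max(abs(z - z2)), 1e-9)
})

test_that("png slice export writes a readable file", {
  cs <- generate_case(tiny_phantom(n_slices = c(6, 6)), 5)
  f <- file.path(tempdir(), "slice.png")
  export_slice_png(cs$volume, 3, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
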