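test_that("phantom cases are deterministic and labels partition correctly", {
  p <- tiny_phantom()
  a <- generate_case(p, 42)
  b <- generate_case(p, 42)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$labels$labels, b$labels$labels)

  lab <- a$labels$labels
  cz <- lab == 1L; pz <- lab == 2L
  expect_false(any(cz & pz))
  expect_identical((cz | pz), lab > 0L)
  expect_true(all(lab %in% 0:2))
})

test_that("prostate tapers toward apex/base and the background dominates", {
  p <- tiny_phantom()
  for (s in derive_seeds(2024, 50)) {
    lab <- generate_case(p, s)$labels$labels
    nz <- dim(lab)[1]
    per_slice <- apply(lab > 0, 1, sum)
    mid <- per_slice[ceiling(nz / 2)]
    expect_gt(mid, per_slice[1])
    expect_gt(mid, per_slice[nz])
    expect_gte(mean(lab == 0L), 0.9)
  }
})

test_that("cohorts vary across cases and master seeds, and are reproducible", {
  p <- tiny_phantom()
  co <- generate_cohort(p, 12, seed = 7)
  expect_length(co, 12)
  vols <- vapply(co, function(cs) sum(cs$labels$labels > 0) *
                   prod(cs$labels$spacing), numeric(1))
  expect_gt(sd(vols) / mean(vols), 0.1)          # shape/size variability
  co2 <- generate_cohort(p, 12, seed = 7)
  expect_identical(co[[5]]$volume$voxels, co2[[5]]$volume$voxels)
  co3 <- generate_cohort(p, 12, seed = 8)
  vols3 <- vapply(co3, function(cs) sum(cs$labels$labels > 0) *
                    prod(cs$labels$spacing), numeric(1))
  expect_false(isTRUE(all.equal(vols, vols3)))
  # single-case cohort equals generate_case at the derived seed
  one <- generate_cohort(p, 1, seed = 3)
  direct <- generate_case(p, derive_seeds(3, 1)[1])
  expect_identical(one[[1]]$volume$voxels, direct$volume$voxels)
  expect_error(generate_cohort(p, 0), "n_cases")
})

test_that("motion blur is seeded, identity at zero strength, intensity-conserving", {
  cs <- generate_case(tiny_phantom(n_slices = c(8, 8)), 9)
  v <- cs$volume
  expect_identical(add_motion_artifact(v, 0)$voxels, v$voxels)
  b1 <- add_motion_artifact(v, 4, seed = 21)
  b2 <- add_motion_artifact(v, 4, seed = 21)
  expect_identical(b1$voxels, b2$voxels)
  expect_false(identical(b1$voxels, v$voxels))
  for (k in seq_len(dim(v$voxels)[1])) {
    s0 <- sum(v$voxels[k, , ]); s1 <- sum(b1$voxels[k, , ])
    expect_lt(abs(s1 - s0) / abs(s0), 0.01)
  }
  expect_error(add_motion_artifact(v, -1), ">= 0")
})

test_that("failure-mode toggles alter intensities but not the label partition", {
  p <- tiny_phantom(turp_cavity = TRUE, bladder = TRUE)
  cs <- generate_case(p, 77)
  base <- generate_case(tiny_phantom(), 77)
  expect_identical(cs$labels$labels, base$labels$labels)
  expect_false(identical(cs$volume$voxels, base$volume$voxels))
})

test_that("cohort export writes image+mask per case and a loadable manifest", {
  p <- tiny_phantom(n_slices = c(5, 5), inplane_size = 32)
  co <- generate_cohort(p, 4, seed = 13)
  dir <- file.path(tempdir(), "cohort_export")
  unlink(dir, recursive = TRUE)
  manifest <- export_cohort(co, dir, format = "nii.gz")
  df <- read.csv(manifest)
  expect_equal(nrow(df), 4)
  expect_length(list.files(dir, pattern = "\\.nii\\.gz$"), 8)
  back <- load_cohort(manifest)
  expect_identical(back[[2]]$volume$voxels, co[[2]]$volume$voxels)
  expect_identical(back[[2]]$labels$labels, co[[2]]$labels$labels)
  # re-export is byte-stable for the mask files
  dir2 <- file.path(tempdir(), "cohort_export2")
  unlink(dir2, recursive = TRUE)
  export_cohort(generate_cohort(p, 4, seed = 13), dir2, format = "mha")
  export_cohort(co, file.path(tempdir(), "cohort_export3"), format = "mha")
  f1 <- file.path(dir2, "case_002_mask.mha")
  f2 <- file.path(tempdir(), "cohort_export3", "case_002_mask.mha")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
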