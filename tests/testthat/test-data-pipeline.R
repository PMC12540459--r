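test_that("NIfTI volumes round-trip grid, spacing and mask values", {
  set.seed(26)
  v <- volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)), c(1, 1.5, 2))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(v, f)
  back <- read_nifti_volume(f, reorient = FALSE)
  expect_equal(back$values, v$values, tolerance = 1e-6)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)

  m <- volume(array(as.integer(runif(6 * 7 * 8) > 0.7), c(6, 7, 8)))
  fm <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(m, fm)
  backm <- read_nifti_volume(fm, reorient = FALSE)
  expect_identical(array(as.integer(backm$values), dim(m$values)), m$values)
  expect_error(read_nifti_volume(tempfile(fileext = ".nii")), "no such file")
})

test_that("preprocessing crops, z-scores and pads to the fixed grid", {
  set.seed(28)
  sp <- synthetic_params(shape = c(40L, 40L, 40L), seed = 7L,
                         semi_axes_range = c(3, 5))
  case <- generate_synthetic_case(sp, "pp1")
  cfg <- preprocess_config(target_shape = c(48L, 48L, 48L))
  pp <- preprocess_case(case, cfg)
  expect_equal(dim(pp$tensor), c(3L, 48L, 48L, 48L))
  expect_equal(pp$modalities, c("t1", "flair", "pet"))
  # foreground z-score: mean ~ 0, sd ~ 1 on nonzero voxels of each modality
  for (i in 1:3) {
    a <- pp$tensor[i, , , ]
    fg <- a != 0
    expect_lt(abs(mean(a[fg])), 1e-5)
    expect_lt(abs(sd(a[fg]) - 1), 1e-2)
  }
  # identity spacing, no resampling: mask voxel count preserved
  expect_equal(sum(pp$mask), sum(case$mask$values))
  expect_error(preprocess_case(list(volumes = list()), cfg), "t1")
})

test_that("predictions map back to the native grid nearly losslessly", {
  set.seed(29)
  sp <- synthetic_params(shape = c(40L, 40L, 40L), seed = 8L,
                         semi_axes_range = c(3, 5))
  case <- generate_synthetic_case(sp, "pp2")
  cfg <- preprocess_config(target_shape = c(48L, 48L, 48L))
  pp <- preprocess_case(case, cfg)
  native <- postprocess_to_native(pp$mask, pp$inverse)
  expect_equal(dim(native), dim(case$mask$values))
  inter <- sum(native & case$mask$values)
  expect_gte(inter / sum(case$mask$values), 0.99)
})

test_that("the synthetic generator is seed-deterministic with lesions inside the head", {
  sp <- synthetic_params(shape = c(32L, 32L, 32L), seed = 5L,
                         semi_axes_range = c(3, 5))
  c1 <- generate_synthetic_case(sp, "s1")
  c2 <- generate_synthetic_case(sp, "s1")
  expect_identical(c1$volumes$t1$values, c2$volumes$t1$values)
  expect_identical(c1$mask$values, c2$mask$values)
  gt <- c1$mask$values
  expect_gt(sum(gt), 0)
  head <- c1$volumes$t1$values != 0
  expect_true(all(head[gt == 1]))
  # lesion volume stays a small fraction of the head analog
  expect_lt(sum(gt) / sum(head), 0.02)
})

test_that("injected contrast is recoverable by thresholding the FLAIR analog", {
  recov_dc <- function(contrast, seed) {
    sp <- synthetic_params(shape = c(32L, 32L, 32L), seed = seed,
                           semi_axes_range = c(3, 5),
                           contrasts = c(t1 = -0.15, flair = contrast, pet = -0.3))
    cs <- generate_synthetic_case(sp, "thr")
    fl <- cs$volumes$flair$values
    head <- fl != 0
    thr <- mean(fl[head]) + contrast / 2
    rec <- array(as.integer(fl > thr & head), dim(fl))
    overlap_metrics(cs$mask$values, rec)$DC
  }
  expect_gt(recov_dc(0.35, 11L), 0.5)
  # contrast monotonicity: doubling contrast cannot hurt recovery
  expect_gte(recov_dc(0.7, 11L) + 1e-9, recov_dc(0.35, 11L))
})

test_that("cross-validation folds partition the cases nearly equally", {
  ids <- sprintf("c%02d", 1:13)
  f <- make_cv_folds(ids, k = 5, seed = 2)
  expect_setequal(names(f), ids)
  expect_true(all(f %in% 1:5))
  sz <- table(f)
  expect_lte(max(sz) - min(sz), 1)
  expect_identical(f, make_cv_folds(ids, k = 5, seed = 2))
  expect_false(identical(f, make_cv_folds(ids, k = 5, seed = 3)))
  expect_error(make_cv_folds(ids[1:3], k = 5), "exceed")
})

test_that("cases and manifests round-trip through the dataset layout", {
  td <- tempfile(); dir.create(td)
  sp <- synthetic_params(shape = c(32L, 32L, 32L), seed = 3L,
                         semi_axes_range = c(3, 5))
  case <- generate_synthetic_case(sp, "case_a")
  write_case(case, td)
  write_manifest(td, "case_a")
  man <- read_manifest(td)
  expect_equal(man$cases, "case_a")
  back <- read_case(td, "case_a")
  expect_equal(back$volumes$t1$values, case$volumes$t1$values, tolerance = 1e-6)
  expect_identical(array(as.integer(back$mask$values), dim(case$mask$values)),
                   case$mask$values)
})
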