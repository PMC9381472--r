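test_that("FWHM to SD conversion and identity kernel behave", {
  expect_equal(fwhm_to_sigma(4), 4 / 2.3548, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(4), 1.6986, tolerance = 1e-4)

  withr::local_seed(8)
  m <- scalar_map(array(rnorm(16 * 16 * 8, 100, 5), c(16, 16, 8)), c(2, 2, 2))
  expect_identical(smooth_gaussian(m, 0)$data, m$data)
  expect_error(smooth_gaussian(m, -1), "non-negative")
})

test_that("smoothing preserves constants and never invents valid voxels", {
  arr <- array(42, c(12, 12, 8))
  arr[3:5, 3:5, 3:5] <- NA
  m <- scalar_map(arr, c(2, 2, 2))
  sm <- smooth_gaussian(m, 6)
  expect_identical(is.na(sm$data), is.na(arr))
  expect_equal(sm$data[!is.na(arr)], rep(42, sum(!is.na(arr))),
               tolerance = 1e-12)
})

test_that("smoothing reduces noise variance but keeps the mean", {
  withr::local_seed(12)
  m <- scalar_map(array(rnorm(24 * 24 * 12, 100, 10), c(24, 24, 12)), c(2, 2, 2))
  sm <- smooth_gaussian(m, 8)
  expect_lt(sd(sm$data), sd(m$data) / 2)
  expect_equal(mean(sm$data), mean(m$data), tolerance = 0.5)
})

test_that("the normative model is the per-voxel sample mean and SD", {
  a <- scalar_map(array(1, c(4, 4, 4)))
  b <- scalar_map(array(3, c(4, 4, 4)))
  model <- build_normative_model(list(a, b), fwhm = 0)
  expect_equal(as.vector(model$mean_map$data), rep(2, 64))
  expect_equal(as.vector(model$sd_map$data), rep(sqrt(2), 64))

  same <- build_normative_model(list(a, a, a), fwhm = 0)
  expect_equal(as.vector(same$sd_map$data), rep(0, 64))

  expect_error(build_normative_model(list(a), fwhm = 0), "2 control")
  c_small <- scalar_map(array(1, c(2, 2, 2)))
  expect_error(build_normative_model(list(a, c_small), fwhm = 0), "grid")
})

test_that("model validity is the intersection of control validity", {
  arr1 <- array(1, c(4, 4, 4))
  arr2 <- array(3, c(4, 4, 4))
  arr2[1, 1, 1] <- NA
  model <- build_normative_model(
    list(scalar_map(arr1), scalar_map(arr2)), fwhm = 0
  )
  expect_true(is.na(model$mean_map$data[1, 1, 1]))
  expect_equal(sum(is.finite(model$mean_map$data)), 63L)
})

test_that("a simulated control cohort reproduces the control hippocampal T2", {
  cfg <- test_phantom_config(noise = 0.02)
  cohort <- generate_control_cohort(cfg, n = 24, seed = 41, render = TRUE)
  maps <- lapply(cohort$subjects, function(s) {
    apply_csf_threshold(fit_t2_volume(s$multi_echo, s$brain_mask))
  })
  model <- build_normative_model(maps, fwhm = 4)
  labels <- phantom_labels(cfg)
  left_er <- erode_mask(labels == 1L)
  expect_lt(abs(extract_roi_mean(model$mean_map, left_er) - 110.40), 2)
})

test_that("z-score maps standardise against the model", {
  withr::local_seed(19)
  controls <- lapply(1:6, function(i) {
    scalar_map(array(rnorm(8 * 8 * 4, 110, 3), c(8, 8, 4)))
  })
  model <- build_normative_model(controls, fwhm = 0)
  z0 <- zscore_map(model$mean_map, model)
  expect_true(all(abs(z0$data) < 1e-12, na.rm = TRUE))

  # single-voxel hand arithmetic at control-magnitude values
  one <- scalar_map(array(121.81, c(1, 1, 1)))
  mod1 <- structure(list(
    mean_map = scalar_map(array(110.40, c(1, 1, 1))),
    sd_map = scalar_map(array(3.11, c(1, 1, 1))),
    n_controls = 24L, modality = "T2", smoothing_fwhm = 0
  ), class = "normative_model")
  expect_equal(zscore_map(one, mod1)$data[1, 1, 1], 3.669, tolerance = 1e-3)
})

test_that("controls z-scored against their own model have mean 0 and SD 1", {
  withr::local_seed(23)
  controls <- lapply(1:8, function(i) {
    scalar_map(array(rnorm(6 * 6 * 4, 110, 3), c(6, 6, 4)))
  })
  model <- build_normative_model(controls, fwhm = 4)
  zs <- vapply(controls, function(m) {
    as.vector(zscore_map(smooth_gaussian(m, 4), model)$data)
  }, numeric(6 * 6 * 4))
  mu <- rowMeans(zs)
  sdv <- apply(zs, 1, sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(sdv - 1)), 1e-10)
})

test_that("z is invariant under a common additive shift", {
  withr::local_seed(29)
  controls <- lapply(1:5, function(i) {
    scalar_map(array(rnorm(4 * 4 * 4, 100, 2), c(4, 4, 4)))
  })
  patient <- scalar_map(array(rnorm(4 * 4 * 4, 104, 2), c(4, 4, 4)))
  z1 <- zscore_map(patient, build_normative_model(controls, fwhm = 0))
  shifted <- lapply(controls, function(m) scalar_map(m$data + 50, m$voxel_size))
  z2 <- zscore_map(scalar_map(patient$data + 50, patient$voxel_size),
                   build_normative_model(shifted, fwhm = 0))
  expect_equal(z1$data, z2$data, tolerance = 1e-9)
})

test_that("degenerate control variance is invalid, and mismatches error", {
  a <- scalar_map(array(5, c(3, 3, 3)))
  model <- build_normative_model(list(a, a), fwhm = 0)  # SD 0 everywhere
  z <- zscore_map(a, model)
  expect_true(all(is.na(z$data)))

  b <- scalar_map(array(1, c(2, 2, 2)))
  expect_error(zscore_map(b, model), "grid")
  suvr_map_obj <- scalar_map(array(1, c(3, 3, 3)), modality = "SUVR")
  expect_error(zscore_map(suvr_map_obj, model), "[Mm]odality")
})
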