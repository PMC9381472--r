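protocol_tes <- c(10.5, 21.0, 31.5, 42.0, 52.5, 63.0)

test_that("two-point noiseless fit matches the closed form", {
  fit <- fit_monoexponential(c(900.325, 810.584), c(10.5, 21.0))
  expect_true(fit$fit_ok)
  expect_equal(fit$t2, 10.5 / log(900.325 / 810.584), tolerance = 1e-6)
  expect_equal(fit$t2, 100, tolerance = 1e-5)
  expect_equal(fit$s0, 1000, tolerance = 1e-4)
})

test_that("degenerate series are flagged rather than fit", {
  expect_false(fit_monoexponential(c(500, 500, 500), c(10, 20, 30))$fit_ok)
  expect_false(fit_monoexponential(c(100, 200, 300), c(10, 20, 30))$fit_ok)
  expect_false(fit_monoexponential(c(100, -5, 50), c(10, 20, 30))$fit_ok)
  expect_error(fit_monoexponential(c(1, 2), c(10, 20, 30)), "length")
  expect_error(fit_monoexponential(1000, 10.5), "2 echoes")
})

test_that("noisy six-echo fits agree with a grid-search least-squares oracle", {
  withr::local_seed(101)
  for (rep in 1:5) {
    signals <- 1000 * exp(-protocol_tes / 131) + rnorm(6, sd = 5)
    fit <- fit_monoexponential(signals, protocol_tes, refine = TRUE)
    oracle <- oracle_t2_grid(signals, protocol_tes,
                             t2_range = c(100, 160), n_grid = 2401)
    expect_true(fit$fit_ok)
    expect_lt(abs(fit$t2 - 131), 3)
    expect_lt(abs(fit$t2 - oracle$t2), 0.5)
  }
})

test_that("fitted T2 is consistent as noise vanishes across the T2 range", {
  for (t2_true in c(50, 110, 170, 2000, 3000)) {
    signals <- 1000 * exp(-protocol_tes / t2_true)
    fit <- fit_monoexponential(signals, protocol_tes)
    expect_lt(abs(fit$t2 - t2_true) / t2_true, 1e-6)
  }
})

test_that("log-linear and refined estimates agree on noiseless input", {
  signals <- 1000 * exp(-protocol_tes / 110)
  a <- fit_monoexponential(signals, protocol_tes, refine = FALSE)
  b <- fit_monoexponential(signals, protocol_tes, refine = TRUE)
  expect_lt(abs(a$t2 - b$t2), 0.1)
})

test_that("scaling all signals rescales S0 and leaves T2 unchanged", {
  withr::local_seed(5)
  signals <- 1000 * exp(-protocol_tes / 95) + rnorm(6, sd = 3)
  base <- fit_monoexponential(signals, protocol_tes)
  for (c_scale in c(0.25, 3, 40)) {
    scaled <- fit_monoexponential(c_scale * signals, protocol_tes)
    expect_equal(scaled$t2, base$t2, tolerance = 1e-10)
    expect_equal(scaled$s0, c_scale * base$s0, tolerance = 1e-8)
  }
})

test_that("volume fitting inverts the noiseless forward model exactly", {
  cfg <- test_phantom_config(noise = 0)
  ph <- generate_phantom_subject(cfg, 110, 109, 0.93, 0.91)
  t2 <- fit_t2_volume(ph$multi_echo, ph$brain_mask)
  brain <- ph$brain_mask
  expect_equal(t2$data[brain], ph$t2_truth$data[brain], tolerance = 1e-8)
  expect_true(all(is.na(t2$data[!brain])))
})

test_that("an empty mask yields a map with zero valid voxels, not a failure", {
  cfg <- test_phantom_config(noise = 0)
  ph <- generate_phantom_subject(cfg, 110, 109, 0.93, 0.91)
  t2 <- fit_t2_volume(ph$multi_echo, array(FALSE, dim(ph$labels)))
  expect_equal(sum(is.finite(t2$data)), 0L)
})

test_that("voxelwise noise propagates at the information-bound scale", {
  # At these six echo times the Cramer-Rao bound for T2 = 110 ms gives a
  # per-voxel SD of about 0.39 ms per unit relative noise percent; the
  # median absolute error must sit near 0.6745 * CRLB, and well under 2 ms
  # at 0.5% noise.
  cfg <- test_phantom_config(noise = 0.005)
  ph <- generate_phantom_subject(cfg, 110, 110, 0.93, 0.91, seed = 17)
  t2 <- fit_t2_volume(ph$multi_echo, ph$brain_mask)
  hip <- ph$labels %in% c(1L, 2L)
  err <- abs(t2$data[hip] - 110)
  expect_lt(median(err, na.rm = TRUE), 2)

  cfg2 <- test_phantom_config(noise = 0.02)
  ph2 <- generate_phantom_subject(cfg2, 110, 110, 0.93, 0.91, seed = 18)
  t22 <- fit_t2_volume(ph2$multi_echo, ph2$brain_mask)
  err2 <- abs(t22$data[ph2$labels %in% c(1L, 2L)] - 110)
  # 0.6745 * 7.7 ms = 5.2 ms; allow estimator inefficiency headroom
  expect_lt(median(err2, na.rm = TRUE), 7)
})

test_that("mask shape mismatches are an error", {
  cfg <- test_phantom_config(noise = 0)
  ph <- generate_phantom_subject(cfg, 110, 109, 0.93, 0.91)
  expect_error(fit_t2_volume(ph$multi_echo, array(TRUE, c(4, 4, 4))), "shape|match")
})

test_that("the CSF exclusion removes long-T2 voxels and nothing else", {
  cfg <- test_phantom_config(noise = 0)
  ph <- generate_phantom_subject(cfg, 110, 130, 0.93, 0.91)
  t2 <- apply_csf_threshold(fit_t2_volume(ph$multi_echo, ph$brain_mask))
  expect_true(all(is.na(t2$data[ph$labels == 3L])))       # 2000 ms CSF gone
  expect_true(all(is.finite(t2$data[ph$labels == 1L])))   # 110 ms kept
  expect_true(all(is.finite(t2$data[ph$labels == 2L])))   # 130 ms kept
  expect_true(all(is.finite(t2$data[ph$labels == 4L])))   # 90 ms kept
})

test_that("CSF thresholding is strict at the boundary and idempotent", {
  m <- scalar_map(array(c(170, 170.0001, 90, NA, 200, 100, 150, 160),
                        c(2, 2, 2)))
  out <- apply_csf_threshold(m, 170)
  expect_equal(out$data[1, 1, 1], 170)              # exactly 170 retained
  expect_true(is.na(out$data[2, 1, 1]))             # just above excluded
  expect_identical(apply_csf_threshold(out, 170)$data, out$data)

  all_low <- scalar_map(array(runif(8, 50, 170), c(2, 2, 2)))
  expect_identical(apply_csf_threshold(all_low, 170)$data, all_low$data)
  expect_error(apply_csf_threshold(m, -1), "positive")
})
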