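#' Default group parameter table for the simulated study population
#'
#' One row per subject group: healthy controls (`HC`) and the four mesial
#' temporal lobe epilepsy subgroups, split by MRI visibility of hippocampal
#' sclerosis (`MRHS_*` vs `MRneg_*`) and by seizure-onset side (`*_LTLE` left,
#' `*_RTLE` right). Columns give the group mean and SD of hippocampal T2 (ms)
#' and SUVR per hemisphere, the moments of the z-score-based asymmetry
#' indices (`ai_*`, z-units, left minus right), the moments of the raw
#' per-subject left-minus-right differences (`delta_*_lr_*`; reported per
#' subject, so they can differ from the difference of the rounded hemisphere
#' means by one rounding unit), and the group size. The values reproduce
#' group statistics reported for a 3T hybrid PET/MR MTLE cohort and are the
#' generative defaults for every simulation in the package.
#'
#' @return A tibble, one row per group.
#' @export
default_group_params <- function() {
  tibble::tribble(
    ~group, ~laterality, ~n_subjects,
    ~t2_left_mean, ~t2_left_sd, ~t2_right_mean, ~t2_right_sd,
    ~suvr_left_mean, ~suvr_left_sd, ~suvr_right_mean, ~suvr_right_sd,
    ~ai_t2_mean, ~ai_t2_sd, ~ai_suvr_mean, ~ai_suvr_sd,
    ~delta_t2_lr_mean, ~delta_t2_lr_sd, ~delta_suvr_lr_mean, ~delta_suvr_lr_sd,
    "HC",          NA,  24L, 110.40, 3.11, 109.23, 2.98, 0.93, 0.06, 0.91, 0.07,  0.00, 0.78,  0.00, 0.54,  1.17, 2.38,  0.02, 0.03,
    "MRHS_LTLE",  "L",  12L, 121.81, 8.00, 111.93, 4.50, 0.79, 0.07, 0.95, 0.05,  2.45, 2.08, -2.97, 1.32,  9.87, 6.46, -0.16, 0.08,
    "MRneg_LTLE", "L",  14L, 110.86, 4.66, 108.51, 5.01, 0.92, 0.07, 0.94, 0.07,  0.38, 0.81, -0.61, 0.65,  2.34, 2.42, -0.02, 0.04,
    "MRHS_RTLE",  "R",  10L, 113.89, 4.12, 117.85, 7.48, 0.94, 0.02, 0.81, 0.09, -1.78, 2.25,  1.69, 1.45, -3.96, 6.72,  0.13, 0.10,
    "MRneg_RTLE", "R",  10L, 112.93, 4.03, 114.94, 4.96, 0.95, 0.04, 0.91, 0.05, -1.11, 1.28,  0.34, 0.33, -2.02, 3.83,  0.04, 0.02
  )
}

.check_group_params <- function(groups) {
  sd_cols <- grep("_sd$", names(groups), value = TRUE)
  for (cl in sd_cols) {
    if (any(!is.finite(groups[[cl]]) | groups[[cl]] <= 0)) {
      abort(sprintf("Group SD column `%s` must be strictly positive.", cl))
    }
  }
  if (any(groups$n_subjects < 1L)) abort("`n_subjects` must be >= 1 per group.")
  invisible(groups)
}

# One bivariate-normal draw block: n pairs with given moments and correlation.
.draw_bivariate <- function(n, mean1, sd1, mean2, sd2, rho) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  tibble::tibble(
    v1 = mean1 + sd1 * z1,
    v2 = mean2 + sd2 * (rho * z1 + sqrt(1 - rho^2) * z2)
  )
}

#' Simulate a cohort-level asymmetry-index feature table
#'
#' Draws, for every group row, `n_subjects` subjects whose T2 and SUVR
#' asymmetry indices come from normal distributions with that group's
#' `ai_*_mean` / `ai_*_sd` moments. The two AIs are drawn independently by
#' default; `ai_correlation` exposes a within-subject correlation. True
#' laterality is `L` for left-sided groups, `R` for right-sided, `NA` for
#' controls.
#'
#' @param groups group parameter tibble, see [default_group_params()].
#' @param seed integer seed; fixed seed gives a reproducible table.
#' @param ai_correlation correlation between a subject's two AIs in `[-1, 1]`.
#'
#' @return Tibble with columns `subject_id`, `group`, `ai_t2`, `ai_suvr`,
#'   `laterality`.
#' @export
generate_cohort_features <- function(groups = default_group_params(),
                                     seed = NULL, ai_correlation = 0) {
  .check_group_params(groups)
  if (abs(ai_correlation) > 1) abort("`ai_correlation` must lie in [-1, 1].")
  run <- function() {
    out <- purrr::pmap_dfr(
      groups[c("group", "laterality", "n_subjects",
               "ai_t2_mean", "ai_t2_sd", "ai_suvr_mean", "ai_suvr_sd")],
      function(group, laterality, n_subjects, ai_t2_mean, ai_t2_sd,
               ai_suvr_mean, ai_suvr_sd) {
        d <- .draw_bivariate(n_subjects, ai_t2_mean, ai_t2_sd,
                             ai_suvr_mean, ai_suvr_sd, ai_correlation)
        tibble::tibble(
          group = group, ai_t2 = d$v1, ai_suvr = d$v2,
          laterality = laterality
        )
      }
    )
    dplyr::mutate(out,
      subject_id = sprintf("S%04d", dplyr::row_number()),
      .before = 1
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Draw per-subject left/right hippocampal T2 and SUVR values for one group
#'
#' Left and right values are drawn as bivariate normals with the group's
#' hemisphere means/SDs and a within-subject left/right correlation
#' (default 0.5, which keeps the SD of the left-minus-right difference near
#' its reported cohort value).
#'
#' @param group_row one row of [default_group_params()].
#' @param n number of subjects.
#' @param lr_correlation within-subject left/right correlation.
#' @param seed optional integer seed.
#'
#' @return Tibble with columns `t2_left`, `t2_right`, `suvr_left`,
#'   `suvr_right`.
#' @export
draw_subject_values <- function(group_row, n, lr_correlation = 0.5,
                                seed = NULL) {
  .check_group_params(group_row)
  if (abs(lr_correlation) > 1) abort("`lr_correlation` must lie in [-1, 1].")
  run <- function() {
    t2 <- .draw_bivariate(n, group_row$t2_left_mean, group_row$t2_left_sd,
                          group_row$t2_right_mean, group_row$t2_right_sd,
                          lr_correlation)
    su <- .draw_bivariate(n, group_row$suvr_left_mean, group_row$suvr_left_sd,
                          group_row$suvr_right_mean, group_row$suvr_right_sd,
                          lr_correlation)
    tibble::tibble(
      t2_left = t2$v1, t2_right = t2$v2,
      suvr_left = su$v1, suvr_right = su$v2
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Phantom geometry and acquisition configuration
#'
#' Defines the synthetic head used by the image-level generator: a brain
#' ellipsoid containing two disjoint hippocampal ellipsoids and a midline CSF
#' compartment, the multi-echo acquisition (six echo times, 10.5 to 63 ms in
#' 10.5 ms steps, as in a clinical multi-echo spin-echo protocol), the
#' baseline signal `s0`, tissue T2 values and the relative noise level. The
#' default grid is 64 x 64 x 32 voxels at 2 mm isotropic: small enough for
#' seconds-per-subject simulation while leaving room for smoothing kernels.
#' Background tissue T2 (90 ms) and CSF T2 (2000 ms) straddle the 170 ms CSF
#' exclusion threshold.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size mm per axis (scalar or length-3).
#' @param echo_times ms, strictly increasing.
#' @param s0 baseline signal inside the brain.
#' @param background_t2,csf_t2 tissue T2 values, ms; `csf_t2` must exceed
#'   170 ms so the CSF exclusion rule has something to remove.
#' @param background_suvr,csf_suvr target SUVR of background tissue and CSF.
#' @param noise_sd_relative echo-image noise SD as a fraction of `s0`.
#' @param lr_correlation within-subject left/right correlation used when
#'   drawing cohort values.
#' @param brain_center,brain_radii,left_center,left_radii,right_center,
#'   right_radii,csf_center,csf_radii ellipsoid geometry in voxel units.
#'
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 32),
                           voxel_size = c(2, 2, 2),
                           echo_times = c(10.5, 21.0, 31.5, 42.0, 52.5, 63.0),
                           s0 = 1000,
                           background_t2 = 90,
                           csf_t2 = 2000,
                           background_suvr = 1,
                           csf_suvr = 0.3,
                           noise_sd_relative = 0.02,
                           lr_correlation = 0.5,
                           brain_center = (grid_shape + 1) / 2,
                           brain_radii = grid_shape * 0.44,
                           left_center = c(grid_shape[1] * 0.31, grid_shape[2] / 2, grid_shape[3] / 2),
                           left_radii = c(6, 4, 3) * pmin(1, grid_shape[1] / 64),
                           right_center = c(grid_shape[1] * 0.70, grid_shape[2] / 2, grid_shape[3] / 2),
                           right_radii = c(6, 4, 3) * pmin(1, grid_shape[1] / 64),
                           csf_center = c(grid_shape[1] / 2, grid_shape[2] / 2, grid_shape[3] / 2),
                           csf_radii = c(3, 3, 3) * pmin(1, grid_shape[1] / 64)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    abort("`grid_shape` must be three axis lengths >= 8 voxels.")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  echo_times <- as.numeric(echo_times)
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    abort("`echo_times` must be positive and strictly increasing.")
  }
  if (csf_t2 <= 170) abort("`csf_t2` must exceed the 170 ms CSF threshold.")
  if (background_t2 <= 0 || s0 <= 0) abort("`background_t2` and `s0` must be positive.")
  if (noise_sd_relative < 0) abort("`noise_sd_relative` must be >= 0.")

  cfg <- structure(
    list(
      grid_shape = grid_shape, voxel_size = voxel_size,
      echo_times = echo_times, s0 = s0,
      background_t2 = background_t2, csf_t2 = csf_t2,
      background_suvr = background_suvr, csf_suvr = csf_suvr,
      noise_sd_relative = noise_sd_relative,
      lr_correlation = lr_correlation,
      brain_center = brain_center, brain_radii = brain_radii,
      left_center = left_center, left_radii = left_radii,
      right_center = right_center, right_radii = right_radii,
      csf_center = csf_center, csf_radii = csf_radii
    ),
    class = "phantom_config"
  )
  labels <- phantom_labels(cfg)
  if (!any(labels == 1L) || !any(labels == 2L)) {
    abort("Hippocampal ellipsoids fall outside the grid.")
  }
  cfg
}

.ellipsoid_mask <- function(grid_shape, center, radii) {
  i <- (seq_len(grid_shape[1]) - center[1]) / radii[1]
  j <- (seq_len(grid_shape[2]) - center[2]) / radii[2]
  k <- (seq_len(grid_shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(i^2, j^2, "+"), k^2, "+")
  d2 <= 1
}

#' Tissue label volume of a phantom configuration
#'
#' Labels: 0 = outside the brain (no signal), 1 = left hippocampus,
#' 2 = right hippocampus, 3 = CSF, 4 = in-brain background tissue. The brain
#' mask is `labels > 0`. Errors if the hippocampal or CSF compartments
#' overlap.
#'
#' @param config A [phantom_config()].
#' @return 3-D integer array of labels.
#' @export
phantom_labels <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  brain <- .ellipsoid_mask(gs, config$brain_center, config$brain_radii)
  lh <- .ellipsoid_mask(gs, config$left_center, config$left_radii) & brain
  rh <- .ellipsoid_mask(gs, config$right_center, config$right_radii) & brain
  csf <- .ellipsoid_mask(gs, config$csf_center, config$csf_radii) & brain
  if (any((lh & rh) | (lh & csf) | (rh & csf))) {
    abort("Phantom ROIs overlap; adjust ellipsoid centers/radii.")
  }
  labels <- array(0L, gs)
  labels[brain] <- 4L
  labels[csf] <- 3L
  labels[lh] <- 1L
  labels[rh] <- 2L
  labels
}

#' Render one phantom subject
#'
#' Builds the ground-truth T2 and uptake volumes from the tissue labels, then
#' simulates the multi-echo acquisition: the signal at echo `k` is
#' `s0 * exp(-TE_k / T2)` plus additive Gaussian noise with SD
#' `noise_sd_relative * s0` (zero outside the brain, where `s0 = 0`). The PET
#' volume assigns each hippocampus and the CSF an uptake solved exactly so
#' that, noiseless, global-mean scaling returns the requested SUVR targets;
#' the whole volume is then multiplied by a random per-subject dose factor,
#' which SUVR normalisation must cancel.
#'
#' @param config A [phantom_config()].
#' @param t2_left,t2_right hippocampal T2 values, ms (> 0).
#' @param suvr_left,suvr_right hippocampal SUVR targets.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   volumes.
#'
#' @return List of class `phantom_subject` with elements `multi_echo`
#'   ([multi_echo_volume()]), `pet` ([scalar_map()], uptake units), `labels`
#'   (integer array), `t2_truth` and `suvr_truth` ([scalar_map()]s), and
#'   `brain_mask`.
#' @export
generate_phantom_subject <- function(config, t2_left, t2_right,
                                     suvr_left, suvr_right, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (any(c(t2_left, t2_right) <= 0)) abort("Hippocampal T2 values must be positive.")
  if (any(c(suvr_left, suvr_right) <= 0)) abort("Hippocampal SUVR targets must be positive.")

  run <- function() {
    labels <- phantom_labels(config)
    gs <- config$grid_shape
    brain <- labels > 0L

    t2 <- array(NA_real_, gs)
    t2[labels == 4L] <- config$background_t2
    t2[labels == 3L] <- config$csf_t2
    t2[labels == 1L] <- t2_left
    t2[labels == 2L] <- t2_right

    s0 <- array(0, gs)
    s0[brain] <- config$s0

    ne <- length(config$echo_times)
    me <- array(0, c(gs, ne))
    decay <- array(0, gs)
    for (k in seq_len(ne)) {
      decay[brain] <- exp(-config$echo_times[k] / t2[brain])
      echo <- s0 * decay
      if (config$noise_sd_relative > 0) {
        echo <- echo + rnorm(length(echo),
                             sd = config$noise_sd_relative * config$s0) *
          (s0 > 0)
      }
      me[, , , k] <- echo
    }

    # Solve uptake levels so that noiseless global-mean scaling hits the
    # hippocampal and CSF SUVR targets exactly; background absorbs the
    # normalisation constraint (its realised SUVR sits near background_suvr).
    n_bg <- sum(labels == 4L)
    n_l <- sum(labels == 1L)
    n_r <- sum(labels == 2L)
    n_c <- sum(labels == 3L)
    n_all <- n_bg + n_l + n_r + n_c
    s_sum <- n_l * suvr_left + n_r * suvr_right + n_c * config$csf_suvr
    gm <- n_bg * config$background_suvr / (n_all - s_sum)
    if (!is.finite(gm) || gm <= 0) {
      abort("Inconsistent SUVR targets: implied global mean is not positive.")
    }

    uptake <- array(NA_real_, gs)
    uptake[labels == 4L] <- config$background_suvr
    uptake[labels == 3L] <- config$csf_suvr * gm
    uptake[labels == 1L] <- suvr_left * gm
    uptake[labels == 2L] <- suvr_right * gm

    dose <- exp(rnorm(1, 0, 0.2))
    uptake <- uptake * dose
    if (config$noise_sd_relative > 0) {
      noise <- rnorm(length(uptake), sd = config$noise_sd_relative * dose)
      uptake[brain] <- pmax(uptake[brain] + noise[which(brain)], 0)
    }

    suvr_truth <- array(NA_real_, gs)
    suvr_truth[labels == 4L] <- config$background_suvr / gm
    suvr_truth[labels == 3L] <- config$csf_suvr
    suvr_truth[labels == 1L] <- suvr_left
    suvr_truth[labels == 2L] <- suvr_right

    structure(
      list(
        multi_echo = multi_echo_volume(me, config$echo_times, config$voxel_size),
        pet = scalar_map(uptake, config$voxel_size, "uptake"),
        labels = labels,
        t2_truth = scalar_map(t2, config$voxel_size, "T2"),
        suvr_truth = scalar_map(suvr_truth, config$voxel_size, "SUVR"),
        brain_mask = brain
      ),
      class = "phantom_subject"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a healthy-control phantom cohort
#'
#' Draws per-subject left/right hippocampal T2 and SUVR from the
#' healthy-control group parameters and (optionally) renders each subject as
#' an image phantom. With `render = FALSE` only the per-subject value table
#' is returned, which is what the feature-level moment checks use.
#'
#' @param config A [phantom_config()].
#' @param hc_params a one-row group parameter tibble; defaults to the `HC`
#'   row of [default_group_params()].
#' @param n number of controls (>= 2; the normative SD is undefined below
#'   that).
#' @param seed optional integer seed.
#' @param render render image phantoms (`TRUE`) or return values only.
#'
#' @return List with `values` (tibble of per-subject draws) and `subjects`
#'   (list of `phantom_subject`, or `NULL` when `render = FALSE`).
#' @export
generate_control_cohort <- function(config = phantom_config(),
                                    hc_params = NULL, n = 24, seed = NULL,
                                    render = TRUE) {
  if (is.null(hc_params)) {
    hc_params <- dplyr::filter(default_group_params(), .data$group == "HC")
  }
  if (n < 2) abort("At least 2 controls are required (normative SD undefined).")
  run <- function() {
    values <- draw_subject_values(hc_params, n, config$lr_correlation)
    subjects <- NULL
    if (render) {
      subjects <- purrr::pmap(values, function(t2_left, t2_right,
                                               suvr_left, suvr_right) {
        generate_phantom_subject(config, t2_left, t2_right,
                                 suvr_left, suvr_right)
      })
    }
    list(values = values, subjects = subjects)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
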