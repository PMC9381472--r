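# Gaussian kernel weight matrix for one axis, in voxel units.
# Any global scale cancels in the mask-normalised convolution.
.gauss_axis_matrix <- function(n, sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(diag(n))
  r <- ceiling(truncate * sigma_vox)
  off <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-0.5 * (off / sigma_vox)^2)
  k[abs(off) > r] <- 0
  k
}

# Apply an axis kernel matrix along dimension `axis` of a 3-D array.
.conv_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- aperm(a, perm)
  db <- dim(b)
  b <- k %*% matrix(b, nrow = db[1])
  dim(b) <- db
  aperm(b, order(perm))
}

#' Gaussian smoothing of a scalar map (FWHM in mm)
#'
#' Convolves the map with a separable isotropic Gaussian of standard
#' deviation `fwhm / (2 * sqrt(2 * log(2)))` mm, converted to voxel units per
#' axis. Invalid voxels are excluded by normalised (mask-weighted)
#' convolution: the value image times the validity mask and the mask itself
#' are smoothed with the same kernel and divided, so invalid voxels neither
#' leak values into their neighbours nor become valid themselves. A constant
#' map is therefore preserved exactly, and `fwhm = 0` is the identity.
#'
#' @param map A [scalar_map()].
#' @param fwhm full width at half maximum of the kernel, mm; `>= 0`.
#'
#' @return The smoothed [scalar_map()] (same validity pattern).
#' @export
smooth_gaussian <- function(map, fwhm) {
  stopifnot(inherits(map, "scalar_map"))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm < 0) {
    abort("`fwhm` must be a single non-negative length in mm.")
  }
  if (fwhm == 0) return(map)

  sigma_mm <- fwhm_to_sigma(fwhm)
  sigma_vox <- sigma_mm / map$voxel_size
  d <- dim(map$data)

  valid <- is.finite(map$data)
  num <- map$data
  num[!valid] <- 0
  den <- array(as.numeric(valid), d)

  for (ax in 1:3) {
    k <- .gauss_axis_matrix(d[ax], sigma_vox[ax])
    num <- .conv_axis(num, k, ax)
    den <- .conv_axis(den, k, ax)
  }

  out <- array(NA_real_, d)
  out[valid] <- num[valid] / den[valid]
  scalar_map(out, map$voxel_size, map$modality)
}

#' Convert a Gaussian FWHM to its standard deviation
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return `fwhm / (2 * sqrt(2 * log(2)))`, same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Build a voxel-wise normative model from a control cohort
#'
#' Each control map is smoothed at `fwhm`, then the per-voxel sample mean and
#' sample standard deviation (n - 1 denominator) are taken over controls. A
#' voxel is valid in the model only if it is valid in every control.
#'
#' @param control_maps list of [scalar_map()]s on a common grid (>= 2).
#' @param fwhm smoothing FWHM in mm applied to each control before pooling.
#'
#' @return An object of class `normative_model` with fields `mean_map`,
#'   `sd_map` (both [scalar_map()]s), `n_controls`, `modality`,
#'   `smoothing_fwhm`.
#' @export
build_normative_model <- function(control_maps, fwhm = 0) {
  if (!is.list(control_maps) || length(control_maps) < 2L) {
    abort("At least 2 control maps are required (sample SD undefined otherwise).")
  }
  if (!all(vapply(control_maps, inherits, logical(1), "scalar_map"))) {
    abort("`control_maps` must be a list of scalar_map objects.")
  }
  d <- dim(control_maps[[1]]$data)
  vs <- control_maps[[1]]$voxel_size
  modality <- control_maps[[1]]$modality
  same <- vapply(control_maps, function(m) {
    identical(dim(m$data), d) && isTRUE(all.equal(m$voxel_size, vs))
  }, logical(1))
  if (!all(same)) abort("All control maps must share one grid and voxel size.")

  sm <- lapply(control_maps, smooth_gaussian, fwhm = fwhm)
  x <- vapply(sm, function(m) as.vector(m$data), numeric(prod(d)))
  n <- length(control_maps)
  valid <- rowSums(!is.finite(x)) == 0L

  mu <- rep(NA_real_, prod(d))
  sdv <- rep(NA_real_, prod(d))
  xv <- x[valid, , drop = FALSE]
  m <- rowMeans(xv)
  mu[valid] <- m
  sdv[valid] <- sqrt(rowSums((xv - m)^2) / (n - 1))

  structure(
    list(
      mean_map = scalar_map(array(mu, d), vs, modality),
      sd_map = scalar_map(array(sdv, d), vs, modality),
      n_controls = n,
      modality = modality,
      smoothing_fwhm = fwhm
    ),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model [%s]> %d controls, smoothing FWHM %.3g mm\n",
    x$modality, x$n_controls, x$smoothing_fwhm
  ))
  invisible(x)
}

#' Voxel-wise z-score map against a normative model
#'
#' Standardises a patient map voxel by voxel: `z = (x - mu) / sigma`, where
#' `mu` and `sigma` are the control-cohort mean and SD from the model. The
#' patient map must already be smoothed at the model's FWHM (the pipeline
#' enforces this ordering). Voxels where the control SD falls below
#' `sd_floor` are invalid: degenerate control variance carries no normative
#' information.
#'
#' @param patient_map A smoothed [scalar_map()] on the model grid.
#' @param model A [build_normative_model()] result of the same modality.
#' @param sd_floor minimum admissible control SD (modality units).
#'
#' @return A [scalar_map()] of z-scores (modality `"z_<modality>"`).
#' @export
zscore_map <- function(patient_map, model, sd_floor = 1e-6) {
  stopifnot(inherits(patient_map, "scalar_map"), inherits(model, "normative_model"))
  if (!identical(dim(patient_map$data), dim(model$mean_map$data))) {
    abort("Patient map grid does not match the normative model grid.")
  }
  if (!identical(patient_map$modality, model$modality)) {
    abort(sprintf(
      "Modality mismatch: patient map is %s, model is %s.",
      patient_map$modality, model$modality
    ))
  }
  x <- patient_map$data
  mu <- model$mean_map$data
  sigma <- model$sd_map$data
  z <- (x - mu) / sigma
  z[!is.finite(z) | !is.finite(sigma) | sigma < sd_floor] <- NA_real_
  scalar_map(z, patient_map$voxel_size, paste0("z_", model$modality))
}
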