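#' Fit a monoexponential T2 decay to one voxel's echo series
#'
#' Estimates `S(TE) = S0 * exp(-TE / T2)` from a multi-echo spin-echo signal
#' series. The default estimator is weighted log-linear least squares
#' (regression of `log S` on TE with weights proportional to the squared
#' signal, which approximates maximum likelihood under additive Gaussian noise
#' at moderate SNR). Setting `refine = TRUE` polishes the estimate with a
#' bounded nonlinear least-squares minimisation of the sum of squared
#' residuals in the signal domain.
#'
#' The fit is flagged as failed (`fit_ok = FALSE`) when any signal is
#' non-positive or the fitted decay rate is non-negative (flat or growing
#' series, for which T2 is undefined); such voxels are invalid downstream.
#'
#' @param signals numeric, signal intensities at each echo.
#' @param echo_times numeric, echo times in ms (strictly increasing, same
#'   length as `signals`).
#' @param refine logical; run bounded nonlinear refinement after the
#'   log-linear fit.
#' @param t2_max upper clip for the fitted T2 in ms; near-flat decays
#'   otherwise explode numerically.
#'
#' @return One-row tibble with columns `s0`, `t2` (ms) and `fit_ok`.
#' @examples
#' fit_monoexponential(c(900.325, 810.584), c(10.5, 21.0))
#' @export
fit_monoexponential <- function(signals, echo_times, refine = FALSE,
                                t2_max = 5000) {
  signals <- as.numeric(signals)
  echo_times <- as.numeric(echo_times)
  if (length(signals) != length(echo_times)) {
    abort("`signals` and `echo_times` must have the same length.")
  }
  if (length(signals) < 2L) abort("At least 2 echoes are required.")
  if (any(diff(echo_times) <= 0) || any(echo_times <= 0)) {
    abort("`echo_times` must be positive and strictly increasing.")
  }

  bad <- tibble::tibble(s0 = NA_real_, t2 = NA_real_, fit_ok = FALSE)
  if (any(!is.finite(signals)) || any(signals <= 0)) return(bad)

  w <- signals^2
  y <- log(signals)
  sw <- sum(w)
  swx <- sum(w * echo_times)
  swy <- sum(w * y)
  swxx <- sum(w * echo_times^2)
  swxy <- sum(w * echo_times * y)
  denom <- sw * swxx - swx^2
  if (denom <= 0) return(bad)
  slope <- (sw * swxy - swx * swy) / denom
  if (slope >= 0) return(bad)
  t2 <- min(-1 / slope, t2_max)
  s0 <- exp((swy - slope * swx) / sw)

  if (refine) {
    fn <- function(par) sum((signals - par[1] * exp(-echo_times / par[2]))^2)
    opt <- optim(c(s0, t2), fn,
      method = "L-BFGS-B",
      lower = c(0, 1e-3), upper = c(Inf, t2_max)
    )
    s0 <- opt$par[1]
    t2 <- opt$par[2]
    if (t2 >= t2_max - 1e-9) return(bad)
  }
  tibble::tibble(s0 = s0, t2 = t2, fit_ok = TRUE)
}

#' Voxel-wise T2 map from a multi-echo volume
#'
#' Applies the weighted log-linear monoexponential estimator (see
#' [fit_monoexponential()]) to every voxel inside `brain_mask`, fully
#' vectorised. Voxels with any non-positive echo signal, or with a
#' non-negative decay slope, are invalid (`NA`) in the output map rather than
#' partially fit.
#'
#' @param volume A [multi_echo_volume()].
#' @param brain_mask 3-D logical array matching the spatial grid; `NULL` fits
#'   every voxel.
#' @param t2_max upper clip for fitted T2 (ms).
#'
#' @return A [scalar_map()] of T2 values in ms (modality `"T2"`).
#' @export
fit_t2_volume <- function(volume, brain_mask = NULL, t2_max = 5000) {
  stopifnot(inherits(volume, "multi_echo_volume"))
  d <- dim(volume$data)
  sp <- d[1:3]
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, sp)
  }
  if (!identical(as.integer(dim(brain_mask)), as.integer(sp))) {
    abort("`brain_mask` shape must match the volume's spatial grid.")
  }

  out <- array(NA_real_, sp)
  idx <- which(brain_mask)
  if (length(idx) == 0L) {
    return(scalar_map(out, volume$voxel_size, "T2"))
  }

  te <- volume$echo_times
  mat <- matrix(volume$data, nrow = prod(sp))[idx, , drop = FALSE]
  ok <- rowSums(!is.finite(mat) | mat <= 0) == 0L

  if (any(ok)) {
    v <- mat[ok, , drop = FALSE]
    w <- v^2
    y <- log(v)
    sw <- rowSums(w)
    swx <- as.vector(w %*% te)
    swxx <- as.vector(w %*% te^2)
    swy <- rowSums(w * y)
    swxy <- as.vector((w * y) %*% te)
    denom <- sw * swxx - swx^2
    slope <- (sw * swxy - swx * swy) / denom
    good <- denom > 0 & slope < 0
    t2 <- rep(NA_real_, nrow(v))
    t2[good] <- pmin(-1 / slope[good], t2_max)
    out[idx[ok]] <- t2
  }
  scalar_map(out, volume$voxel_size, "T2")
}

#' Exclude CSF-contaminated voxels from a T2 map
#'
#' CSF has a very long transverse relaxation time; voxels whose fitted T2
#' exceeds the threshold are treated as CSF-contaminated and invalidated.
#' The comparison is strict (`>`), so a voxel at exactly the threshold is
#' retained, and the operation is idempotent.
#'
#' @param t2_map A [scalar_map()] of T2 values (ms).
#' @param threshold exclusion threshold in ms; default 170.
#'
#' @return The map with supra-threshold voxels set invalid.
#' @export
apply_csf_threshold <- function(t2_map, threshold = 170) {
  stopifnot(inherits(t2_map, "scalar_map"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive value in ms.")
  }
  data <- t2_map$data
  data[which(data > threshold)] <- NA_real_
  scalar_map(data, t2_map$voxel_size, t2_map$modality)
}
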