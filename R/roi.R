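#' Binary erosion of a 3-D ROI mask
#'
#' Erodes with a 6-connected cross structuring element (the voxel and its six
#' face neighbours), repeated `iterations` times; used to shrink hippocampal
#' masks away from CSF-adjacent boundaries and reduce partial-volume effects.
#' The output is always a subset of the input. If erosion would empty the
#' mask, a warning is raised and the original, un-eroded mask is returned so
#' downstream extraction still has support.
#'
#' @param mask 3-D logical array, non-empty.
#' @param iterations number of erosion passes; default 1.
#'
#' @return 3-D logical array.
#' @export
erode_mask <- function(mask, iterations = 1) {
  if (!is.array(mask) || length(dim(mask)) != 3L) abort("`mask` must be a 3-D array.")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) abort("`mask` is empty.")
  iterations <- as.integer(iterations)
  if (iterations < 0L) abort("`iterations` must be non-negative.")

  shift_and <- function(m, axis, by) {
    d <- dim(m)
    out <- array(FALSE, d)
    n <- d[axis]
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst <- src
    if (by > 0) {
      dst[[axis]] <- seq(1 + by, n)
      src[[axis]] <- seq(1, n - by)
    } else {
      dst[[axis]] <- seq(1, n + by)
      src[[axis]] <- seq(1 - by, n)
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }

  out <- mask
  for (i in seq_len(iterations)) {
    er <- out
    for (ax in 1:3) {
      er <- er & shift_and(out, ax, 1L) & shift_and(out, ax, -1L)
    }
    if (!any(er)) {
      warn("Erosion emptied the mask; falling back to the un-eroded input.")
      return(mask)
    }
    out <- er
  }
  out
}

#' Mean of a scalar map over an ROI
#'
#' Arithmetic mean over the ROI voxels that are valid in the map; invalid
#' voxels (e.g. CSF-excluded T2 voxels) simply drop out of the average.
#'
#' @param map A [scalar_map()].
#' @param roi_mask 3-D logical array on the same grid.
#' @param roi_name label used in error messages.
#'
#' @return A single numeric value.
#' @export
extract_roi_mean <- function(map, roi_mask, roi_name = "ROI") {
  stopifnot(inherits(map, "scalar_map"))
  if (!identical(as.integer(dim(roi_mask)), as.integer(dim(map$data)))) {
    abort("`roi_mask` shape must match the map grid.")
  }
  use <- roi_mask & valid_mask(map)
  if (!any(use)) {
    abort(sprintf("No valid voxels in %s (%s map); cannot extract a mean.",
                  roi_name, map$modality))
  }
  mean(map$data[use])
}

#' Left-minus-right asymmetry index
#'
#' The lateralization feature: left minus right hippocampal measurement
#' (here, mean z-score within the eroded hippocampal ROI). Negative values
#' point left for SUVR (ipsilateral hypometabolism), positive values point
#' left for T2 (ipsilateral T2 prolongation).
#'
#' @param left,right finite numeric values (vectorised).
#' @return `left - right`.
#' @export
asymmetry_index <- function(left, right) {
  if (any(!is.finite(left)) || any(!is.finite(right))) {
    abort("`left` and `right` must be finite.")
  }
  left - right
}

#' Pool subgroup left-right asymmetries into an ipsilateral-contralateral mean
#'
#' Converts each subgroup's mean left-minus-right difference to the
#' ipsilateral-minus-contralateral orientation (negated for right-sided
#' groups, since there ipsilateral = right) and returns the
#' sample-size-weighted mean across subgroups.
#'
#' @param subgroups data frame with columns `mean` (L-R subgroup mean), `n`
#'   (subgroup size) and `laterality` (`"L"` or `"R"`).
#'
#' @return A single numeric: the pooled ipsilateral-minus-contralateral mean.
#' @examples
#' pooled_ic_delta(data.frame(
#'   mean = c(2.34, -2.02), n = c(14, 10), laterality = c("L", "R")
#' ))
#' @export
pooled_ic_delta <- function(subgroups) {
  if (!is.data.frame(subgroups) || nrow(subgroups) == 0L) {
    abort("`subgroups` must be a non-empty data frame.")
  }
  if (!all(c("mean", "n", "laterality") %in% names(subgroups))) {
    abort("`subgroups` needs columns `mean`, `n`, `laterality`.")
  }
  if (any(subgroups$n <= 0)) abort("Subgroup sizes must be positive.")
  if (!all(subgroups$laterality %in% c("L", "R"))) {
    abort("`laterality` must be 'L' or 'R'.")
  }
  oriented <- ifelse(subgroups$laterality == "R", -subgroups$mean, subgroups$mean)
  weighted.mean(oriented, subgroups$n)
}

#' Empirical reference interval of control asymmetry indices
#'
#' Central `level` percentile interval of the control AI distribution
#' (empirical 2.5-97.5 percentiles at the default level); a patient AI
#' strictly inside the interval is "within the normal range" of control
#' asymmetry. `method = "normal"` gives the normal-theory alternative
#' `mean +/- z * SD`.
#'
#' @param control_ais numeric, control asymmetry indices (>= 3 values).
#' @param level central coverage, in (0, 1]; `1` returns the control range.
#' @param method `"empirical"` (percentiles) or `"normal"`.
#'
#' @return Tibble with columns `low`, `high`, `level`.
#' @export
control_reference_interval <- function(control_ais, level = 0.95,
                                       method = c("empirical", "normal")) {
  method <- match.arg(method)
  control_ais <- as.numeric(control_ais)
  if (length(control_ais) < 3L) abort("At least 3 control values are required.")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1) {
    abort("`level` must be in (0, 1].")
  }
  if (method == "normal") {
    z <- qnorm(1 - (1 - level) / 2)
    lo <- mean(control_ais) - z * sd(control_ais)
    hi <- mean(control_ais) + z * sd(control_ais)
  } else if (level == 1) {
    lo <- min(control_ais)
    hi <- max(control_ais)
  } else {
    q <- quantile(control_ais, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
    lo <- q[1]
    hi <- q[2]
  }
  tibble::tibble(low = lo, high = hi, level = level)
}

#' Derive asymmetry and laterality-oriented differences for a measures table
#'
#' Adds, per subject: `ai_t2` / `ai_suvr` (left-minus-right z means),
#' `delta_t2_lr` / `delta_suvr_lr` (raw left-minus-right), and, for subjects
#' with known laterality, the ipsilateral-minus-contralateral deltas
#' (`delta_t2_ic` / `delta_suvr_ic` = L-R for left-sided disease, negated for
#' right-sided).
#'
#' @param measures tibble with columns `z_t2_left`, `z_t2_right`,
#'   `z_suvr_left`, `z_suvr_right`, `t2_left`, `t2_right`, `suvr_left`,
#'   `suvr_right` and `laterality` (`"L"`, `"R"` or `NA`).
#'
#' @return The tibble with the derived columns appended.
#' @export
derive_asymmetry <- function(measures) {
  need <- c("z_t2_left", "z_t2_right", "z_suvr_left", "z_suvr_right",
            "t2_left", "t2_right", "suvr_left", "suvr_right", "laterality")
  miss <- setdiff(need, names(measures))
  if (length(miss)) abort(paste("Missing columns:", paste(miss, collapse = ", ")))
  sign_ic <- ifelse(is.na(measures$laterality), NA_real_,
                    ifelse(measures$laterality == "L", 1, -1))
  dplyr::mutate(
    measures,
    ai_t2 = .data$z_t2_left - .data$z_t2_right,
    ai_suvr = .data$z_suvr_left - .data$z_suvr_right,
    delta_t2_lr = .data$t2_left - .data$t2_right,
    delta_suvr_lr = .data$suvr_left - .data$suvr_right,
    delta_t2_ic = sign_ic * (.data$t2_left - .data$t2_right),
    delta_suvr_ic = sign_ic * (.data$suvr_left - .data$suvr_right)
  )
}

#' Mirror every subject's hemispheres in a measures table
#'
#' Swaps all left/right column pairs and flips the recorded laterality;
#' useful for checking that the whole analysis is equivariant under a
#' hemisphere swap (every asymmetry index changes sign, every lateralization
#' call flips).
#'
#' @param measures tibble with `*_left`/`*_right` column pairs and a
#'   `laterality` column.
#' @return The mirrored tibble with derived asymmetries recomputed.
#' @export
swap_hemispheres <- function(measures) {
  nm <- names(measures)
  lefts <- grep("_left$", nm, value = TRUE)
  for (l in lefts) {
    r <- sub("_left$", "_right", l)
    if (r %in% nm) {
      tmp <- measures[[l]]
      measures[[l]] <- measures[[r]]
      measures[[r]] <- tmp
    }
  }
  measures$laterality <- unname(c(L = "R", R = "L")[measures$laterality])
  derive_asymmetry(measures)
}
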