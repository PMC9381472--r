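#' Scalar voxel map
#'
#' A 3-D grid holding one quantitative value per voxel: a T2 map (ms), a PET
#' SUVR map (dimensionless), or a z-score map (z-units). Invalid voxels
#' (outside the brain, failed fits, CSF-excluded) carry `NA` and are excluded
#' from every downstream statistic.
#'
#' @param data 3-D numeric array; `NA` marks invalid voxels.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param modality character tag, e.g. `"T2"`, `"SUVR"`, `"z_T2"`.
#'
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(data, voxel_size = c(1, 1, 1), modality = "T2") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive lengths in mm.")
  }
  structure(
    list(data = data, voxel_size = voxel_size, modality = modality),
    class = "scalar_map"
  )
}

#' Validity mask of a scalar map
#'
#' @param map A [scalar_map()].
#' @return 3-D logical array, `TRUE` where the voxel holds a valid value.
#' @export
valid_mask <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  v <- is.finite(map$data)
  dim(v) <- dim(map$data)
  v
}

#' @export
print.scalar_map <- function(x, ...) {
  d <- dim(x$data)
  nv <- sum(is.finite(x$data))
  cat(sprintf(
    "<scalar_map [%s]> %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d valid (%.1f%%)\n",
    x$modality, d[1], d[2], d[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    nv, 100 * nv / prod(d)
  ))
  rng <- suppressWarnings(range(x$data, na.rm = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  value range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Multi-echo spin-echo volume
#'
#' A 4-D stack of echo images (x, y, z, echo) with the echo times at which the
#' signals were sampled; the raw input of voxel-wise T2 relaxometry.
#'
#' @param data 4-D numeric array `(x, y, z, echo)`.
#' @param echo_times numeric, echo times in ms; strictly increasing, one per
#'   echo image.
#' @param voxel_size numeric length-3, mm.
#'
#' @return An object of class `multi_echo_volume`.
#' @export
multi_echo_volume <- function(data, echo_times, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4-D array (x, y, z, echo).")
  }
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 2L) abort("At least 2 echoes are required.")
  if (any(!is.finite(echo_times)) || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    abort("`echo_times` must be positive and strictly increasing (ms).")
  }
  if (dim(data)[4] != length(echo_times)) {
    abort("Number of echo images must match `length(echo_times)`.")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(
    list(data = data, echo_times = echo_times, voxel_size = voxel_size),
    class = "multi_echo_volume"
  )
}

#' @export
print.multi_echo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<multi_echo_volume> %d x %d x %d voxels, %d echoes (TE %s ms)\n",
    d[1], d[2], d[3], d[4], paste(format(x$echo_times), collapse = ", ")
  ))
  invisible(x)
}
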