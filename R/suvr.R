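#' PET intensity normalisation to SUVR by global mean scaling
#'
#' Divides each in-mask voxel by the mean uptake over the mask, yielding a
#' standardised uptake value ratio (SUVR) map whose in-mask mean is exactly 1.
#' This cancels injected dose, body weight and scanner scaling, so the result
#' is invariant to any positive rescaling of the input. Out-of-mask voxels are
#' invalid in the output.
#'
#' @param pet A [scalar_map()] of PET uptake (non-negative, arbitrary units).
#' @param brain_mask 3-D logical array defining the global reference region
#'   (typically the whole brain); `NULL` uses every valid voxel.
#'
#' @return A [scalar_map()] with modality `"SUVR"`.
#' @export
compute_suvr <- function(pet, brain_mask = NULL) {
  stopifnot(inherits(pet, "scalar_map"))
  if (is.null(brain_mask)) brain_mask <- valid_mask(pet)
  if (!identical(as.integer(dim(brain_mask)), as.integer(dim(pet$data)))) {
    abort("`brain_mask` shape must match the PET grid.")
  }
  use <- brain_mask & valid_mask(pet)
  if (!any(use)) abort("Empty reference mask: no valid in-mask PET voxels.")
  vals <- pet$data[use]
  if (any(vals < 0)) abort("PET uptake must be non-negative.")
  gm <- mean(vals)
  if (gm <= 0) abort("Global mean uptake is not positive; cannot scale.")
  out <- array(NA_real_, dim(pet$data))
  out[use] <- vals / gm
  scalar_map(out, pet$voxel_size, "SUVR")
}
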