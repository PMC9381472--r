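#' Write a scalar map, multi-echo volume or label array as NIfTI-1
#'
#' Scalar maps are written with `NA` voxels stored as `NaN`; multi-echo
#' volumes are written 4-D with the echo times (ms) in a JSON sidecar next to
#' the image (`<basename>.json`, field `"EchoTimesMs"`). Voxel sizes go into
#' the NIfTI header.
#'
#' @param x A [scalar_map()], [multi_echo_volume()] or integer label array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel size for bare arrays, mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "scalar_map")) {
    img <- RNifti::asNifti(structure(x$data, pixdim = x$voxel_size),
                           datatype = "float")
  } else if (inherits(x, "multi_echo_volume")) {
    img <- RNifti::asNifti(structure(x$data, pixdim = c(x$voxel_size, 1)),
                           datatype = "float")
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(EchoTimesMs = x$echo_times), sidecar,
                         auto_unbox = FALSE, digits = NA)
  } else if (is.array(x)) {
    img <- RNifti::asNifti(structure(x + 0L, pixdim = voxel_size),
                           datatype = "int16")
  } else {
    abort("Unsupported object type for NIfTI output.")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a NIfTI-1 volume as a scalar map or multi-echo volume
#'
#' 3-D images are returned as a [scalar_map()] (`NaN`s become invalid
#' voxels). 4-D images are interpreted as multi-echo series and require a
#' JSON sidecar (`<basename>.json` with field `"EchoTimesMs"`) listing one
#' echo time per volume; a missing or mismatched sidecar is an error. When
#' the header carries an interpretable orientation whose first axis runs
#' left-to-right in world space (orientation string starting "L", i.e. left
#' at high indices), the first axis is flipped so that, as everywhere in
#' this package, the left hemisphere sits at lower first-axis indices.
#'
#' @param path NIfTI file path.
#' @param modality modality tag for scalar maps.
#' @return A [scalar_map()] or [multi_echo_volume()].
#' @export
read_volume <- function(path, modality = "T2") {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)
  arr <- array(as.vector(as.array(img)), dim(img))  # drop RNifti attributes
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orient) && nzchar(orient)) {
    first <- substr(orient, 1, 1)
    if (!first %in% c("L", "R")) {
      abort(sprintf("Unsupported orientation '%s': first axis must be L/R.", orient))
    }
    if (first == "L") {
      idx <- rev(seq_len(dim(arr)[1]))
      arr <- if (length(dim(arr)) == 4L) arr[idx, , , , drop = FALSE] else arr[idx, , , drop = FALSE]
    }
  }
  nd <- length(dim(arr))
  if (nd == 3L) {
    arr[!is.finite(arr)] <- NA_real_
    scalar_map(arr, vs[1:3], modality)
  } else if (nd == 4L) {
    sidecar <- .sidecar_path(path)
    if (!file.exists(sidecar)) {
      abort(sprintf("Missing echo-time sidecar '%s' for 4-D volume.", sidecar))
    }
    te <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$EchoTimesMs
    if (is.null(te) || length(te) != dim(arr)[4]) {
      abort(sprintf(
        "Sidecar lists %d echo times for %d echo volumes.",
        length(te), dim(arr)[4]
      ))
    }
    multi_echo_volume(arr, te, vs[1:3])
  } else {
    abort("Only 3-D or 4-D NIfTI volumes are supported.")
  }
}
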