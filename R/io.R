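#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (plain or gzipped) into a [volume()]. Only
#' axis-aligned affines are accepted: the rotation part of the sform/qform
#' must be a permutation of scaled axes; volumes are returned in the array
#' order stored in the file with spacing taken from the affine column norms.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param semantic value semantic to attach, see [volume()].
#' @return a `zteac_volume`.
#' @export
read_volume <- function(path, semantic = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(d), " dimensions")
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  colnorm <- sqrt(colSums(rot^2))
  dircos <- sweep(rot, 2, pmax(colnorm, 1e-12), "/")
  if (any(abs(abs(dircos) - (abs(dircos) > 0.5)) > 1e-4) ||
      any(colSums(abs(dircos) > 0.5) != 1))
    stop("non-axis-aligned affine in ", path,
         ": reorient the volume to a canonical axis-aligned grid first")
  spacing <- RNifti::pixdim(img)[1:3]
  volume(array(as.numeric(img), dim = d), spacing = spacing,
         semantic = semantic)
}

#' Write a 3D volume as NIfTI
#'
#' Values are stored as 64-bit floats so a write/read round trip preserves
#' them bit-exactly; spacing is written into the pixdim/affine.
#'
#' @param vol a `zteac_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  arr <- vol$data
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
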