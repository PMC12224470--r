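#' Read a 4D NIfTI volume stack
#'
#' Thin wrapper around RNifti returning the voxel data, the 4x4 affine and the
#' voxel size. Data and affine round-trip losslessly within float precision.
#'
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param require_4d error if the image is not 4-dimensional.
#' @return A list of class `volume_stack` with `data` (4D array), `affine`
#'   (4x4 matrix) and `voxel_size` (length-3, mm).
#' @export
read_nifti_stack <- function(path, require_4d = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (require_4d && length(dim(arr)) != 4)
    stop("expected a 4D volume, got ", length(dim(arr)), "D: ", path)
  structure(list(data = arr,
                 affine = structure(RNifti::xform(img), class = "matrix",
                                    dimnames = NULL)[1:4, 1:4],
                 voxel_size = RNifti::pixdim(img)[1:3]),
            class = "volume_stack")
}

#' Write a 4D NIfTI volume stack
#'
#' @param stack a `volume_stack` (or plain array).
#' @param path output path.
#' @export
write_nifti_stack <- function(stack, path) {
  if (inherits(stack, "volume_stack")) {
    img <- RNifti::asNifti(stack$data)
    if (!is.null(stack$affine))
      RNifti::qform(img) <- structure(stack$affine, code = 2L)
  } else img <- RNifti::asNifti(as.array(stack))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a volume stack from an array
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 spatial transform (default: identity scaled by voxel size).
#' @param voxel_size length-3 voxel size in mm.
#' @return A `volume_stack`.
#' @export
volume_stack <- function(data, affine = NULL, voxel_size = c(2, 2, 2)) {
  data <- as.array(data)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(list(data = data, affine = affine, voxel_size = voxel_size),
            class = "volume_stack")
}

# Flatten a 4D stack into a (volumes x voxels) signal matrix together with the
# voxel index grid, optionally restricted to a mask.
stack_to_signals <- function(stack, mask = NULL) {
  d <- dim(stack$data)
  if (length(d) != 4) stop("expected a 4D volume stack")
  nvox <- prod(d[1:3])
  sig <- t(matrix(stack$data, nrow = nvox, ncol = d[4]))
  if (is.null(mask)) mask <- rep(TRUE, nvox) else mask <- as.vector(mask)
  list(signals = sig[, mask, drop = FALSE], mask = mask, dim = d[1:3])
}

# Inverse of stack_to_signals for a single parameter map.
map_to_stack <- function(values, mask, dim3, affine = NULL,
                         voxel_size = c(2, 2, 2), background = 0) {
  full <- rep(background, prod(dim3))
  full[mask] <- values
  volume_stack(array(full, dim3), affine = affine, voxel_size = voxel_size)
}
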