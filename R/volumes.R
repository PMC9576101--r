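#' Hounsfield-unit volume
#'
#' A 3-D voxel array of CT values in Hounsfield units with grid spacing in mm.
#' Masks are represented the same way with integer labels
#' ([label_volume()]); density outputs carry units and calibration
#' provenance ([density_volume()]).
#'
#' @param voxels numeric 3-D array of HU values.
#' @param spacing numeric length-3 voxel spacing in mm (all positive).
#' @return object of class `hu_volume` (an array with attributes).
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1)) {
  .new_volume(voxels, spacing, "hu_volume")
}

#' Integer label volume (ROI mask)
#'
#' @param voxels integer 3-D array; 0 = background.
#' @param spacing voxel spacing in mm.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1)) {
  v <- .new_volume(voxels, spacing, "label_volume")
  storage.mode(v) <- "integer"
  v
}

#' Water-equivalent density volume
#'
#' @param voxels numeric 3-D array of densities.
#' @param spacing voxel spacing in mm.
#' @param units unit string, `"g/cm^3"` for water-equivalent density or
#'   `"mgHA/cm^3"` for hydroxyapatite-equivalent output.
#' @param provenance free-form list describing the calibration that produced
#'   the volume (kept for report writing).
#' @return object of class `density_volume`.
#' @export
density_volume <- function(voxels, spacing = c(1, 1, 1), units = "g/cm^3",
                           provenance = NULL) {
  v <- .new_volume(voxels, spacing, "density_volume")
  attr(v, "units") <- units
  attr(v, "provenance") <- provenance
  v
}

.new_volume <- function(voxels, spacing, class) {
  if (is.null(dim(voxels))) dim(voxels) <- c(length(voxels), 1L, 1L)
  if (length(dim(voxels)) != 3)
    qct_stop("volumes must be 3-D arrays", "qct_input_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    qct_stop("spacing must be three positive numbers (mm)", "qct_input_error")
  structure(voxels, spacing = spacing, class = class)
}

#' @export
print.hu_volume <- function(x, ...) .print_volume(x, "HU")
#' @export
print.density_volume <- function(x, ...) .print_volume(x, attr(x, "units"))
#' @export
print.label_volume <- function(x, ...) {
  .print_volume(x, sprintf("labels {%s}", paste(sort(unique(as.vector(x[x != 0]))),
                                                collapse = ",")))
}

.print_volume <- function(x, what) {
  d <- dim(x); s <- attr(x, "spacing")
  cat(sprintf("<%s: %dx%dx%d voxels, %.3gx%.3gx%.3g mm, %s, range [%.4g, %.4g]>\n",
              class(x)[1], d[1], d[2], d[3], s[1], s[2], s[3], what,
              min(x), max(x)))
  invisible(x)
}

#' Volume spacing accessor
#' @param x a volume object.
#' @return numeric length-3 spacing in mm.
#' @export
voxel_spacing <- function(x) attr(x, "spacing")

#' Read a NIfTI volume as Hounsfield units
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return an [hu_volume()].
#' @export
read_hu_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hu_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' Read a NIfTI integer label mask
#' @param path NIfTI file.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(round(as.array(img)), spacing = RNifti::pixdim(img)[1:3])
}

#' Write a volume to NIfTI
#'
#' Density volumes are written as float32; label volumes as int16.
#'
#' @param vol an `hu_volume`, `density_volume` or `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- array(as.vector(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_spacing(vol)
  datatype <- if (inherits(vol, "label_volume")) "int16" else "float"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
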