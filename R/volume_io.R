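#' CT volume container
#'
#' A CT volume holds a 3D grid of Hounsfield units (HU) indexed `(z, y, x)` —
#' the slice (axial) axis first — together with the voxel spacing
#' `(dz, dy, dx)` in millimetres. HU values are clipped to the 12-bit scanner
#' range `[-1024, 3071]` on construction.
#'
#' @param voxels numeric 3D array of HU values indexed `(z, y, x)`.
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in mm, all positive.
#' @param meta optional list of opaque metadata (origin, orientation, ...)
#'   passed through unchanged by I/O.
#' @return An object of class `ct_volume`.
#' @examples
#' ct <- ct_volume(array(-1024, c(4, 8, 8)), spacing = c(5, 1, 1))
#' dim(ct$voxels)
#' @export
ct_volume <- function(voxels, spacing, meta = list()) {
  if (length(dim(voxels)) != 3L) bc_stop("voxels must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    bc_stop("spacing must be three strictly positive numbers (dz, dy, dx)")
  storage.mode(voxels) <- "double"
  voxels <- clip_hu(voxels)
  structure(list(voxels = voxels, spacing = spacing, meta = meta),
            class = "ct_volume")
}

#' Clip Hounsfield units to the 12-bit scanner range
#'
#' Values are clipped to `[-1024, 3071]`. The operation is idempotent.
#'
#' @param x numeric vector or array of HU values.
#' @return `x` with values clipped.
#' @export
clip_hu <- function(x) {
  x[x < BC_HU_MIN] <- BC_HU_MIN
  x[x > BC_HU_MAX] <- BC_HU_MAX
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z, y, x), spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range: [%d, %d]\n", as.integer(min(x$voxels)), as.integer(max(x$voxels))))
  invisible(x)
}

#' Label map container
#'
#' A label map assigns each voxel of a paired [ct_volume()] one of six region
#' codes, or the ignore code for unannotated voxels:
#' 0 = background, 1 = muscle, 2 = bones, 3 = subcutaneous tissue,
#' 4 = abdominal cavity, 5 = thoracic cavity, 255 = ignore.
#'
#' @param labels integer 3D array indexed `(z, y, x)`.
#' @param spacing numeric `(dz, dy, dx)` in mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing) {
  if (length(dim(labels)) != 3L) bc_stop("labels must be a 3D array (z, y, x)")
  storage.mode(labels) <- "integer"
  bc_assert_codes(labels)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    bc_stop("spacing must be three strictly positive numbers (dz, dy, dx)")
  structure(list(labels = labels, spacing = spacing), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = c(BC_CODES, BC_IGNORE),
                      labels = c(names(BC_CODES), "ignore")))
  cat(sprintf("<label_map> %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  print(tab)
  invisible(x)
}

#' Read a CT volume
#'
#' Reads a CT volume from a NIfTI file or a DICOM series directory into the
#' package's internal `(z, y, x)` axis order. For DICOM input the stored
#' values are rescaled to HU (`stored * RescaleSlope + RescaleIntercept`);
#' either way HU are clipped to `[-1024, 3071]`.
#'
#' @param path path to a `.nii`/`.nii.gz` file or a directory of DICOM slices.
#' @param format `"nifti"` or `"dicom_dir"`; the default guesses from `path`.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (!file.exists(path)) bc_stop("path does not exist: ", path)
  if (format == "dicom_dir") return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)            # (dx, dy, dz)
  arr <- aperm(as.array(img), c(3, 2, 1))
  ct_volume(arr, spacing = rev(sp[1:3]),
            meta = list(nifti_header = RNifti::niftiHeader(img)))
}

#' Write a CT volume to NIfTI
#'
#' @param ct a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  arr <- aperm(ct$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(ct$spacing)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read or write a label map (NIfTI)
#'
#' Label maps round-trip exactly through NIfTI (uint8 storage; the ignore
#' code 255 is chosen to survive it). Codes outside `{0..5, 255}` are
#' rejected with an error listing the offending codes.
#'
#' @param path a `.nii`/`.nii.gz` path.
#' @return [read_label_map()] returns a [label_map()].
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) bc_stop("path does not exist: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3, 2, 1))
  label_map(arr, spacing = rev(sp[1:3]))
}

#' @rdname read_label_map
#' @param lm a [label_map()].
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  arr <- aperm(lm$labels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(lm$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
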