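#' @title Label volumes
#' @description A `label_volume` is the package's container for a segmented
#'   sagittal MR stack: a 3D integer array indexed `[slice, row, col]` plus
#'   physical voxel spacing. Axis conventions (fixed across the package):
#'   slices run medial to lateral, in-slice rows run superior to inferior, and
#'   in-slice columns run anterior to posterior. Label codes are 0 background,
#'   1 bone, 2 cartilage.
#' @name label_volume
NULL

#  label codes (internal constants)
LBL_BACKGROUND <- 0L
LBL_BONE <- 1L
LBL_CARTILAGE <- 2L

#' Create a label volume
#'
#' @param labels 3D integer array `[slice, row, col]` with codes 0 (background),
#'   1 (bone), 2 (cartilage).
#' @param spacing numeric length 3, `c(dx, dy, dz)` in mm: `dx` along columns
#'   (anterior-posterior), `dy` along rows (superior-inferior), `dz` between
#'   slices (medial-lateral).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array [slice, row, col]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be positive")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing), class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d slices x %d rows x %d cols, spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- table(factor(x$labels, levels = 0:2,
                      labels = c("background", "bone", "cartilage")))
  print(tab)
  invisible(x)
}

#' Write a label volume to NIfTI
#'
#' Voxel spacing is stored in the NIfTI header (`pixdim`), in array-dimension
#' order `(dz, dy, dx)` since dimension 1 of the array is the slice axis.
#'
#' @param vol a [label_volume].
#' @param path output path, typically ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- vol$spacing[c(3L, 2L, 1L)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @param path a NIfTI file written by [write_label_volume()] (or any label
#'   image following the same axis conventions).
#' @return A [label_volume].
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  label_volume(array(as.integer(img), dim = dim(img)), spacing = sp[c(3L, 2L, 1L)])
}

# physical coordinate of a 1-based index along an axis with spacing s (mm)
vox_coord <- function(i, s) (i - 1) * s
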