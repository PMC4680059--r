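#' @title Rectangular universal surface coordinates
#' @description One articular surface (distal lateral femur or proximal
#'   lateral tibia) is flattened to a rectangular coordinate system:
#'   the v axis (0 = most medial, 1 = most lateral) spans the slices that
#'   contain bone; the u axis (0 = most anterior, 1 = most posterior) spans
#'   each slice's own bone-cartilage boundary, normalized per slice so that a
#'   slice's anterior and posterior boundary extremes map to 0 and 1.
#' @name coords
NULL

#' Find the bounding (most medial / most lateral) slices containing bone
#'
#' @param volume a [label_volume].
#' @param min_bone_voxels minimum number of bone voxels for a slice to count
#'   (guards against stray labels).
#' @return Integer length 2: `c(medial_slice, lateral_slice)` (1-based).
#' @export
find_bounding_slices <- function(volume, min_bone_voxels = 1L) {
  stopifnot(inherits(volume, "label_volume"))
  counts <- apply(volume$labels == LBL_BONE, 1L, sum)
  idx <- which(counts >= min_bone_voxels)
  if (length(idx) == 0L) stop("empty volume: no bone found")
  if (min(idx) == max(idx)) stop("degenerate medial-lateral extent: bone confined to a single slice")
  c(medial_slice = min(idx), lateral_slice = max(idx))
}

#' Extract the bone-cartilage boundary of one slice
#'
#' For every in-slice column where bone is present, takes the bone voxel
#' facing the articular side (`"superior"`: smallest row, for the tibial
#' plateau; `"inferior"`: largest row, for the femoral condyle). Only the
#' largest contiguous run of columns is kept, ordered anterior to posterior.
#'
#' @param volume a [label_volume].
#' @param slice 1-based slice index.
#' @param side `"superior"` or `"inferior"`; which side of the bone is the
#'   articular surface.
#' @return A data.frame with columns `col`, `row` (1-based voxel indices),
#'   ordered by increasing `col`.
#' @export
extract_boundary <- function(volume, slice, side = c("superior", "inferior")) {
  side <- match.arg(side)
  m <- volume$labels[slice, , ]
  bone_cols <- which(apply(m == LBL_BONE, 2L, any))
  if (length(bone_cols) == 0L) stop(sprintf("no bone in slice %d", slice))
  # largest contiguous run of bone-bearing columns
  runs <- split(bone_cols, cumsum(c(1L, diff(bone_cols) != 1L)))
  lens <- lengths(runs)
  keep <- runs[[which.max(lens)]]
  if (length(keep) < 3L) stop(sprintf("degenerate boundary in slice %d", slice))
  rows <- vapply(keep, function(cc) {
    b <- which(m[, cc] == LBL_BONE)
    if (side == "superior") min(b) else max(b)
  }, integer(1))
  data.frame(col = keep, row = rows)
}

#' Build the surface coordinate frame for a volume
#'
#' @param volume a [label_volume].
#' @param side articular side, see [extract_boundary()].
#' @param min_bone_voxels see [find_bounding_slices()].
#' @return An object of class `surface_frame`: bounding slices, the per-slice
#'   boundary point lists, and per-slice anterior/posterior extreme columns.
#'   Slices within the bounding range whose boundary is degenerate are stored
#'   as `NULL` and cannot host measurements.
#' @export
build_surface_frame <- function(volume, side = c("superior", "inferior"),
                                min_bone_voxels = 1L) {
  side <- match.arg(side)
  bs <- find_bounding_slices(volume, min_bone_voxels)
  slices <- seq(bs[1], bs[2])
  boundaries <- vector("list", length(slices))
  names(boundaries) <- as.character(slices)
  for (i in seq_along(slices)) {
    b <- tryCatch(extract_boundary(volume, slices[i], side), error = function(e) NULL)
    boundaries[[i]] <- b
  }
  structure(list(side = side,
                 medial_slice = unname(bs[1]), lateral_slice = unname(bs[2]),
                 boundaries = boundaries,
                 spacing = volume$spacing),
            class = "surface_frame")
}

#' @export
print.surface_frame <- function(x, ...) {
  cat(sprintf("<surface_frame> side=%s slices %d..%d (%d with boundary)\n",
              x$side, x$medial_slice, x$lateral_slice,
              sum(!vapply(x$boundaries, is.null, logical(1)))))
  invisible(x)
}

frame_boundary <- function(frame, slice) {
  b <- frame$boundaries[[as.character(slice)]]
  if (is.null(b)) stop(sprintf("no valid boundary stored for slice %d", slice))
  b
}

#' Map v in [0,1] to a slice index
#'
#' Linear interpolation between the bounding slices; rounding ties go toward
#' the lateral slice.
#'
#' @param v medial-lateral coordinate in `[0, 1]`.
#' @param frame a `surface_frame`.
#' @return 1-based slice index.
#' @export
slice_for_v <- function(v, frame) {
  if (any(v < 0 | v > 1)) stop("v must lie in [0, 1]")
  as.integer(floor(frame$medial_slice + v * (frame$lateral_slice - frame$medial_slice) + 0.5))
}

#' Map a slice index to v
#' @param slice 1-based slice index within the bounding range.
#' @param frame a `surface_frame`.
#' @return v in `[0, 1]`.
#' @export
v_for_slice <- function(slice, frame) {
  if (any(slice < frame$medial_slice | slice > frame$lateral_slice))
    stop("slice outside the medial-lateral bounding range")
  (slice - frame$medial_slice) / (frame$lateral_slice - frame$medial_slice)
}

#' Map an in-slice column to u
#'
#' u is normalized per slice: the slice's own anterior and posterior boundary
#' extremes map to 0 and 1.
#'
#' @param col 1-based column index.
#' @param frame a `surface_frame`.
#' @param slice 1-based slice index.
#' @return u in `[0, 1]`.
#' @export
u_for_point <- function(col, frame, slice) {
  b <- frame_boundary(frame, slice)
  a <- min(b$col); p <- max(b$col)
  if (any(col < a | col > p)) stop("off-surface: column outside the boundary extent")
  (col - a) / (p - a)
}

#' Map u to the nearest boundary column of a slice
#' @param u anterior-posterior coordinate in `[0, 1]`.
#' @param frame a `surface_frame`.
#' @param slice 1-based slice index.
#' @return 1-based column index (rounding ties toward posterior).
#' @export
col_for_u <- function(u, frame, slice) {
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  b <- frame_boundary(frame, slice)
  a <- min(b$col); p <- max(b$col)
  as.integer(floor(a + u * (p - a) + 0.5))
}

#' Write a surface frame to JSON
#' @param frame a `surface_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_frame <- function(frame, path) {
  obj <- list(side = frame$side,
              medial_slice = frame$medial_slice,
              lateral_slice = frame$lateral_slice,
              spacing = frame$spacing,
              boundaries = lapply(frame$boundaries, function(b)
                if (is.null(b)) NULL else list(col = b$col, row = b$row)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a surface frame from JSON
#' @param path a file written by [write_surface_frame()].
#' @return A `surface_frame`.
#' @export
read_surface_frame <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  boundaries <- lapply(obj$boundaries, function(b)
    if (is.null(b) || length(b) == 0L) NULL
    else data.frame(col = as.integer(b$col), row = as.integer(b$row)))
  structure(list(side = obj$side,
                 medial_slice = as.integer(obj$medial_slice),
                 lateral_slice = as.integer(obj$lateral_slice),
                 boundaries = boundaries,
                 spacing = as.numeric(obj$spacing)),
            class = "surface_frame")
}
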