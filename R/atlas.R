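#' @title Denudation frequency atlas and informative locations
#' @description Denudation annotations from many knees are projected into the
#'   surface's (u, v) coordinate system, binned on a cell grid, and summed
#'   into a frequency map. The 9 informative measurement locations per
#'   surface are then placed as an even 3 x 3 grid over the region that most
#'   frequently exhibits denudation: threshold the map, keep the
#'   highest-count connected component (8-connectivity), dilate its bounding
#'   box by a margin, and partition that box evenly.
#' @name atlas
NULL

#' Project denuded boundary points into (u, v) cells
#'
#' Accepts either a 3D 0/1 denudation mask (same dims as the label volume the
#' frame was built from) or a data.frame of boundary points with columns
#' `slice` and `col`. Each point maps to v via its slice and to u via its
#' column within that slice's boundary extremes; cells are half-open
#' (`u = 1`, `v = 1` fall in the last cell).
#'
#' @param x denudation mask array or data.frame with `slice`, `col`.
#' @param frame a `surface_frame`.
#' @param grid integer length 2, `(n_u, n_v)` cells (default `c(100, 100)`).
#' @return Logical `n_u x n_v` matrix; `[iu, iv]` is `TRUE` iff at least one
#'   denuded point maps into that cell. An empty mask yields all-`FALSE`.
#' @export
project_denudation <- function(x, frame, grid = c(100L, 100L)) {
  grid <- as.integer(grid)
  if (is.array(x) && length(dim(x)) == 3L) {
    idx <- which(x != 0, arr.ind = TRUE)
    pts <- data.frame(slice = idx[, 1], col = idx[, 3])
  } else {
    pts <- as.data.frame(x)
    stopifnot(all(c("slice", "col") %in% names(pts)))
  }
  mask <- matrix(FALSE, grid[1], grid[2])
  if (nrow(pts) == 0L) return(mask)
  keep <- pts$slice >= frame$medial_slice & pts$slice <= frame$lateral_slice
  pts <- pts[keep, , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    s <- pts$slice[i]
    b <- frame$boundaries[[as.character(s)]]
    if (is.null(b)) next
    a <- min(b$col); p <- max(b$col)
    if (pts$col[i] < a || pts$col[i] > p) next
    u <- (pts$col[i] - a) / (p - a)
    v <- v_for_slice(s, frame)
    iu <- min(floor(u * grid[1]), grid[1] - 1L) + 1L
    iv <- min(floor(v * grid[2]), grid[2] - 1L) + 1L
    mask[iu, iv] <- TRUE
  }
  mask
}

#' Mark the (u, v) cells covered by lesion rectangles
#'
#' Fast-mode counterpart of [project_denudation()]: bins full-thickness
#' lesion rectangles directly, without a voxel volume. A cell is marked iff
#' its half-open extent intersects a depth-1 lesion rectangle.
#'
#' @param lesions list of [lesion_spec()] objects.
#' @param grid integer length 2, `(n_u, n_v)`.
#' @return Logical `n_u x n_v` matrix.
#' @export
lesion_cell_mask <- function(lesions, grid = c(100L, 100L)) {
  grid <- as.integer(grid)
  mask <- matrix(FALSE, grid[1], grid[2])
  centers_u <- (seq_len(grid[1]) - 0.5) / grid[1]
  centers_v <- (seq_len(grid[2]) - 0.5) / grid[2]
  lo_u <- (seq_len(grid[1]) - 1) / grid[1]; hi_u <- seq_len(grid[1]) / grid[1]
  lo_v <- (seq_len(grid[2]) - 1) / grid[2]; hi_v <- seq_len(grid[2]) / grid[2]
  for (ls in lesions) {
    if (ls$depth_fraction < 1) next
    r <- ls$rect
    iu <- which(hi_u > r["u_lo"] & lo_u < r["u_hi"])
    iv <- which(hi_v > r["v_lo"] & lo_v < r["v_hi"])
    mask[iu, iv] <- TRUE
  }
  mask
}

#' Accumulate per-knee cell masks into a frequency map
#'
#' @param masks list of logical `n_u x n_v` matrices, one per knee, all of the
#'   same shape.
#' @param surface `"femur"` or `"tibia"` (recorded).
#' @return An object of class `frequency_map`: integer `counts` matrix
#'   (`counts[iu, iv]` = number of knees marking that cell), `n_knees`,
#'   `surface`, `grid`.
#' @export
accumulate_frequency <- function(masks, surface = c("femur", "tibia")) {
  surface <- match.arg(surface)
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1))))
    stop("all masks must share the same grid shape")
  counts <- Reduce(`+`, lapply(masks, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  structure(list(counts = counts, n_knees = length(masks),
                 surface = surface, grid = d),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> %s, %d x %d cells, %d knees, max count %d\n",
              x$surface, x$grid[1], x$grid[2], x$n_knees, max(x$counts)))
  invisible(x)
}

# 8-connected component labeling of a logical matrix (small grids; BFS).
# EBImage::bwlabel is 4-connected, hence this dedicated labeler.
label_components8 <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% d[1] + 1L
      j <- (cur - 1L) %/% d[1] + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > d[1] || jj < 1L || jj > d[2]) next
        k <- (jj - 1L) * d[1] + ii
        if (mask[k] && lab[k] == 0L) {
          lab[k] <- nxt
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

#' Select the informative measurement locations from a frequency map
#'
#' Operationalizes "evenly select 9 locations in and around the most
#' frequently denuded region": (1) threshold the map at a quantile of its
#' positive counts; (2) keep the 8-connected component with the largest total
#' count (ties go to the more posterior component, i.e. larger mean u);
#' (3) dilate the component's bounding box by `margin_uv`, clipped to
#' `[0,1]^2`; (4) partition the box into an even `grid_shape` grid and place
#' one location at each cell center.
#'
#' @param freq a `frequency_map`.
#' @param threshold_quantile quantile of positive counts used as the
#'   hotspot threshold (default 0.75).
#' @param margin_uv bounding-box dilation in (u, v) units (default 0.05).
#' @param grid_shape integer length 2, locations per axis (default `c(3, 3)`,
#'   i.e. 9 locations).
#' @return An object of class `location_set`: `surface`, `grid_shape`,
#'   `box` (`u_lo, u_hi, v_lo, v_hi`), `locations` (data.frame `u`, `v`) and
#'   `cells` (data.frame `u_lo, u_hi, v_lo, v_hi`, one half-open rectangle per
#'   location, tiling the box).
#' @export
select_informative_locations <- function(freq, threshold_quantile = 0.75,
                                         margin_uv = 0.05,
                                         grid_shape = c(3L, 3L)) {
  stopifnot(inherits(freq, "frequency_map"))
  grid_shape <- as.integer(grid_shape)
  pos <- freq$counts[freq$counts > 0]
  if (length(pos) == 0L) stop("no denudation observed: frequency map is all zero")
  thr <- stats::quantile(pos, threshold_quantile, names = FALSE)
  mask <- freq$counts >= thr
  lab <- label_components8(mask)
  ncomp <- max(lab)
  totals <- vapply(seq_len(ncomp), function(k) sum(freq$counts[lab == k]), numeric(1))
  best <- which(totals == max(totals))
  if (length(best) > 1L) {
    # tie-break: more posterior component (larger mean u of its cells)
    mean_u <- vapply(best, function(k) {
      ij <- which(lab == k, arr.ind = TRUE)
      mean((ij[, 1] - 0.5) / freq$grid[1])
    }, numeric(1))
    best <- best[which.max(mean_u)]
  }
  ij <- which(lab == best, arr.ind = TRUE)
  box <- c(u_lo = (min(ij[, 1]) - 1) / freq$grid[1],
           u_hi = max(ij[, 1]) / freq$grid[1],
           v_lo = (min(ij[, 2]) - 1) / freq$grid[2],
           v_hi = max(ij[, 2]) / freq$grid[2])
  box <- c(u_lo = max(0, box[["u_lo"]] - margin_uv),
           u_hi = min(1, box[["u_hi"]] + margin_uv),
           v_lo = max(0, box[["v_lo"]] - margin_uv),
           v_hi = min(1, box[["v_hi"]] + margin_uv))
  out <- location_set_from_box(freq$surface, box, grid_shape)
  out$threshold_quantile <- threshold_quantile
  out$margin_uv <- margin_uv
  out
}

#' Build a location set as the even partition of a (u, v) box
#'
#' Places `grid_shape[1] x grid_shape[2]` locations at the cell centers of an
#' even partition of the box. [select_informative_locations()] uses this for
#' its final step; it is also handy for constructing fixed location sets.
#'
#' @param surface `"femur"` or `"tibia"`.
#' @param box named numeric `(u_lo, u_hi, v_lo, v_hi)` within `[0,1]^2`.
#' @param grid_shape integer length 2 (default `c(3, 3)`).
#' @return A `location_set`.
#' @export
location_set_from_box <- function(surface, box, grid_shape = c(3L, 3L)) {
  grid_shape <- as.integer(grid_shape)
  nu <- grid_shape[1]; nv <- grid_shape[2]
  eu <- seq(box[["u_lo"]], box[["u_hi"]], length.out = nu + 1L)
  ev <- seq(box[["v_lo"]], box[["v_hi"]], length.out = nv + 1L)
  cu <- (eu[-1] + eu[-(nu + 1L)]) / 2
  cv <- (ev[-1] + ev[-(nv + 1L)]) / 2
  locations <- expand.grid(u = cu, v = cv, KEEP.OUT.ATTRS = FALSE)
  cells <- expand.grid(iu = seq_len(nu), iv = seq_len(nv), KEEP.OUT.ATTRS = FALSE)
  cells <- data.frame(u_lo = eu[cells$iu], u_hi = eu[cells$iu + 1L],
                      v_lo = ev[cells$iv], v_hi = ev[cells$iv + 1L])
  structure(list(surface = surface, grid_shape = grid_shape,
                 box = box[c("u_lo", "u_hi", "v_lo", "v_hi")],
                 locations = locations, cells = cells),
            class = "location_set")
}

#' @export
print.location_set <- function(x, ...) {
  cat(sprintf("<location_set> %s, %d locations in u[%.3f, %.3f] x v[%.3f, %.3f]\n",
              x$surface, nrow(x$locations),
              x$box[["u_lo"]], x$box[["u_hi"]], x$box[["v_lo"]], x$box[["v_hi"]]))
  invisible(x)
}

#' Write a location set (atlas) to JSON
#' @param locset a `location_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_location_set <- function(locset, path) {
  obj <- list(surface = locset$surface,
              grid_shape = locset$grid_shape,
              box = as.list(locset$box),
              locations = locset$locations,
              cells = locset$cells,
              threshold_quantile = locset$threshold_quantile,
              margin_uv = locset$margin_uv)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a location set from JSON
#' @param path a file written by [write_location_set()].
#' @return A `location_set`.
#' @export
read_location_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(surface = obj$surface,
                 grid_shape = as.integer(obj$grid_shape),
                 box = unlist(obj$box),
                 locations = as.data.frame(obj$locations),
                 cells = as.data.frame(obj$cells),
                 threshold_quantile = obj$threshold_quantile,
                 margin_uv = obj$margin_uv),
            class = "location_set")
}

#' Write a frequency map as a CSV grid
#' @param freq a `frequency_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_map <- function(freq, path) {
  utils::write.csv(as.data.frame(freq$counts), path, row.names = FALSE)
  invisible(path)
}

#' Render a frequency map heat map to PNG
#' @param freq a `frequency_map`.
#' @param path output PNG path.
#' @param locset optional `location_set` to overlay.
#' @return `path`, invisibly.
#' @export
plot_frequency_map <- function(freq, path, locset = NULL) {
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  u <- (seq_len(freq$grid[1]) - 0.5) / freq$grid[1]
  v <- (seq_len(freq$grid[2]) - 0.5) / freq$grid[2]
  graphics::image(u, v, freq$counts,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "u (anterior → posterior)",
                  ylab = "v (medial → lateral)",
                  main = sprintf("Denudation frequency, %s (%d knees)",
                                 freq$surface, freq$n_knees))
  if (!is.null(locset))
    graphics::points(locset$locations$u, locset$locations$v, pch = 3, cex = 1.4)
  invisible(path)
}
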