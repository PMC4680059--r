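#' @title Synthetic knee phantoms
#' @description Phantom generator for one articular surface of the lateral
#'   tibiofemoral compartment. The femoral condyle is modeled as a cylindrical
#'   cap (bone inside a cylinder whose axis runs medial-lateral; cartilage on
#'   the inferior arc), the tibial plateau as a shallow elliptic dish (bone
#'   below a gently curved top surface; cartilage above). Cartilage local
#'   thickness along the outward surface normal equals
#'   `thickness_field(u, v) * (1 - lesion depth)`, where `(u, v)` is the
#'   surface's rectangular universal coordinate system (u: anterior->posterior
#'   within slice, v: medial->lateral across slices). Default voxel geometry
#'   follows a 3D sagittal DESS acquisition: 0.365 x 0.456 x 0.7 mm voxels,
#'   307 x 384 in-plane matrix, 160 slices.
#' @name phantom
NULL

#' Specify a focal cartilage lesion
#'
#' Lesions are axis-aligned rectangles in (u, v) surface coordinates,
#' half-open on the upper edges: a point is inside iff
#' `u_lo <= u < u_hi` and `v_lo <= v < v_hi`. `depth_fraction = 1` is
#' full-thickness denudation (bare bone).
#'
#' @param center_uv numeric length 2, lesion center in `[0,1]^2`.
#' @param extent_uv numeric length 2, full widths `(du, dv)`.
#' @param depth_fraction fraction of local thickness removed, in `[0, 1]`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_uv, extent_uv, depth_fraction = 1) {
  center_uv <- as.numeric(center_uv); extent_uv <- as.numeric(extent_uv)
  stopifnot(length(center_uv) == 2L, length(extent_uv) == 2L)
  if (any(extent_uv <= 0)) stop("lesion extent must be positive")
  if (depth_fraction < 0 || depth_fraction > 1)
    stop("depth_fraction must lie in [0, 1]")
  rect <- c(u_lo = center_uv[1] - extent_uv[1] / 2,
            u_hi = center_uv[1] + extent_uv[1] / 2,
            v_lo = center_uv[2] - extent_uv[2] / 2,
            v_hi = center_uv[2] + extent_uv[2] / 2)
  if (rect["u_hi"] <= 0 || rect["u_lo"] >= 1 || rect["v_hi"] <= 0 || rect["v_lo"] >= 1)
    stop("lesion rectangle does not intersect the unit square")
  structure(list(center_uv = center_uv, extent_uv = extent_uv,
                 depth_fraction = depth_fraction, rect = rect),
            class = "lesion_spec")
}

#' Specify a single-surface knee phantom
#'
#' @param surface `"femur"` or `"tibia"`.
#' @param n_slices number of sagittal slices (medial to lateral).
#' @param in_plane_shape integer length 2, `(rows, cols)` of each slice.
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm (see [label_volume]).
#' @param base_thickness_mm cartilage thickness (mm) used when
#'   `thickness_field` is `NULL`; may be 0 (no cartilage).
#' @param thickness_field optional vectorized `function(u, v)` returning
#'   thickness in mm over `[0,1]^2`; must be non-negative.
#' @param lesions list of [lesion_spec()] objects.
#' @param seed integer seed (recorded; rasterization itself is deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(surface = c("femur", "tibia"),
                         n_slices = 160L,
                         in_plane_shape = c(307L, 384L),
                         spacing = c(0.365, 0.456, 0.7),
                         base_thickness_mm = 2.2,
                         thickness_field = NULL,
                         lesions = list(),
                         seed = 1L) {
  surface <- match.arg(surface)
  n_slices <- as.integer(n_slices)
  in_plane_shape <- as.integer(in_plane_shape)
  spacing <- as.numeric(spacing)
  if (n_slices < 3L) stop("n_slices must be at least 3")
  if (any(spacing <= 0)) stop("spacing components must be positive")
  if (base_thickness_mm < 0) stop("base_thickness_mm must be non-negative")
  if (is.null(thickness_field)) {
    tb <- base_thickness_mm
    thickness_field <- function(u, v) rep_len(tb, length(u))
  }
  uu <- rep(seq(0, 1, length.out = 51), each = 51)
  vv <- rep(seq(0, 1, length.out = 51), times = 51)
  tprobe <- thickness_field(uu, vv)
  if (any(!is.finite(tprobe)) || any(tprobe < 0))
    stop("thickness_field must be non-negative and finite over [0,1]^2")
  if (!all(vapply(lesions, inherits, logical(1), "lesion_spec")))
    stop("lesions must be a list of lesion_spec objects")
  structure(list(surface = surface, n_slices = n_slices,
                 in_plane_shape = in_plane_shape, spacing = spacing,
                 base_thickness_mm = base_thickness_mm,
                 thickness_field = thickness_field,
                 lesions = lesions, seed = as.integer(seed),
                 max_thickness_mm = max(tprobe)),
            class = "phantom_spec")
}

# fraction of local thickness remaining at (u, v) after lesions
# (overlapping lesions: the deepest wins)
lesion_factor <- function(u, v, lesions) {
  f <- rep_len(1, length(u))
  for (ls in lesions) {
    r <- ls$rect
    inside <- u >= r["u_lo"] & u < r["u_hi"] & v >= r["v_lo"] & v < r["v_hi"]
    f[inside] <- pmin(f[inside], 1 - ls$depth_fraction)
  }
  f
}

# TRUE at (u, v) covered by a full-thickness (depth 1) lesion
is_denuded_uv <- function(u, v, lesions) {
  d <- rep_len(FALSE, length(u))
  for (ls in lesions) {
    if (ls$depth_fraction < 1) next
    r <- ls$rect
    d <- d | (u >= r["u_lo"] & u < r["u_hi"] & v >= r["v_lo"] & v < r["v_hi"])
  }
  d
}

# Analytic surface parameters for a spec. All quantities in mm.
phantom_geometry <- function(spec) {
  nr <- spec$in_plane_shape[1]; nc <- spec$in_plane_shape[2]
  dx <- spec$spacing[1]; dy <- spec$spacing[2]; dz <- spec$spacing[3]
  X <- (nc - 1) * dx; Y <- (nr - 1) * dy; Z <- (spec$n_slices - 1) * dz
  tmax <- spec$max_thickness_mm
  if (spec$surface == "femur") {
    R <- 0.22 * min(X, Y)
    geo <- list(surface = "femur", side = "inferior",
                xc = X / 2, yc = 0.38 * Y, R = R,
                phi_max = 70 * pi / 180,
                z0 = 0.12 * Z, z1 = 0.88 * Z)
    if (geo$yc + R + tmax > Y || geo$xc + (R + tmax) * sin(geo$phi_max) > X ||
        geo$xc - (R + tmax) * sin(geo$phi_max) < 0)
      stop("phantom overflow: cartilage thickness exceeds the volume extent")
  } else {
    rx <- 0.40 * X; rz <- 0.38 * Z
    A <- 0.055 * rx                      # dish depth scales with plateau size
    gmax <- 2 * A / min(rx, rz)          # worst-case surface slope
    cos_min <- 1 / sqrt(1 + gmax^2)
    geo <- list(surface = "tibia", side = "superior",
                xc = X / 2, zc = Z / 2, rx = rx, rz = rz,
                yt = 0.45 * Y, A = A,
                w_min_frac = 0.08,       # min squared half-chord fraction
                y_bottom = min(Y, 0.45 * Y + A + 0.45 * Y))
    if (geo$yt - tmax / cos_min < 0)
      stop("phantom overflow: cartilage thickness exceeds the volume extent")
  }
  geo$X <- X; geo$Y <- Y; geo$Z <- Z
  geo
}

# half-chord of the tibial footprint at medial-lateral position z
tibia_half_chord <- function(z, geo) {
  q <- 1 - ((z - geo$zc) / geo$rz)^2
  geo$rx * sqrt(pmax(geo$w_min_frac, q))
}

# tibial top-surface height (mm, y increases inferiorly) and slope factor
tibia_surface <- function(x, z, geo) {
  q <- pmin(1, ((x - geo$xc) / geo$rx)^2 + ((z - geo$zc) / geo$rz)^2)
  ys <- geo$yt + geo$A * (1 - q)
  gx <- ifelse(q < 1, -2 * geo$A * (x - geo$xc) / geo$rx^2, 0)
  gz <- ifelse(q < 1, -2 * geo$A * (z - geo$zc) / geo$rz^2, 0)
  list(ys = ys, cos_theta = 1 / sqrt(1 + gx^2 + gz^2))
}

#' Rasterize a phantom into a label volume
#'
#' Produces the voxel label volume, a denudation mask marking the articular
#' bone-surface voxels under full-thickness lesions, and a ground-truth record
#' with the analytic cartilage volume (continuum integral of the thickness
#' field over the curved surface, lesions applied).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([label_volume]), `denudation`
#'   (3D 0/1 integer array, same dims), and `truth` (list: `volume_mm3`,
#'   `thickness_at` = `function(u, v)` with lesions applied, `geometry`,
#'   `surface`, `side`).
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  nr <- spec$in_plane_shape[1]; nc <- spec$in_plane_shape[2]
  dx <- spec$spacing[1]; dy <- spec$spacing[2]; dz <- spec$spacing[3]
  ns <- spec$n_slices
  labels <- array(LBL_BACKGROUND, dim = c(ns, nr, nc))
  denud <- array(0L, dim = c(ns, nr, nc))
  xcol <- vox_coord(seq_len(nc), dx)     # anterior -> posterior
  yrow <- vox_coord(seq_len(nr), dy)     # superior -> inferior
  field <- spec$thickness_field

  thick_at <- function(u, v)
    field(u, v) * lesion_factor(u, v, spec$lesions)

  for (s in seq_len(ns)) {
    z <- vox_coord(s, dz)
    if (geo$surface == "femur") {
      if (z < geo$z0 || z > geo$z1) next
      v <- (z - geo$z0) / (geo$z1 - geo$z0)
      xm <- matrix(xcol, nr, nc, byrow = TRUE)
      ym <- matrix(yrow, nr, nc)
      rho <- sqrt((xm - geo$xc)^2 + (ym - geo$yc)^2)
      phi <- atan2(xm - geo$xc, ym - geo$yc)   # 0 = straight inferior
      sl <- matrix(LBL_BACKGROUND, nr, nc)
      sl[rho <= geo$R & ym >= geo$yc] <- LBL_BONE
      onarc <- abs(phi) <= geo$phi_max & rho > geo$R
      if (any(onarc)) {
        u <- (sin(phi) + 1) / 2
        tl <- matrix(0, nr, nc)
        tl[onarc] <- thick_at(u[onarc], rep_len(v, sum(onarc)))
        cart <- onarc & rho <= geo$R + tl
        sl[cart] <- LBL_CARTILAGE
      }
      labels[s, , ] <- sl
      # denudation mask: inferior-most bone voxel per column under depth-1 lesions
      if (length(spec$lesions)) {
        xs <- xcol[abs(xcol - geo$xc) <= geo$R * sin(geo$phi_max)]
        if (length(xs)) {
          uu <- ((xs - geo$xc) / geo$R + 1) / 2
          den <- is_denuded_uv(uu, rep_len(v, length(uu)), spec$lesions)
          for (x in xs[den]) {
            cc <- which.min(abs(xcol - x))
            ysurf <- geo$yc + sqrt(geo$R^2 - (x - geo$xc)^2)
            rr <- max(which(yrow <= ysurf))
            denud[s, rr, cc] <- 1L
          }
        }
      }
    } else {
      if (abs(z - geo$zc) > geo$rz) next
      v <- (z - (geo$zc - geo$rz)) / (2 * geo$rz)
      w <- tibia_half_chord(z, geo)
      incol <- abs(xcol - geo$xc) <= w
      if (!any(incol)) next
      xs <- xcol[incol]; ci <- which(incol)
      surf <- tibia_surface(xs, z, geo)
      u <- (xs - (geo$xc - w)) / (2 * w)
      tl <- thick_at(u, rep_len(v, length(u)))
      sl <- matrix(LBL_BACKGROUND, nr, nc)
      ym <- matrix(yrow, nr, length(ci))
      ysm <- matrix(surf$ys, nr, length(ci), byrow = TRUE)
      ctm <- matrix(surf$cos_theta, nr, length(ci), byrow = TRUE)
      tlm <- matrix(tl, nr, length(ci), byrow = TRUE)
      bone <- ym >= ysm & ym <= geo$y_bottom
      cart <- ym < ysm & (ysm - ym) * ctm <= tlm
      sub <- matrix(LBL_BACKGROUND, nr, length(ci))
      sub[bone] <- LBL_BONE
      sub[cart] <- LBL_CARTILAGE
      sl[, ci] <- sub
      labels[s, , ] <- sl
      if (length(spec$lesions)) {
        den <- is_denuded_uv(u, rep_len(v, length(u)), spec$lesions)
        for (k in which(den)) {
          rr <- min(which(yrow >= surf$ys[k]))
          denud[s, rr, ci[k]] <- 1L
        }
      }
    }
  }

  truth <- list(
    volume_mm3 = phantom_true_volume(spec, geo),
    thickness_at = thick_at,
    geometry = geo,
    surface = spec$surface,
    side = geo$side
  )
  list(volume = label_volume(labels, spec$spacing),
       denudation = denud, truth = truth)
}

# Continuum cartilage volume of the phantom (numeric surface integral on a
# fine parameter grid; exact up to quadrature, independent of voxelization).
phantom_true_volume <- function(spec, geo = phantom_geometry(spec), n_grid = 600L) {
  field <- spec$thickness_field
  thick_at <- function(u, v) field(u, v) * lesion_factor(u, v, spec$lesions)
  if (geo$surface == "femur") {
    # radial band: dV = (t R + t^2/2) dphi dz
    phi <- seq(-geo$phi_max, geo$phi_max, length.out = n_grid)
    z <- seq(geo$z0, geo$z1, length.out = n_grid)
    dphi <- diff(phi[1:2]); dzz <- diff(z[1:2])
    u <- (sin(phi) + 1) / 2
    v <- (z - geo$z0) / (geo$z1 - geo$z0)
    tt <- outer(u, v, function(uu, vv) thick_at(uu, vv))
    sum(tt * geo$R + tt^2 / 2) * dphi * dzz
  } else {
    # vertical extent per (x, z) is t / cos(theta)
    z <- seq(geo$zc - geo$rz, geo$zc + geo$rz, length.out = n_grid)
    dzz <- diff(z[1:2])
    total <- 0
    for (zz in z) {
      w <- tibia_half_chord(zz, geo)
      x <- seq(geo$xc - w, geo$xc + w, length.out = n_grid)
      dxx <- diff(x[1:2])
      surf <- tibia_surface(x, zz, geo)
      u <- (x - (geo$xc - w)) / (2 * w)
      v <- (zz - (geo$zc - geo$rz)) / (2 * geo$rz)
      tt <- thick_at(u, rep_len(v, length(u)))
      total <- total + sum(tt / surf$cos_theta) * dxx * dzz
    }
    total
  }
}
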