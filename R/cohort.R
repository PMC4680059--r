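#' @title Synthetic longitudinal cohorts
#' @description Cohort generator emulating the validation-study designs:
#'   knees stratified by lateral JSN grade (default 25 per grade, mirroring
#'   the validation design; 5 per grade for reliability), with grade-dependent
#'   cartilage thinning, focal full-thickness lesions concentrated at a
#'   posterior hotspot, a 24-month progression draw, and radiographic
#'   covariates (JSW, HKA, KL grade) linked to the true cartilage volume.
#'   Cohorts are generated in "fast mode": per-surface (u, v) thickness grids
#'   rather than rasterized volumes, so cohort-scale statistics run in
#'   seconds. [rasterize_phantom()] provides the voxel-level route for
#'   coordinate and measurement tests.
#' @name cohort
NULL

#' Specify a synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: all lateral
#' JSN grades represented equally, mean thickness decreasing with grade,
#' lesion probability increasing with grade, lesions drawn inside a posterior
#' hotspot, and 24-month thickness loss.
#'
#' @param n_per_grade knees per JSN grade (default 25, the validation design;
#'   use 5 for a reliability set).
#' @param grade_levels ordered JSN grades (default 0:3).
#' @param grade_effect_mm mean thickness decrement per JSN grade step (mm).
#' @param lesion_prob_by_grade probability of a hotspot denudation lesion per
#'   grade.
#' @param hotspot_uv named numeric `(u_lo, u_hi, v_lo, v_hi)`: the posterior
#'   hotspot rectangle lesions are drawn in (shared by femur and tibia).
#' @param lesion_extent_range full lesion widths (u and v) are drawn
#'   uniformly from this range.
#' @param progression_mean_mm,progression_sd_mm 24-month thickness-loss
#'   distribution (mm; loss is subtracted, thickness floored at 0).
#' @param remeasure_noise_sd repeated-measurement noise SD on each location's
#'   thickness (mm).
#' @param height_dist `c(mean_m, sd_m)` of subject height.
#' @param base_thickness_mm named `c(femur, tibia)` healthy mean thickness (mm).
#' @param subject_sd_mm between-subject SD of mean thickness (mm).
#' @param jsw_link,hka_link linear links from the standardized baseline true
#'   cartilage volume z to the covariate: `c(intercept, slope, noise_sd)`;
#'   `jsw = a + b z + e`, `hka = a + b z + e` (HKA slope negative: less
#'   cartilage, more malalignment).
#' @param grid_shape thickness-grid resolution per surface.
#' @param ap_extent_mm nominal anterior-posterior extents (mm) for fast-mode
#'   measurement and surface areas.
#' @param surface_area_mm2 nominal articular surface areas (mm^2) converting
#'   mean thickness to true volume.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_grade = 25L,
                        grade_levels = 0:3,
                        grade_effect_mm = 0.35,
                        lesion_prob_by_grade = c(0.05, 0.25, 0.55, 0.85),
                        hotspot_uv = c(u_lo = 0.55, u_hi = 0.85,
                                       v_lo = 0.30, v_hi = 0.60),
                        lesion_extent_range = c(0.10, 0.22),
                        progression_mean_mm = 0.10,
                        progression_sd_mm = 0.12,
                        remeasure_noise_sd = 0.15,
                        height_dist = c(1.68, 0.09),
                        base_thickness_mm = c(femur = 2.2, tibia = 1.8),
                        subject_sd_mm = 0.25,
                        jsw_link = c(intercept = 4.4, slope = 1.9, noise_sd = 1.3),
                        hka_link = c(intercept = 3.0, slope = -1.5, noise_sd = 4.45),
                        grid_shape = c(50L, 50L),
                        ap_extent_mm = c(femur = 55, tibia = 40),
                        surface_area_mm2 = c(femur = 1600, tibia = 1150),
                        seed = 1L) {
  if (length(grade_levels) == 0L) stop("grade list must not be empty")
  if (n_per_grade < 1L) stop("n_per_grade must be at least 1")
  if (length(lesion_prob_by_grade) != length(grade_levels))
    stop("lesion_prob_by_grade must have one entry per grade")
  if (any(lesion_prob_by_grade < 0 | lesion_prob_by_grade > 1))
    stop("lesion probabilities must lie in [0, 1]")
  if (progression_sd_mm <= 0) stop("progression_sd_mm must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

# draw one full-thickness lesion rectangle inside the hotspot
draw_hotspot_lesion <- function(spec) {
  h <- spec$hotspot_uv
  du <- stats::runif(1, spec$lesion_extent_range[1], spec$lesion_extent_range[2])
  dv <- stats::runif(1, spec$lesion_extent_range[1], spec$lesion_extent_range[2])
  du <- min(du, h[["u_hi"]] - h[["u_lo"]])
  dv <- min(dv, h[["v_hi"]] - h[["v_lo"]])
  cu <- stats::runif(1, h[["u_lo"]] + du / 2, h[["u_hi"]] - du / 2)
  cv <- stats::runif(1, h[["v_lo"]] + dv / 2, h[["v_hi"]] - dv / 2)
  lesion_spec(center_uv = c(cu, cv), extent_uv = c(du, dv), depth_fraction = 1)
}

# smooth spatial thickness profile: slightly thicker centrally
thickness_profile <- function(grid_shape) {
  u <- (seq_len(grid_shape[1]) - 0.5) / grid_shape[1]
  v <- (seq_len(grid_shape[2]) - 0.5) / grid_shape[2]
  0.3 * outer(sin(pi * u), sin(pi * v))
}

#' Generate a synthetic longitudinal cohort
#'
#' Fully reproducible given `spec$seed`. Each knee gets baseline and
#' month-24 thickness grids per surface, known true cartilage volumes, and
#' covariates (JSN and KL grades, JSW, HKA, height). By construction the
#' per-grade mean true thickness strictly decreases with JSN grade (when
#' `grade_effect_mm > 0`).
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cdi_cohort`: `spec`, `table` (one row per
#'   knee and visit, with true volumes, true progression, and covariates),
#'   `grids` (per knee: `baseline`/`month24`, each with `femur`/`tibia`
#'   matrices), and `lesions` (per knee and surface, the lesion list).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  grades <- rep(spec$grade_levels, each = spec$n_per_grade)
  n <- length(grades)
  ids <- sprintf("knee%03d", seq_len(n))
  prof <- thickness_profile(spec$grid_shape)
  area <- spec$surface_area_mm2

  heights <- stats::rnorm(n, spec$height_dist[1], spec$height_dist[2])
  heights <- pmax(1.3, heights)           # heights drawn once, reused per visit
  kl <- pmin(4L, as.integer(grades) +
               stats::rbinom(n, 1L, 0.55) + stats::rbinom(n, 1L, 0.25))

  grids <- vector("list", n); names(grids) <- ids
  lesions <- vector("list", n); names(lesions) <- ids
  rows <- vector("list", 2L * n)
  gidx <- match(grades, spec$grade_levels)

  for (i in seq_len(n)) {
    subj_mean <- spec$base_thickness_mm -
      spec$grade_effect_mm * (gidx[i] - 1L) +
      stats::rnorm(1, 0, spec$subject_sd_mm)
    subj_mean <- pmax(subj_mean, 0.2)   # keep surface names
    les <- list(femur = list(), tibia = list())
    g0 <- list()
    for (srf in c("femur", "tibia")) {
      g <- pmax(subj_mean[[srf]] + prof, 0)
      if (stats::runif(1) < spec$lesion_prob_by_grade[gidx[i]]) {
        ls <- draw_hotspot_lesion(spec)
        les[[srf]] <- list(ls)
        g <- apply_lesions_grid(g, list(ls))
      }
      g0[[srf]] <- g
    }
    d <- stats::rnorm(1, spec$progression_mean_mm, spec$progression_sd_mm)
    g1 <- lapply(g0, function(g) pmax(g - d, 0))
    grids[[i]] <- list(baseline = g0, month24 = g1)
    lesions[[i]] <- les
    vols0 <- vapply(c("femur", "tibia"),
                    function(s) mean(g0[[s]]) * area[[s]], numeric(1))
    vols1 <- vapply(c("femur", "tibia"),
                    function(s) mean(g1[[s]]) * area[[s]], numeric(1))
    rows[[2L * i - 1L]] <- data.frame(
      knee_id = ids[i], visit = "baseline", jsn = grades[i], kl = kl[i],
      height_m = heights[i],
      true_femur_volume_mm3 = vols0[["femur"]],
      true_tibia_volume_mm3 = vols0[["tibia"]],
      true_total_volume_mm3 = sum(vols0),
      true_progression_mm = d,
      has_lesion = length(les$femur) + length(les$tibia) > 0)
    rows[[2L * i]] <- data.frame(
      knee_id = ids[i], visit = "month24", jsn = grades[i], kl = kl[i],
      height_m = heights[i],
      true_femur_volume_mm3 = vols1[["femur"]],
      true_tibia_volume_mm3 = vols1[["tibia"]],
      true_total_volume_mm3 = sum(vols1),
      true_progression_mm = d,
      has_lesion = length(les$femur) + length(les$tibia) > 0)
  }
  tab <- do.call(rbind, rows)

  # covariates linked to standardized baseline true total volume
  b <- tab[tab$visit == "baseline", ]
  z <- as.numeric(scale(b$true_total_volume_mm3))
  jsw <- spec$jsw_link[["intercept"]] + spec$jsw_link[["slope"]] * z +
    stats::rnorm(n, 0, spec$jsw_link[["noise_sd"]])
  hka <- spec$hka_link[["intercept"]] - abs(spec$hka_link[["slope"]]) * z +
    stats::rnorm(n, 0, spec$hka_link[["noise_sd"]])
  tab$jsw <- jsw[match(tab$knee_id, b$knee_id)]
  tab$hka <- hka[match(tab$knee_id, b$knee_id)]
  rownames(tab) <- NULL

  structure(list(spec = spec, table = tab, grids = grids, lesions = lesions),
            class = "cdi_cohort")
}

# zero out grid cells whose centers fall in a depth-1 lesion rectangle
apply_lesions_grid <- function(g, lesions) {
  d <- dim(g)
  u <- (seq_len(d[1]) - 0.5) / d[1]
  v <- (seq_len(d[2]) - 0.5) / d[2]
  for (ls in lesions) {
    r <- ls$rect
    iu <- u >= r[["u_lo"]] & u < r[["u_hi"]]
    iv <- v >= r[["v_lo"]] & v < r[["v_hi"]]
    g[iu, iv] <- g[iu, iv] * (1 - ls$depth_fraction)
  }
  g
}

#' @export
print.cdi_cohort <- function(x, ...) {
  cat(sprintf("<cdi_cohort> %d knees x 2 visits, JSN grades %s, seed %d\n",
              length(x$grids),
              paste(x$spec$grade_levels, collapse = "/"), x$spec$seed))
  invisible(x)
}

#' Measure CDI across a cohort (fast mode)
#'
#' Applies [measure_grid_cdi()] to every knee and visit. Each call is one
#' independent "reading": rerunning with a different seed yields an
#' independent remeasurement realization (the route used for the
#' reliability analysis).
#'
#' @param cohort a `cdi_cohort`.
#' @param locations named list of femur/tibia `location_set`s.
#' @param noise_sd remeasurement noise SD (mm); defaults to the cohort
#'   spec's `remeasure_noise_sd`.
#' @param seed integer seed for the measurement noise.
#' @param visits which visits to measure.
#' @return The cohort table restricted to `visits`, with `femur_cdi`,
#'   `tibia_cdi`, `total_cdi` columns appended.
#' @export
measure_cohort <- function(cohort, locations, noise_sd = NULL, seed = 1L,
                           visits = c("baseline", "month24")) {
  stopifnot(inherits(cohort, "cdi_cohort"))
  if (is.null(noise_sd)) noise_sd <- cohort$spec$remeasure_noise_sd
  tab <- cohort$table[cohort$table$visit %in% visits, ]
  withr::with_seed(seed, {
    res <- lapply(seq_len(nrow(tab)), function(r) {
      g <- cohort$grids[[tab$knee_id[r]]][[tab$visit[r]]]
      cdi <- measure_grid_cdi(g, locations, tab$height_m[r],
                              noise_sd = noise_sd,
                              ap_extent_mm = cohort$spec$ap_extent_mm)
      c(cdi$femur_cdi, cdi$tibia_cdi, cdi$total_cdi)
    })
  })
  res <- do.call(rbind, res)
  tab$femur_cdi <- res[, 1]; tab$tibia_cdi <- res[, 2]; tab$total_cdi <- res[, 3]
  rownames(tab) <- NULL
  tab
}

#' Two-realization reliability measurements for a cohort
#'
#' Emulates two readings separated in time as two independent measurement
#' noise realizations of the baseline visit.
#'
#' @param cohort a `cdi_cohort` (typically 5 knees per grade).
#' @param locations named list of femur/tibia `location_set`s.
#' @param noise_sd remeasurement noise SD (mm).
#' @param seed integer seed; the two realizations use `seed` and `seed + 1`.
#' @return A long data.frame: `knee_id`, `surface`, `rep`, `value`, ready for
#'   [build_validation_report()].
#' @export
measure_reliability <- function(cohort, locations, noise_sd = NULL, seed = 1L) {
  m1 <- measure_cohort(cohort, locations, noise_sd, seed = seed, visits = "baseline")
  m2 <- measure_cohort(cohort, locations, noise_sd, seed = seed + 1L, visits = "baseline")
  long <- function(m, rep_id) {
    do.call(rbind, lapply(c(femur = "femur_cdi", tibia = "tibia_cdi",
                            total = "total_cdi"), function(cn)
      data.frame(knee_id = m$knee_id, value = m[[cn]], rep = rep_id)))
  }
  a <- long(m1, 1L); b <- long(m2, 2L)
  a$surface <- rep(c("femur", "tibia", "total"), each = nrow(m1))
  b$surface <- rep(c("femur", "tibia", "total"), each = nrow(m2))
  out <- rbind(a, b)
  rownames(out) <- NULL
  out[, c("knee_id", "surface", "rep", "value")]
}

#' Write a cohort's tables to CSV
#' @param cohort a `cdi_cohort`.
#' @param path output CSV path for the knee table.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort$table, path, row.names = FALSE)
  invisible(path)
}
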