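test_that("thickness at locations matches the uniform field within discretization", {
  # single-location accuracy is bounded by voxel discretization: with 0.456 mm
  # rows each interface localizes only to ~half the in-plane voxel diagonal
  for (surface in c("femur", "tibia")) {
    fx <- uniform_fixture(surface)
    errs <- c()
    for (u in seq(0.2, 0.8, by = 0.1)) for (v in seq(0.2, 0.8, by = 0.15)) {
      m <- measure_thickness(fx$ph$volume, fx$fr, c(u, v))
      errs <- c(errs, m$thickness_mm - 2.0)
    }
    expect_lt(max(abs(errs)), 0.35)
    expect_lt(abs(mean(errs)), 0.12)
  }
})

test_that("a linear wedge field is recovered at interior locations", {
  for (surface in c("femur", "tibia")) {
    ph <- small_phantom(surface, thickness_field = function(u, v) 1 + 2 * u)
    fr <- build_surface_frame(ph$volume, side_of(surface))
    m <- measure_thickness(ph$volume, fr, c(0.7, 0.5))
    expect_lt(abs(m$thickness_mm - 2.4), 0.35)
    m2 <- measure_thickness(ph$volume, fr, c(0.3, 0.4))
    expect_lt(abs(m2$thickness_mm - 1.6), 0.35)
  }
})

test_that("a full-thickness lesion reads as exactly zero thickness", {
  les <- lesion_spec(center_uv = c(0.7, 0.45), extent_uv = c(0.2, 0.14))
  for (surface in c("femur", "tibia")) {
    ph <- small_phantom(surface, lesions = list(les))
    fr <- build_surface_frame(ph$volume, side_of(surface))
    m <- measure_thickness(ph$volume, fr, c(0.7, 0.45))
    expect_identical(m$thickness_mm, 0)
    # ap length over the lesion-covered cell is zero too
    m2 <- measure_thickness(ph$volume, fr, c(0.7, 0.45),
                            cell = c(u_lo = 0.62, u_hi = 0.78))
    expect_identical(m2$ap_length_mm, 0)
  }
})

test_that("compute_cdi implements the height-normalized sum of products", {
  one <- data.frame(surface = c("femur", "tibia"),
                    thickness_mm = c(2, 0), ap_length_mm = c(10, 5),
                    ml_factor_mm = 0.7)
  res <- compute_cdi(one, height_m = 1.70)
  expect_equal(res$femur_cdi, 2 * 10 * 0.7 / 1.70)   # 8.2353 mm^3/m
  expect_equal(res$femur_cdi, 8.23529411764706, tolerance = 1e-10)
  expect_equal(res$tibia_cdi, 0)
  expect_equal(res$total_cdi, res$femur_cdi + res$tibia_cdi)

  # all-zero thickness gives exactly zero everywhere
  zero <- data.frame(surface = rep(c("femur", "tibia"), each = 9),
                     thickness_mm = 0, ap_length_mm = 3, ml_factor_mm = 0.7)
  rz <- compute_cdi(zero, 1.6)
  expect_identical(rz$total_cdi, 0)

  # linearity: doubling thickness doubles each surface CDI exactly
  m <- data.frame(surface = rep(c("femur", "tibia"), each = 3),
                  thickness_mm = c(1, 2, 3, 1.5, 2.5, 0.5),
                  ap_length_mm = 4:9, ml_factor_mm = 0.7)
  r1 <- compute_cdi(m, 1.7)
  m2 <- m; m2$thickness_mm <- 2 * m2$thickness_mm
  r2 <- compute_cdi(m2, 1.7)
  expect_equal(r2$femur_cdi, 2 * r1$femur_cdi)
  expect_equal(r2$tibia_cdi, 2 * r1$tibia_cdi)

  # height invariance: scaling height by c scales CDI by 1/c exactly
  r3 <- compute_cdi(m, 1.7 * 1.25)
  expect_equal(r3$total_cdi, r1$total_cdi / 1.25)

  expect_error(compute_cdi(m, 0), "height")
  expect_error(compute_cdi(m[m$surface == "femur", ], 1.7),
               "empty measurement list for surface tibia")
})

test_that("zero-thickness phantom scores exactly zero CDI", {
  vols <- list(femur = small_phantom("femur", thickness = 0)$volume,
               tibia = small_phantom("tibia", thickness = 0)$volume)
  locs <- list(femur = location_set_from_box("femur", test_box),
               tibia = location_set_from_box("tibia", test_box))
  res <- measure_cdi(vols, locs, height_m = 1.70)
  expect_identical(res$total_cdi, 0)
})

test_that("phantom CDI matches the closed-form oracle within 5%", {
  # thickness constant within each location cell -> CDI has a closed form
  # using the analytic per-slice AP extent
  tvals <- matrix(c(1.6, 2.0, 2.4, 1.8, 2.2, 1.4, 2.6, 1.2, 2.0), 3, 3)
  box <- test_box
  field <- function(u, v) {
    t <- rep(2.0, length(u))
    iu <- pmin(2, pmax(0, floor((u - box["u_lo"]) / ((box["u_hi"] - box["u_lo"]) / 3))))
    iv <- pmin(2, pmax(0, floor((v - box["v_lo"]) / ((box["v_hi"] - box["v_lo"]) / 3))))
    inb <- u >= box["u_lo"] & u < box["u_hi"] & v >= box["v_lo"] & v < box["v_hi"]
    t[inb] <- tvals[cbind(iu[inb] + 1, iv[inb] + 1)]
    t
  }
  h <- 1.70
  for (surface in c("femur", "tibia")) {
    ph <- small_phantom(surface, thickness_field = field,
                        n_slices = 48L, shape = c(140L, 170L))
    fr <- build_surface_frame(ph$volume, side_of(surface))
    ls <- location_set_from_box(surface, box)
    meas <- measure_surface(ph$volume, fr, ls)
    closed <- 0
    for (k in 1:9) {
      s <- slice_for_v(ls$locations$v[k], fr)
      b <- fr$boundaries[[as.character(s)]]
      ext <- (max(b$col) - min(b$col)) * ph$volume$spacing[1]
      closed <- closed + tvals[k] * (ls$cells$u_hi[k] - ls$cells$u_lo[k]) *
        ext * ph$volume$spacing[3] / h
    }
    measured <- sum(meas$thickness_mm * meas$ap_length_mm * meas$ml_factor_mm) / h
    expect_lt(abs(measured - closed) / closed, 0.05)
  }
})

test_that("visit pairs difference correctly and lesions are localized", {
  locs <- list(femur = location_set_from_box("femur", test_box),
               tibia = location_set_from_box("tibia", test_box))
  base <- list(femur = small_phantom("femur")$volume,
               tibia = small_phantom("tibia")$volume)
  # identical volumes: change is exactly zero
  same <- cdi_for_pair(base, base, locs, height_m = 1.70)
  expect_identical(unname(same$change), c(0, 0, 0))

  # follow-up with a new full-thickness lesion covering exactly the center
  # femur location cell
  k <- 5L   # center of the 3x3 grid
  cellk <- locs$femur$cells[k, ]
  les <- lesion_spec(center_uv = c(mean(c(cellk$u_lo, cellk$u_hi)),
                                   mean(c(cellk$v_lo, cellk$v_hi))),
                     extent_uv = c(cellk$u_hi - cellk$u_lo,
                                   cellk$v_hi - cellk$v_lo))
  fup <- list(femur = small_phantom("femur", lesions = list(les))$volume,
              tibia = base$tibia)
  pair <- cdi_for_pair(base, fup, locs, height_m = 1.70)
  baseline_contrib <- pair$baseline$measurements$contribution[
    pair$baseline$measurements$surface == "femur"][k]
  # measurement tolerance: thickness discretization over the cell's AP length
  cell_ap <- pair$baseline$measurements$ap_length_mm[
    pair$baseline$measurements$surface == "femur"][k]
  tol <- 0.35 * cell_ap * 0.7 / 1.70 + 0.5
  expect_lt(abs(pair$change[["femur"]] + baseline_contrib), tol)
  expect_identical(pair$change[["tibia"]], 0)

  # a lesion disjoint from every location cell barely changes the CDI
  far <- lesion_spec(center_uv = c(0.2, 0.12), extent_uv = c(0.12, 0.1))
  fup2 <- list(femur = small_phantom("femur", lesions = list(far))$volume,
               tibia = base$tibia)
  pair2 <- cdi_for_pair(base, fup2, locs, height_m = 1.70)
  expect_lt(abs(pair2$change[["total"]]), tol)
})

test_that("CDI declines on average in a progressing cohort", {
  ch <- generate_cohort(cohort_spec(seed = 12L))
  locs <- list(femur = location_set_from_box("femur", test_box),
               tibia = location_set_from_box("tibia", test_box))
  m <- measure_cohort(ch, locs, seed = 4L)
  wide <- merge(m[m$visit == "baseline", c("knee_id", "total_cdi")],
                m[m$visit == "month24", c("knee_id", "total_cdi")],
                by = "knee_id")
  expect_lt(mean(wide[[3]] - wide[[2]]), 0)
})

test_that("fast-mode CDI tracks the thickness grids deterministically", {
  ch <- generate_cohort(cohort_spec(n_per_grade = 4L, seed = 3L))
  locs <- list(femur = location_set_from_box("femur", test_box),
               tibia = location_set_from_box("tibia", test_box))
  g <- ch$grids[[1]]$baseline
  r1 <- measure_grid_cdi(g, locs, height_m = 1.7, noise_sd = 0)
  r2 <- measure_grid_cdi(g, locs, height_m = 1.7, noise_sd = 0)
  expect_identical(r1$total_cdi, r2$total_cdi)
  # noise-free grid CDI equals the hand-computed sum over locations
  expected <- 0
  for (srf in c("femur", "tibia")) {
    ap <- c(femur = 55, tibia = 40)[[srf]]
    for (k in 1:9) {
      u <- locs[[srf]]$locations$u[k]; v <- locs[[srf]]$locations$v[k]
      d <- dim(g[[srf]])
      tt <- g[[srf]][min(floor(u * d[1]), d[1] - 1) + 1,
                     min(floor(v * d[2]), d[2] - 1) + 1]
      expected <- expected +
        tt * (locs[[srf]]$cells$u_hi[k] - locs[[srf]]$cells$u_lo[k]) * ap * 0.7 / 1.7
    }
  }
  expect_equal(r1$total_cdi, expected, tolerance = 1e-12)
})
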