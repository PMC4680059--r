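test_that("icc31 equals the brute-force ANOVA oracle on random matrices", {
  set.seed(101)
  for (r in 1:50) {
    n <- sample(4:30, 1)
    k <- sample(2:min(4, n - 1), 1)
    x <- matrix(stats::rnorm(n * k, mean = 10, sd = 2), n, k) +
      stats::rnorm(n)   # subject effects
    expect_lt(abs(icc31(x) - icc31_oracle(x)), 1e-10)
  }
})

test_that("icc31 agrees with the aov-based mean squares decomposition", {
  set.seed(55)
  x <- matrix(stats::rnorm(40, 5, 1), 20, 2) + stats::rnorm(20, 0, 2)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(20), 2)),
                   meas = factor(rep(1:2, each = 20)))
  ms <- summary(stats::aov(y ~ subj + meas, data = df))[[1]][, "Mean Sq"]
  icc_aov <- (ms[1] - ms[3]) / (ms[1] + (2 - 1) * ms[3])
  expect_equal(icc31(x), icc_aov, tolerance = 1e-12)
})

test_that("icc31 handles perfect agreement, offsets, and degenerate input", {
  x <- matrix(stats::rnorm(6), 6, 1)[, c(1, 1)]
  expect_equal(icc31(x), 1.0)
  # consistency ICC ignores a fixed shift between sessions
  y <- cbind(x[, 1], x[, 1] + 3.7)
  expect_equal(icc31(y), 1.0)
  expect_error(icc31(matrix(2, 5, 2)), "degenerate")
  expect_error(icc31(matrix(1:4, 2, 2)), "n >= 3")
})

test_that("srm is mean over sd of change with sign preserved", {
  expect_equal(srm(c(-1, -2, -3)), -2.0)
  expect_equal(srm(c(-2, -1, 0, 1, 2)), 0.0)
  expect_equal(srm(c(1, 3)), sqrt(2))
  expect_error(srm(c(1, 1, 1)), "no variance")
  expect_error(srm(1), "at least 2")
})

test_that("srm recovers -mu/sigma in simulation", {
  set.seed(7)
  for (mu in c(0.5, 0.87, 2)) {
    est <- replicate(200, srm(stats::rnorm(100, -mu, 1)))
    # SE of the SRM estimate at n = 100
    se <- sqrt((1 + mu^2 / 2) / 100)
    expect_lt(abs(mean(est) + mu), 3 * se / sqrt(200))
  }
})

test_that("spearman_rho matches monotone expectations and the rank oracle", {
  x <- c(1, 2, 5, 7, 11, 13)
  expect_equal(spearman_rho(x, x^3)$rho, 1.0)
  expect_equal(spearman_rho(x, -x)$rho, -1.0)
  # tied 6-point data vs a hand-computed averaged-rank table
  xt <- c(1, 2, 2, 3, 4, 4)
  yt <- c(10, 10, 20, 20, 30, 40)
  rx <- c(1, 2.5, 2.5, 4, 5.5, 5.5)
  ry <- c(1.5, 1.5, 3.5, 3.5, 5, 6)
  rho_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- spearman_rho(xt, yt)
  expect_equal(got$rho, rho_manual, tolerance = 1e-12)
  # cross-check rho against the standard implementation
  expect_equal(got$rho, unname(stats::cor(xt, yt, method = "spearman")),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(9)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, base)
  expect_equal(spearman_rho(x, y^3 + 2 * y)$rho, base)
  expect_equal(spearman_rho(rank(x), y)$rho, base)
})

test_that("spearman exact permutation p agrees with the t approximation in spirit", {
  set.seed(13)
  x <- c(3.1, 0.2, -1.4, 2.2, 0.9, -0.3)
  y <- c(2.9, 0.5, -0.7, 1.8, 1.4, 0.1)
  ex <- spearman_rho(x, y, method = "exact")
  tt <- spearman_rho(x, y)
  expect_equal(ex$rho, tt$rho)
  expect_true(ex$p > 0 && ex$p <= 1)
  # strong monotone association: exact p is small
  expect_lt(ex$p, 0.05)
})

test_that("trend statistic equals the O(N^2) counting oracle", {
  set.seed(21)
  for (r in 1:10) {
    g <- rep(1:4, times = sample(3:8, 4, replace = TRUE))
    x <- stats::rnorm(length(g)) + 0.3 * g
    x[sample(length(x), 3)] <- x[1]    # inject ties
    got <- trend_test(x, g, n_perm = 50L, seed = 1L)
    expect_equal(got$statistic, jt_oracle(x, g))
  }
})

test_that("trend_test detects the per-grade mean pattern and reports direction", {
  set.seed(33)
  means <- c(4000, 3900, 2850, 1900)
  x <- stats::rnorm(100, rep(means, each = 25), 300)
  g <- rep(0:3, each = 25)
  res <- trend_test(x, g, n_perm = 10000L, seed = 5L)
  expect_lt(res$p, 0.001)
  expect_equal(res$direction, "decreasing")
  # swapping two group labels on a strictly monotone dataset lowers the
  # (decreasing-direction) trend strength
  xm <- rep(c(40, 30, 20, 10), each = 5) + seq(0, 0.9, length.out = 20)
  gm <- rep(1:4, each = 5)
  U0 <- trend_test(xm, gm, n_perm = 10L, seed = 1L)$statistic
  gs <- gm; gs[1:5] <- 2L; gs[6:10] <- 1L
  U1 <- trend_test(xm, gs, n_perm = 10L, seed = 1L)$statistic
  # monotone decreasing data: U is minimal; a label swap increases U toward E
  expect_gt(U1, U0)
  # the lm-on-grade alternative agrees on direction
  lm_res <- trend_test(x, g, method = "lm")
  expect_equal(lm_res$direction, "decreasing")
  expect_lt(lm_res$p, 0.001)
})

test_that("trend_test permutation p is reproducible and calibrated", {
  x <- stats::rnorm(60, 0, 1)
  g <- rep(1:3, each = 20)
  a <- trend_test(x, g, n_perm = 500L, seed = 42L)
  b <- trend_test(x, g, n_perm = 500L, seed = 42L)
  expect_identical(a$p, b$p)
  # type-I error at alpha = 0.05 over null replicates
  set.seed(77)
  rej <- replicate(600, {
    xn <- stats::rnorm(100)
    trend_test(xn, rep(0:3, each = 25), n_perm = 200L)$p <= 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("validation report assembles all statistics with the right signs", {
  ch <- generate_cohort(cohort_spec(seed = 14L))
  rel <- generate_cohort(cohort_spec(n_per_grade = 5L, seed = 15L))
  locs <- list(femur = location_set_from_box("femur", test_box),
               tibia = location_set_from_box("tibia", test_box))
  meas <- measure_cohort(ch, locs, seed = 16L)
  reliability <- measure_reliability(rel, locs, seed = 17L)
  rep <- build_validation_report(meas, reliability, n_perm = 500L, seed = 18L)
  for (srf in c("femur", "tibia", "total")) {
    s <- rep$per_surface[[srf]]
    expect_true(s$icc >= -1 && s$icc <= 1)
    expect_true(s$spearman_jsw$p >= 0 && s$spearman_jsw$p <= 1)
    expect_gt(s$spearman_jsw$rho, 0)     # more cartilage, wider joint space
    expect_lt(s$spearman_hka$rho, 0)     # more cartilage, less malalignment
    expect_lt(s$srm, 0)                  # cohort declines over 24 months
    expect_equal(s$trend_jsn$direction, "decreasing")
  }
  # per-grade mean total CDI decreases with JSN grade
  pg <- rep$per_grade
  tot <- pg[pg$surface == "total" & pg$grade_variable == "jsn", ]
  expect_true(all(diff(tot$mean_cdi[order(tot$grade)]) < 0))
  # serialization writes the three artifacts
  dir <- withr::local_tempdir()
  write_validation_report(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("report.json", "per_grade_means.csv", "rank_pairs.csv")))))
})

test_that("a null cohort yields small SRM and unremarkable trend p", {
  spec <- cohort_spec(grade_effect_mm = 0, lesion_prob_by_grade = rep(0, 4),
                      progression_mean_mm = 0, remeasure_noise_sd = 0.3,
                      seed = 19L)
  ch <- generate_cohort(spec)
  locs <- list(femur = location_set_from_box("femur", test_box),
               tibia = location_set_from_box("tibia", test_box))
  meas <- measure_cohort(ch, locs, seed = 20L)
  rep <- build_validation_report(meas, NULL, n_perm = 500L, seed = 21L)
  expect_lt(abs(rep$per_surface$total$srm), 0.35)
  expect_gt(rep$per_surface$total$trend_jsn$p, 0.01)
})

test_that("ICC decreases as remeasurement noise increases", {
  rel <- generate_cohort(cohort_spec(n_per_grade = 5L, seed = 22L))
  locs <- list(femur = location_set_from_box("femur", test_box),
               tibia = location_set_from_box("tibia", test_box))
  iccs <- vapply(c(0.05, 0.5, 2.0), function(ns) {
    r <- measure_reliability(rel, locs, noise_sd = ns, seed = 23L)
    w <- r[r$surface == "total", ]
    m <- merge(w[w$rep == 1, c("knee_id", "value")],
               w[w$rep == 2, c("knee_id", "value")], by = "knee_id")
    icc31(as.matrix(m[, -1]))
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})
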