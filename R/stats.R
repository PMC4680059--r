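#' @title Validation statistics
#' @description The statistics used to validate the CDI as an imaging
#'   biomarker: ICC(3,1) intra-rater reliability (two-way mixed, single
#'   measure, consistency), the standardized response mean (SRM) for
#'   responsiveness, Spearman rank correlation for construct validity, and
#'   the Jonckheere-Terpstra ordered trend test for association with ordinal
#'   radiographic grades.
#' @name cdi-stats
NULL

#' Intraclass correlation, ICC(3,1)
#'
#' Two-way mixed model, single measure, consistency (Shrout-Fleiss (3,1)):
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)` from the
#' subjects x measurements ANOVA decomposition. Consistency ICC ignores
#' fixed shifts between measurement sessions.
#'
#' @param ratings numeric matrix, subjects in rows, repeated measurements in
#'   columns; no missing values, `n > k`, `n >= 3`, `k >= 2`.
#' @return ICC value in `[-1, 1]`.
#' @export
icc31 <- function(ratings) {
  x <- as.matrix(ratings)
  if (any(!is.finite(x))) stop("ratings must be complete and finite")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L || k < 2L || n <= k)
    stop("ratings must have n >= 3 subjects, k >= 2 measurements, n > k")
  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total < 1e-12 * max(1, grand^2)) stop("degenerate ratings: zero total variance")
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_meas <- n * sum((colMeans(x) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_meas
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
}

#' Standardized response mean
#'
#' `mean(changes) / sd(changes)` with the n-1 denominator. The sign is
#' preserved: negative SRM means decline.
#'
#' @param changes numeric vector of per-subject change scores (n >= 2).
#' @return The SRM.
#' @export
srm <- function(changes) {
  changes <- as.numeric(changes)
  if (length(changes) < 2L) stop("need at least 2 change scores")
  s <- stats::sd(changes)
  if (s == 0) stop("no variance in change")
  mean(changes) / s
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged). The p-value uses
#' the t-approximation with n-2 degrees of freedom by default; for small
#' samples (`n <= 8`) an exact permutation p is available.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @param method `"t"` (default) or `"exact"` (full permutation enumeration,
#'   `n <= 8`).
#' @return A list with `rho`, `p`, `n`, `method`.
#' @export
spearman_rho <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y) || n < 4L) stop("x and y must be paired with n >= 4")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 8L) stop("exact permutation p only available for n <= 8")
    perms <- permutations_all(n)
    rhos <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1 - 1e-12) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n <= 8
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Jonckheere-Terpstra test for ordered trend
#'
#' Tests for a monotone trend in a continuous outcome across ordered groups
#' (e.g. CDI across JSN or KL grades). The statistic counts, over all group
#' pairs (i < j in grade order), pairs of observations with the later-grade
#' value larger (ties count 1/2). The two-sided p-value comes from a
#' label-permutation null (seeded); `direction` reports whether the observed
#' trend is increasing or decreasing with grade. A linear-regression-on-grade
#' alternative is available via `method = "lm"`.
#'
#' @param values numeric outcome vector.
#' @param groups ordinal group labels (ordered factor, or anything coercible;
#'   sort order defines the grade order). At least 3 groups with n >= 2 each.
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional integer seed for the permutation draw.
#' @param method `"jt"` (default) or `"lm"`.
#' @return A list with `statistic`, `p`, `direction`, `method`, `n_perm`.
#' @export
trend_test <- function(values, groups, n_perm = 10000L, seed = NULL,
                       method = c("jt", "lm")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (!is.factor(groups)) groups <- factor(groups)
  groups <- droplevels(groups)
  ng <- table(groups)
  if (length(ng) < 3L) stop("need at least 3 ordered groups")
  if (any(ng < 2L)) stop("each group needs at least 2 observations")
  if (method == "lm") {
    fit <- stats::lm(values ~ as.numeric(groups))
    cf <- summary(fit)$coefficients
    return(list(statistic = cf[2, 1], p = cf[2, 4],
                direction = if (cf[2, 1] >= 0) "increasing" else "decreasing",
                method = "lm", n_perm = NA_integer_))
  }
  N <- length(values)
  g <- as.integer(groups)
  m <- length(ng)
  # pairwise comparison matrix: C[a, b] = 1 if x_a < x_b, 1/2 on ties
  C <- outer(values, values, "<") + 0.5 * outer(values, values, "==")
  G <- matrix(0, N, m)
  G[cbind(seq_len(N), g)] <- 1
  jt_stat <- function(Gm) {
    M <- crossprod(Gm, C %*% Gm)
    sum(M[upper.tri(M)])
  }
  U <- jt_stat(G)
  EU <- (N^2 - sum(ng^2)) / 4
  draw <- function() {
    stats <- numeric(n_perm)
    for (b in seq_len(n_perm)) stats[b] <- jt_stat(G[sample.int(N), , drop = FALSE])
    stats
  }
  perm <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  p <- (1 + sum(abs(perm - EU) >= abs(U - EU) - 1e-9)) / (n_perm + 1)
  list(statistic = U, p = p,
       direction = if (U >= EU) "increasing" else "decreasing",
       method = "jt", n_perm = n_perm)
}

#' Build the full validation report for a measured cohort
#'
#' Assembles, per surface (femur, tibia, total): baseline Spearman
#' correlations against JSW and HKA, trend tests against JSN and KL grade,
#' per-grade mean CDI tables, the SRM of 24-month change, the intra-rater
#' ICC(3,1) from the reliability remeasurements, and the rank pairs used for
#' rank scatter plots.
#'
#' @param measurements data.frame with columns `knee_id`, `visit`
#'   (`"baseline"`/`"month24"`), `femur_cdi`, `tibia_cdi`, `total_cdi`,
#'   `jsn`, `kl`, `jsw`, `hka`, `height_m`.
#' @param reliability optional data.frame with columns `knee_id`, `surface`
#'   (`femur`/`tibia`/`total`), `rep` (1 or 2), `value`.
#' @param n_perm permutations for the trend tests.
#' @param seed integer seed for the trend-test permutations.
#' @return An object of class `validation_report`.
#' @export
build_validation_report <- function(measurements, reliability = NULL,
                                    n_perm = 10000L, seed = 1L) {
  m <- as.data.frame(measurements)
  need <- c("knee_id", "visit", "femur_cdi", "tibia_cdi", "total_cdi",
            "jsn", "kl", "jsw", "hka")
  if (!all(need %in% names(m)))
    stop("measurements lacks columns: ", paste(setdiff(need, names(m)), collapse = ", "))
  base <- m[m$visit == "baseline", ]
  fup <- m[m$visit == "month24", ]
  surfaces <- c(femur = "femur_cdi", tibia = "tibia_cdi", total = "total_cdi")

  per_surface <- list()
  rank_pairs <- NULL
  per_grade <- NULL
  for (srf in names(surfaces)) {
    cdi <- base[[surfaces[[srf]]]]
    sp_jsw <- spearman_rho(cdi, base$jsw)
    sp_hka <- spearman_rho(cdi, base$hka)
    tr_jsn <- trend_test(cdi, base$jsn, n_perm = n_perm, seed = seed)
    tr_kl <- trend_test(cdi, base$kl, n_perm = n_perm, seed = seed + 1L)
    chg <- merge(base[, c("knee_id", surfaces[[srf]])],
                 fup[, c("knee_id", surfaces[[srf]])], by = "knee_id")
    srm_val <- if (nrow(chg) >= 2L) srm(chg[[3]] - chg[[2]]) else NA_real_
    icc_val <- NA_real_
    if (!is.null(reliability)) {
      r <- reliability[reliability$surface == srf, ]
      if (nrow(r)) {
        w <- stats::reshape(r[, c("knee_id", "rep", "value")],
                            idvar = "knee_id", timevar = "rep",
                            direction = "wide")
        icc_val <- icc31(as.matrix(w[, -1]))
      }
    }
    per_surface[[srf]] <- list(
      spearman_jsw = sp_jsw, spearman_hka = sp_hka,
      trend_jsn = tr_jsn, trend_kl = tr_kl,
      srm = srm_val, icc = icc_val)
    for (grade_var in c("jsn", "kl")) {
      means <- tapply(cdi, base[[grade_var]], mean)
      per_grade <- rbind(per_grade, data.frame(
        surface = srf, grade_variable = grade_var,
        grade = as.integer(names(means)), mean_cdi = as.numeric(means),
        n = as.integer(table(base[[grade_var]]))))
    }
    for (cov in c("jsw", "hka"))
      rank_pairs <- rbind(rank_pairs, data.frame(
        surface = srf, covariate = cov,
        knee_id = base$knee_id,
        rank_cdi = rank(cdi), rank_covariate = rank(base[[cov]])))
  }
  structure(list(per_surface = per_surface, per_grade = per_grade,
                 rank_pairs = rank_pairs,
                 n_baseline = nrow(base), n_change = nrow(fup),
                 n_perm = n_perm, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n=%d baseline knees\n", x$n_baseline))
  for (srf in names(x$per_surface)) {
    s <- x$per_surface[[srf]]
    cat(sprintf("  %-6s ICC=%.3f  SRM=%+.2f  rho(JSW)=%+.2f  rho(HKA)=%+.2f  trend p(JSN)=%.2g\n",
                srf, s$icc, s$srm, s$spearman_jsw$rho, s$spearman_hka$rho,
                s$trend_jsn$p))
  }
  invisible(x)
}

#' Serialize a validation report
#'
#' Writes `report.json` plus `per_grade_means.csv` and `rank_pairs.csv`.
#'
#' @param report a `validation_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(n_baseline = report$n_baseline, n_perm = report$n_perm,
             seed = report$seed,
             per_surface = lapply(report$per_surface, function(s) list(
               icc = s$icc, srm = s$srm,
               spearman_jsw = s$spearman_jsw[c("rho", "p")],
               spearman_hka = s$spearman_hka[c("rho", "p")],
               trend_jsn = s$trend_jsn[c("statistic", "p", "direction")],
               trend_kl = s$trend_kl[c("statistic", "p", "direction")])))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(report$per_grade, file.path(dir, "per_grade_means.csv"),
                   row.names = FALSE)
  utils::write.csv(report$rank_pairs, file.path(dir, "rank_pairs.csv"),
                   row.names = FALSE)
  invisible(dir)
}
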