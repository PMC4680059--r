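# Shared fixtures, built once per test run. Phantoms use reduced slice counts
# and in-plane matrices at the standard DESS voxel spacing so each rasterization
# stays around a second.

small_phantom <- function(surface, thickness = 2.0, lesions = list(),
                          n_slices = 40L, shape = c(100L, 120L),
                          thickness_field = NULL) {
  rasterize_phantom(phantom_spec(
    surface = surface, n_slices = n_slices, in_plane_shape = shape,
    base_thickness_mm = thickness, thickness_field = thickness_field,
    lesions = lesions))
}

side_of <- function(surface) if (surface == "femur") "inferior" else "superior"

# cached uniform 2 mm phantoms + frames used across test files
fixture_env <- new.env()
uniform_fixture <- function(surface) {
  key <- paste0("uniform_", surface)
  if (is.null(fixture_env[[key]])) {
    ph <- small_phantom(surface)
    fr <- build_surface_frame(ph$volume, side_of(surface))
    fixture_env[[key]] <- list(ph = ph, fr = fr)
  }
  fixture_env[[key]]
}

# a hand-built frame on a regular synthetic grid: slices 1..101 each with
# boundary columns 11..111, so u and v quantize in exact 0.01 steps
regular_frame <- function() {
  boundaries <- lapply(1:101, function(s) data.frame(col = 11:111, row = 50L))
  names(boundaries) <- as.character(1:101)
  structure(list(side = "superior", medial_slice = 1L, lateral_slice = 101L,
                 boundaries = boundaries, spacing = c(0.365, 0.456, 0.7)),
            class = "surface_frame")
}

# brute-force ICC(3,1) oracle: explicit ANOVA sums of squares via loops
icc31_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(x[i, ]) - grand)^2
  ss_meas <- 0
  for (j in seq_len(k)) ss_meas <- ss_meas + n * (mean(x[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (x[i, j] - grand)^2
  ms_subj <- ss_subj / (n - 1)
  ms_err <- (ss_tot - ss_subj - ss_meas) / ((n - 1) * (k - 1))
  (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
}

# brute-force Jonckheere-Terpstra statistic: O(N^2) double loop
jt_oracle <- function(values, groups) {
  g <- as.integer(factor(groups))
  U <- 0
  n <- length(values)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (g[a] < g[b]) {
      if (values[a] < values[b]) U <- U + 1
      else if (values[a] == values[b]) U <- U + 0.5
    }
  }
  U
}

# standard informative-location box used in measurement tests
test_box <- c(u_lo = 0.50, u_hi = 0.90, v_lo = 0.25, v_hi = 0.65)
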