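# Shared fixtures: all synthetic, built in code at test time.

# Compact cohort configuration for fast tests.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_markers = c(breast = 1L, thorax = 1L, abdomen = 1L),
    n_sessions = 3L, dibhs_per_session = 4L,
    sample_rate = 25, plateau_duration_s = c(5, 8),
    seed = 101L
  )
  defaults[names(args)] <- args
  do.call(simulation_config, defaults)
}

# Configuration with every variability source switched off: noiseless,
# driftless plateaus at a fixed held volume with identity transforms.
quiet_config <- function(...) {
  args <- list(...)
  defaults <- list(
    noise_sd_mm = 0, dropout_rate = 0,
    drift_mm_per_s = matrix(0, 3, 3), drift_brownian_sd = 0,
    dibh_offset_sd_mm = 0, marker_scatter_sd_mm = 0,
    session_offset_sd_mm = 0, alpha_dibh_sd = 0, alpha_session_sd = 0,
    volume_jitter_sd_l = 0, volume_wiggle_l = 0,
    setup_shift_mm = c(0, 0, 0)
  )
  defaults[names(args)] <- args
  do.call(quick_config, defaults)
}

# Independent sort-based percentile oracle (linear interpolation between
# order statistics, hand-coded; kept independent of stats::quantile).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p + 1
  fl <- floor(h)
  lo <- x[fl]
  if (fl >= n) return(lo)
  lo + (h - fl) * (x[fl + 1L] - lo)
}

oracle_range <- function(x, lo = 0.05, hi = 0.95) {
  oracle_quantile(x, hi) - oracle_quantile(x, lo)
}

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) %/% 2L] else (x[n %/% 2L] + x[n %/% 2L + 1L]) / 2
}

# Well-spread 9-marker constellation for registration tests.
test_constellation <- function(n = 9L, seed = 42L) {
  set.seed(seed)
  cbind(stats::runif(n, -120, 120),
        stats::runif(n, 40, 120),
        stats::runif(n, -150, 150))
}

# Random rigid transform with setup-error-scale magnitudes, pivoted at a
# constellation centroid so parameters compare directly after fitting.
random_transform <- function(points, max_t = 6.3, max_r = 2.1) {
  rigid_transform(
    rotations_deg = stats::runif(3, -max_r, max_r),
    translations_mm = stats::runif(3, -max_t, max_t),
    center_mm = colMeans(points)
  )
}
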