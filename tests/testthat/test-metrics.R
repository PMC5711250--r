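make_traj <- function(values, axis = "ap", dt = 0.02) {
  n <- length(values)
  coords <- matrix(0, n, 3)
  coords[, match(axis, linac_axes())] <- values
  marker_trajectory("m1", "thorax", (seq_len(n) - 1) * dt, coords)
}

test_that("intra-DIBH position is the per-axis median over the window", {
  w <- dibh_window(0, 1, "field")
  tr <- make_traj(rep(7, 100))
  expect_equal(intra_dibh_position(tr, w)$d[["ap"]], 7)
  tr2 <- make_traj(c(1, 2, 3, 4, 100), dt = 0.2)
  expect_equal(intra_dibh_position(tr2, w)$d[["ap"]], 3)
})

test_that("intra-DIBH stability matches the percentile-range oracle", {
  w <- dibh_window(0, 100, "field")
  tr <- make_traj(rep(2.5, 50))
  expect_equal(intra_dibh_stability(tr, w)[["ap"]], 0)
  vals <- seq(0, 10, length.out = 1000)
  tr2 <- make_traj(vals, dt = 0.05)
  expect_equal(intra_dibh_stability(tr2, w)[["ap"]], 9.0)
  tr3 <- make_traj(vals + 5, dt = 0.05)
  expect_equal(intra_dibh_stability(tr3, w)[["ap"]], 9.0)
  set.seed(1)
  vals4 <- rnorm(200)
  tr4 <- make_traj(vals4, dt = 0.1)
  expect_equal(intra_dibh_stability(tr4, w)[["ap"]], oracle_range(vals4))
})

test_that("setup-shift correction follows the patient-displacement convention", {
  w <- dibh_window(0, 1, "ssd")
  tr <- make_traj(rep(0, 100))
  p <- intra_dibh_position(tr, w)
  p$d <- c(ll = 1, ap = 2, cc = 3)
  p0 <- correct_setup_shift(p, c(0, 0, 0))
  expect_equal(p0$d, c(ll = 1, ap = 2, cc = 3))
  expect_true(p0$corrected)
  pc <- correct_setup_shift(p, c(-1, 0, 0))
  expect_equal(pc$d, c(ll = 0, ap = 2, cc = 3))
  expect_error(correct_setup_shift(pc, c(1, 1, 1)), "already")
  # field windows pass through unchanged but are marked corrected
  wf <- dibh_window(0, 1, "field")
  pf <- intra_dibh_position(tr, wf)
  pf$d <- c(ll = 1, ap = 2, cc = 3)
  pf2 <- correct_setup_shift(pf, c(5, 5, 5))
  expect_equal(pf2$d, c(ll = 1, ap = 2, cc = 3))
  expect_true(pf2$corrected)
})

test_that("V, W and F match brute-force oracles on small inputs", {
  d <- cbind(0:4, 0:4, 0:4)
  V <- intrafraction_reproducibility(d)
  expect_equal(as.numeric(V), rep(oracle_range(0:4), 3))
  expect_equal(as.numeric(intrafraction_reproducibility(cbind(1, 1, 1) %x%
                                                          rep(1, 5))),
               rep(0, 3))
  expect_true(all(is.na(intrafraction_reproducibility(d[1, , drop = FALSE]))))
  # two sessions whose baseline-corrected positions pool to {-1,-1,1,1}
  d_by <- list(cbind(c(4, 4), c(-1, -1), c(0, 2)),
               cbind(c(6, 6), c(1, 1), c(10, 12)))
  f_by <- list(c(5, 0, 1), c(5, 0, 11))
  W <- interfraction_reproducibility(d_by, f_by)
  expect_equal(W[["ll"]], oracle_range(c(-1, -1, 1, 1)))
  expect_equal(W[["ap"]], oracle_range(c(-1, -1, 1, 1)))
  expect_equal(W[["cc"]], oracle_range(c(-1, -1, 1, 1)))
  # F: deviations {-1, 0, 1} about the baseline give median |dev| = 1
  b_by <- list(rbind(c(-1, -1, -1), c(0, 0, 0), c(1, 1, 1)))
  f0 <- list(c(0, 0, 0))
  expect_equal(as.numeric(free_breathing_stability(b_by, f0)),
               rep(1, 3))
  expect_equal(as.numeric(free_breathing_stability(
    list(rbind(c(2, 2, 2), c(2, 2, 2))), list(c(2, 2, 2)))), rep(0, 3))
})

test_that("session baseline is the per-axis median of fb positions", {
  b <- rbind(c(1, 10, 100), c(3, 30, 300), c(5, 50, 500))
  expect_equal(as.numeric(session_baseline(b)), c(3, 30, 300))
  expect_equal(as.numeric(session_baseline(b[2, , drop = FALSE])),
               c(3, 30, 300))
})

test_that("free-breathing position handles symmetry and missing cycles", {
  n <- 200
  tt <- (seq_len(n) - 1) * 0.02
  sine <- sin(2 * pi * tt / 4)[tt < 4]   # one full cycle centred at 0
  tr <- make_traj(2 + 0 * tt)
  w <- dibh_window(3.99, 4.2, "field",
                   pre_fb_intervals = rbind(c(0, 3.98)))
  expect_equal(free_breathing_position(tr, w)[["ap"]], 2)
  tr2 <- make_traj(c(sine, rep(9, n - length(sine))))
  expect_equal(free_breathing_position(tr2, w)[["ap"]], 0, tolerance = 1e-9)
  w_none <- dibh_window(3.99, 4.2, "field")
  expect_true(all(is.na(free_breathing_position(tr, w_none))))
})

test_that("baseline subtraction cancels per-session constant offsets", {
  set.seed(23)
  d_by <- lapply(1:4, function(i) matrix(rnorm(15), 5, 3))
  b_by <- lapply(1:4, function(i) matrix(rnorm(9), 3, 3))
  f_by <- lapply(b_by, session_baseline)
  W0 <- interfraction_reproducibility(d_by, f_by)
  offs <- lapply(1:4, function(i) rnorm(3, 0, 50))
  d_sh <- Map(function(d, o) sweep(d, 2, o, "+"), d_by, offs)
  b_sh <- Map(function(b, o) sweep(b, 2, o, "+"), b_by, offs)
  f_sh <- lapply(b_sh, session_baseline)
  W1 <- interfraction_reproducibility(d_sh, f_sh)
  expect_equal(W1, W0, tolerance = 1e-12)
})

test_that("volume correlation handles exact, degenerate and sparse cases", {
  v <- c(2.6, 2.65, 2.7, 2.75, 2.8)
  expect_equal(volume_correlation(3 + 10 * v, v), 1)
  expect_equal(volume_correlation(3 - 10 * v, v), -1)
  expect_true(is.na(volume_correlation(c(1, 2, 3, 4, 5), rep(2.7, 5))))
  expect_true(is.na(volume_correlation(c(1, 2), c(2.6, 2.7))))
})

test_that("cohort report aggregates reproduce a by-hand computation", {
  cfg <- quick_config(seed = 71L, n_sessions = 3L,
                      n_markers = c(breast = 2L, thorax = 2L, abdomen = 1L))
  rep <- compute_variability(simulate_cohort(cfg))
  expect_identical(nrow(rep$interfraction), 5L * 3L)
  expect_true(all(rep$interfraction$W >= 0))
  expect_true(all(rep$positions$S >= 0, na.rm = TRUE))
  expect_true(all(abs(rep$pearson$r) <= 1, na.rm = TRUE))
  agg <- aggregate_report(rep)
  # recompute the breast W median by hand from marker-level values
  breast_w <- rep$interfraction[rep$interfraction$region == "breast" &
                                  rep$interfraction$axis == "cc", "W"]
  expect_equal(agg$median[agg$group == "breast" & agg$index == "W" &
                            agg$axis == "cc"],
               oracle_median(breast_w))
  # single-marker group: the aggregate is the marker itself
  abd_w <- rep$interfraction[rep$interfraction$region == "abdomen" &
                               rep$interfraction$axis == "ll", "W"]
  expect_equal(agg$median[agg$group == "abdomen" & agg$index == "W" &
                            agg$axis == "ll"], abd_w)
  # warning (not error) when a region has no markers
  cfg2 <- quick_config(seed = 72L,
                       n_markers = c(breast = 1L, thorax = 1L, abdomen = 0L))
  expect_warning(aggregate_report(compute_variability(simulate_cohort(cfg2))),
                 "abdomen")
})

test_that("pre- and post-setup holds agree after shift correction", {
  cfg <- quiet_config(seed = 73L, n_sessions = 2L,
                      setup_shift_mm = c(3, -2, 1))
  rep <- compute_variability(simulate_cohort(cfg))
  pos <- rep$positions
  for (mk in unique(pos$marker_id)) {
    for (a in linac_axes()) {
      sub <- pos[pos$marker_id == mk & pos$axis == a & pos$session == 1, ]
      expect_lt(diff(range(sub$d)), 1e-9)
    }
  }
})
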