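test_that("gating window follows the 90% / +/- 0.1 L rule", {
  gw <- compute_gating_window(3.0)
  expect_equal(gw$center, 2.7)
  expect_equal(gw$lower, 2.6)
  expect_equal(gw$upper, 2.8)
  expect_equal(unlist(compute_gating_window(1.0)), c(center = 0.9, lower = 0.8, upper = 1.0))
  expect_equal(unlist(compute_gating_window(2.0)), c(center = 1.8, lower = 1.7, upper = 1.9))
  expect_error(compute_gating_window(0), "positive")
  expect_error(compute_gating_window(-1), "positive")
})

test_that("simulation is deterministic under the seed", {
  cfg <- quick_config(seed = 77L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$truth, b$truth)
  # and byte-identical on disk
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
  cfg2 <- quick_config(seed = 78L)
  expect_false(identical(simulate_cohort(cfg2)$sessions, a$sessions))
})

test_that("volume stays inside the gating window during every plateau", {
  co <- simulate_cohort(quick_config(seed = 5L))
  for (s in co$sessions) {
    for (w in s$dibh_windows) {
      sel <- s$volume$time_s >= w$start_s & s$volume$time_s <= w$end_s
      v <- s$volume$volume_l[sel]
      expect_true(all(v >= s$gating$lower & v <= s$gating$upper))
    }
  }
})

test_that("with all variability sources off, plateau coordinates are constant", {
  co <- simulate_cohort(quiet_config(seed = 9L, n_sessions = 2L))
  for (s in co$sessions) {
    for (w in s$dibh_windows) {
      for (tr in s$trajectories) {
        sel <- tr$time_s >= w$start_s & tr$time_s <= w$end_s
        spread <- apply(tr$coords[sel, , drop = FALSE], 2,
                        function(x) diff(range(x)))
        expect_lt(max(spread), 1e-9)
      }
    }
  }
})

test_that("linear drift produces the expected intra-plateau range", {
  drift <- matrix(0, 3, 3, dimnames = list(c("breast", "thorax", "abdomen"),
                                           linac_axes()))
  drift["thorax", "cc"] <- 0.2
  co <- simulate_cohort(quiet_config(
    seed = 2L, n_sessions = 2L, sample_rate = 50,
    drift_mm_per_s = drift, plateau_duration_s = c(20, 20)))
  s <- co$sessions[[1]]
  thorax <- Filter(function(tr) tr$region == "thorax", s$trajectories)[[1]]
  w <- s$dibh_windows[[1]]
  sel <- thorax$time_s >= w$start_s & thorax$time_s <= w$end_s
  cc_range <- diff(range(thorax$coords[sel, "cc"]))
  expect_equal(cc_range, 4.0, tolerance = 0.01)
  # other axes unaffected
  expect_lt(diff(range(thorax$coords[sel, "ll"])), 1e-9)
})

test_that("thoracic CC and abdominal AP trade off at constant volume", {
  co <- simulate_cohort(quiet_config(
    seed = 13L, n_sessions = 2L, dibhs_per_session = 6L,
    alpha_dibh_sd = 0.08))
  rep <- compute_variability(co)
  pos <- rep$positions
  s1 <- pos[pos$session == 1, ]
  thor_cc <- s1$d[s1$region == "thorax" & s1$axis == "cc"]
  abd_ap <- s1$d[s1$region == "abdomen" & s1$axis == "ap"]
  vols <- unique(s1[, c("dibh", "volume_mean")])$volume_mean
  # volume essentially constant while both coordinates move
  expect_lt(diff(range(vols)), 1e-6)
  expect_gt(sd(thor_cc), 0.5)
  expect_gt(sd(abd_ap), 0.5)
  expect_lt(cor(thor_cc, abd_ap), -0.99)
})

test_that("cohort emits the expected number of breath-hold windows", {
  cfg <- quick_config(seed = 3L, n_sessions = 7L, dibhs_per_session = 5L,
                      sample_rate = 10)
  co <- simulate_cohort(cfg)
  n_windows <- sum(vapply(co$sessions, function(s) length(s$dibh_windows),
                          integer(1)))
  expect_identical(n_windows, 35L)
  types <- vapply(co$sessions[[1]]$dibh_windows, `[[`, character(1), "type")
  expect_identical(types, c("ssd", "portal", "field", "field", "field"))
})

test_that("ground-truth positions equal medians of noise-free coordinates", {
  # offsets and drift on, but no noise: emitted == noise-free
  cfg <- quiet_config(seed = 21L, n_sessions = 2L,
                      dibh_offset_sd_mm = 1.0, session_offset_sd_mm = 1.0,
                      marker_scatter_sd_mm = 0.4,
                      setup_shift_mm = c(2, -1, 3))
  out <- simulate_session(cfg, 1L)
  s <- out$session; gt <- out$truth
  for (m in seq_along(s$trajectories)) {
    tr <- s$trajectories[[m]]
    for (i in seq_along(s$dibh_windows)) {
      w <- s$dibh_windows[[i]]
      p <- intra_dibh_position(tr, w)
      p <- correct_setup_shift(p, s$setup_shift_mm)
      expect_equal(as.numeric(p$d), as.numeric(gt$d_true[m, i, ]),
                   tolerance = 1e-9)
      b <- free_breathing_position(tr, w)
      expect_equal(as.numeric(b), as.numeric(gt$b_true[m, i, ]),
                   tolerance = 1e-9)
    }
  }
})

test_that("no between-session source means W tracks V", {
  cfg <- quiet_config(seed = 31L, n_sessions = 6L, dibhs_per_session = 30L,
                      sample_rate = 10, plateau_duration_s = c(5, 6),
                      n_markers = c(breast = 1L, thorax = 0L, abdomen = 0L),
                      dibh_offset_sd_mm = 1.0)
  rep <- suppressWarnings(compute_variability(simulate_cohort(cfg)))
  for (a in linac_axes()) {
    V_med <- median(rep$intrafraction$V[rep$intrafraction$axis == a])
    W <- rep$interfraction$W[rep$interfraction$axis == a]
    expect_lt(abs(W - V_med) / V_med, 0.2)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(dibhs_per_session = 3), "at least 4")
  expect_error(simulation_config(sample_rate = 0), "sample_rate")
  expect_error(simulation_config(plateau_duration_s = c(2, 1)), "range")
  expect_error(simulation_config(plateau_duration_s = c(0.01, 1),
                                 sample_rate = 50),
               "shorter than")
  expect_error(simulation_config(setup_shift_mm = c(0.5, 0, 0)),
               "multiples of 1 mm")
  expect_error(simulation_config(n_fb_cycles = 0), "free-breathing cycle")
})
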