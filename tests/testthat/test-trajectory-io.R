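test_that("session records round-trip through the CSV/JSON dialect", {
  co <- simulate_cohort(quick_config(seed = 55L, n_sessions = 1L))
  s <- co$sessions[[1]]
  td <- tempfile("io"); dir.create(td)
  paths <- write_session(s, file.path(td, "t.csv"), file.path(td, "v.csv"),
                         file.path(td, "m.json"))
  s2 <- read_session(paths["trajectory"], paths["volume"], paths["metadata"])
  expect_identical(s2$session_index, s$session_index)
  expect_equal(s2$setup_shift_mm, s$setup_shift_mm)
  expect_equal(s2$volume$volume_l, s$volume$volume_l, tolerance = 1e-9)
  expect_identical(length(s2$trajectories), length(s$trajectories))
  for (m in seq_along(s$trajectories)) {
    expect_identical(s2$trajectories[[m]]$marker_id,
                     s$trajectories[[m]]$marker_id)
    expect_identical(s2$trajectories[[m]]$region, s$trajectories[[m]]$region)
    expect_equal(s2$trajectories[[m]]$coords, s$trajectories[[m]]$coords,
                 tolerance = 1e-9)
    expect_identical(s2$trajectories[[m]]$valid, s$trajectories[[m]]$valid)
  }
  for (i in seq_along(s$dibh_windows)) {
    expect_equal(s2$dibh_windows[[i]]$start_s, s$dibh_windows[[i]]$start_s)
    expect_identical(s2$dibh_windows[[i]]$type, s$dibh_windows[[i]]$type)
    expect_equal(s2$dibh_windows[[i]]$pre_fb_intervals,
                 s$dibh_windows[[i]]$pre_fb_intervals, tolerance = 1e-12)
  }
  unlink(td, recursive = TRUE)
})

test_that("malformed session files raise named schema errors", {
  co <- simulate_cohort(quick_config(seed = 56L, n_sessions = 1L))
  s <- co$sessions[[1]]
  td <- tempfile("bad"); dir.create(td)
  paths <- write_session(s, file.path(td, "t.csv"), file.path(td, "v.csv"),
                         file.path(td, "m.json"))
  # a breath-hold window beyond the last timestamp
  meta <- jsonlite::read_json(paths[["metadata"]], simplifyVector = FALSE)
  meta$dibh_windows[[1]]$end_s <- 1e6
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_session(paths["trajectory"], paths["volume"],
                            paths["metadata"]),
               "outside the")
  # unknown region
  tr <- utils::read.csv(paths[["trajectory"]])
  tr$region[1] <- "pelvis"
  utils::write.csv(tr, paths[["trajectory"]], row.names = FALSE)
  expect_error(read_session(paths["trajectory"], paths["volume"],
                            paths["metadata"]),
               "unknown region")
  expect_error(read_session("nope.csv", paths["volume"], paths["metadata"]),
               "not found")
  unlink(td, recursive = TRUE)
})

test_that("invalid samples are excluded from downstream statistics", {
  co <- simulate_cohort(quick_config(seed = 57L, n_sessions = 1L))
  s <- co$sessions[[1]]
  tr <- s$trajectories[[1]]
  w <- s$dibh_windows[[3]]
  sel <- which(tr$time_s >= w$start_s & tr$time_s <= w$end_s)
  # corrupt 30% of in-window samples and mask them
  bad <- sel[seq(1, length(sel), by = 3)]
  tr2 <- tr
  tr2$coords[bad, ] <- tr2$coords[bad, ] + 500
  tr2$valid[bad] <- FALSE
  p2 <- intra_dibh_position(tr2, w)
  keep <- setdiff(sel, bad)
  manual <- apply(tr$coords[keep, ], 2, median)
  expect_equal(as.numeric(p2$d), as.numeric(manual))
  s2 <- intra_dibh_stability(tr2, w)
  manual_s <- apply(tr$coords[keep, ], 2, oracle_range)
  expect_equal(as.numeric(s2), as.numeric(manual_s))
  # metamorphic: masking a sample outside the window changes nothing
  tr3 <- tr
  outside <- which(tr$time_s < w$start_s)[1]
  tr3$valid[outside] <- FALSE
  expect_equal(intra_dibh_position(tr3, w)$d, intra_dibh_position(tr, w)$d)
  # below 50% validity the position is missing
  tr4 <- tr
  tr4$valid[sel[seq_len(ceiling(0.6 * length(sel)))]] <- FALSE
  expect_true(all(is.na(intra_dibh_position(tr4, w)$d)))
})

test_that("reports round-trip as schema-versioned JSON", {
  co <- simulate_cohort(quick_config(seed = 58L))
  rep <- compute_variability(co)
  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  back <- read_report(f)
  expect_equal(back$interfraction$W, rep$interfraction$W, tolerance = 1e-12)
  expect_equal(back$positions$d, rep$positions$d, tolerance = 1e-12)
  # one W entry per marker and axis
  expect_identical(nrow(back$interfraction), 3L * 3L)
  # an empty report section still round-trips as valid JSON
  write_report(list(positions = data.frame()), f)
  expect_true(is.list(read_report(f)))
  expect_error(read_report(tempfile()), "not found")
  unlink(f)
})

test_that("cohorts round-trip through a directory", {
  cfg <- quick_config(seed = 59L, n_sessions = 2L)
  co <- simulate_cohort(cfg)
  td <- tempfile("coh")
  write_cohort(co, td)
  back <- read_cohort(td)
  expect_identical(length(back$sessions), 2L)
  expect_equal(back$planning$ll, co$planning$ll, tolerance = 1e-9)
  # planning reader accepts both column dialects
  pl <- read_planning(file.path(td, "planning.csv"))
  expect_identical(dim(pl), c(3L, 3L))
  unlink(td, recursive = TRUE)
})
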