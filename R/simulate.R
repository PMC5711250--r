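#' Spirometric gating window
#'
#' The breath-hold target volume is set to 90% of the patient's maximum
#' inspiratory capacity, and breath holds are accepted while the inspired
#' volume stays within a tolerance of +/- 0.1 litres around that level.
#'
#' @param max_inspiratory_capacity Maximum inspiratory capacity (litres, > 0).
#' @param tolerance_l Half-width of the acceptance band (litres, default 0.1).
#' @return List with `center`, `lower`, `upper` (litres).
#' @examples
#' compute_gating_window(3.0)  # center 2.7, bounds 2.6 / 2.8 L
#' @export
compute_gating_window <- function(max_inspiratory_capacity, tolerance_l = 0.1) {
  if (!is.numeric(max_inspiratory_capacity) ||
      length(max_inspiratory_capacity) != 1L ||
      !is.finite(max_inspiratory_capacity) ||
      max_inspiratory_capacity <= 0) {
    stop("maximum inspiratory capacity must be a positive number of litres",
         call. = FALSE)
  }
  center <- 0.9 * max_inspiratory_capacity
  list(center = center, lower = center - tolerance_l,
       upper = center + tolerance_l)
}

#' Configuration of the breath-hold cohort simulator
#'
#' Defines the study conditions emulated by the synthetic cohort: a patient
#' monitored over several treatment sessions, each with a fixed number of
#' spirometer-gated deep-inspiration breath holds (DIBHs) preceded by free
#' breathing, tracked through passive surface markers grouped into breast,
#' thorax and abdomen regions.
#'
#' The generative model, per marker coordinate:
#' free breathing follows a raised-cosine-squared waveform (long end-exhale
#' dwell) with 5% per-cycle period/amplitude jitter; each breath hold ramps
#' to a plateau held inside the volumetric gating window, with a linear
#' (optionally Brownian) drift, a between-DIBH offset shared by all markers
#' (`dibh_offset_sd_mm`), a per-marker scatter (`marker_scatter_sd_mm`), and a
#' between-session offset applied to breath-hold plateaus only
#' (`session_offset_sd_mm`) — the constant-volume session-to-session surface
#' displacement that free-breathing baseline subtraction cannot remove.
#' The inspired volume is a fixed positive linear combination of the thoracic
#' CC and abdominal AP compartment displacements (`volume_coupling`, litres
#' per mm) plus hold logic; during plateaus the thoracic/abdominal share of
#' the held volume (`alpha_split` with per-DIBH and per-session jitter)
#' varies, reproducing the inverse thoracic-CC / abdominal-AP relationship at
#' constant inspired volume.
#'
#' @param n_markers Named integer vector: markers per region
#'   (`breast`, `thorax`, `abdomen`).
#' @param n_sessions Monitored sessions (default 7).
#' @param dibhs_per_session Breath holds per session (>= 4; the first is an
#'   SSD check, the second a portal acquisition, the rest field deliveries).
#' @param sample_rate Optical tracker sampling rate, Hz.
#' @param fb_period Mean free-breathing period, s.
#' @param fb_amplitude_mm 3 x 3 matrix (region x axis) of free-breathing
#'   peak amplitudes, mm.
#' @param dibh_elevation_mm 3 x 3 matrix of plateau elevations above the
#'   free-breathing end-exhale level, mm. The thorax-CC and abdomen-AP
#'   entries are superseded by the volume partition.
#' @param drift_mm_per_s 3 x 3 matrix of linear intra-plateau drift rates.
#' @param drift_brownian_sd Brownian drift increment SD, mm per sqrt(s).
#' @param plateau_duration_s Length-2 range of plateau durations, s.
#' @param max_inspiratory_capacity Litres; gating window derives from it.
#' @param volume_coupling Named vector `c(cc=, ap=)`: litres of inspired
#'   volume per mm of thoracic-CC / abdominal-AP compartment displacement.
#' @param alpha_split Nominal thoracic share of the held volume.
#' @param alpha_dibh_sd,alpha_session_sd Jitter SDs of the thoracic share
#'   per breath hold / per session.
#' @param dibh_offset_sd_mm SD of the constellation-wide between-DIBH
#'   position offset at constant volume, mm per axis.
#' @param marker_scatter_sd_mm SD of the per-marker between-DIBH scatter, mm.
#' @param session_offset_sd_mm SD of the constellation-wide between-session
#'   plateau offset at constant volume, mm per axis.
#' @param session_transform `NULL` (identity), a single [rigid_transform()]
#'   applied to every session, or a list of per-session transforms —
#'   emulates a planning-to-treatment setup displacement.
#' @param setup_shift_mm Couch correction applied after the portal breath
#'   hold: `NULL` draws one per session (rounded to the 1 mm couch
#'   resolution), a length-3 vector is recycled, or an `n_sessions` x 3
#'   matrix gives one per session.
#' @param n_fb_cycles Complete free-breathing cycles emitted before each
#'   breath hold (>= 1).
#' @param fb_jitter_cv Coefficient of variation of per-cycle period and
#'   amplitude jitter.
#' @param volume_jitter_sd_l SD of the held volume around the window center,
#'   litres (truncated to stay inside the window).
#' @param volume_wiggle_l Amplitude of the slow intra-plateau volume
#'   oscillation, litres.
#' @param ramp_up_s,ramp_down_s Inhale/exhale ramp durations, s.
#' @param noise_sd_mm Isotropic Gaussian measurement noise SD per sample, mm.
#' @param dropout_rate Fraction of samples flagged invalid (tracker dropout).
#' @param seed Integer seed; together with the session index it fully
#'   determines the output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_markers = c(breast = 2L, thorax = 3L, abdomen = 3L),
    n_sessions = 7L,
    dibhs_per_session = 5L,
    sample_rate = 50,
    fb_period = 4.0,
    fb_amplitude_mm = rbind(breast = c(0.5, 2.0, 2.5),
                            thorax = c(0.5, 2.0, 3.0),
                            abdomen = c(0.5, 4.0, 2.0)),
    dibh_elevation_mm = rbind(breast = c(1.0, 8.0, 8.0),
                              thorax = c(1.0, 6.0, 10.0),
                              abdomen = c(1.0, 12.0, 4.0)),
    drift_mm_per_s = rbind(breast = c(0, -0.05, -0.05),
                           thorax = c(0, -0.05, -0.10),
                           abdomen = c(0, -0.10, -0.05)),
    drift_brownian_sd = 0,
    plateau_duration_s = c(5, 20),
    max_inspiratory_capacity = 3.0,
    volume_coupling = c(cc = 0.135, ap = 0.1125),
    alpha_split = 0.5,
    alpha_dibh_sd = 0.04,
    alpha_session_sd = 0.04,
    dibh_offset_sd_mm = 0.8,
    marker_scatter_sd_mm = 0.3,
    session_offset_sd_mm = 1.0,
    session_transform = NULL,
    setup_shift_mm = NULL,
    n_fb_cycles = 2L,
    fb_jitter_cv = 0.05,
    volume_jitter_sd_l = 0.04,
    volume_wiggle_l = 0.015,
    ramp_up_s = 2.0,
    ramp_down_s = 1.5,
    noise_sd_mm = 0.3,
    dropout_rate = 0,
    seed = 1L) {
  regions <- c("breast", "thorax", "abdomen")
  n_markers <- as.integer(n_markers[regions])
  names(n_markers) <- regions
  fix_mat <- function(m, what) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(3L, 3L))) {
      stop(what, " must be a 3 x 3 (region x axis) matrix", call. = FALSE)
    }
    rownames(m) <- regions
    colnames(m) <- linac_axes()
    m
  }
  fb_amplitude_mm <- fix_mat(fb_amplitude_mm, "fb_amplitude_mm")
  dibh_elevation_mm <- fix_mat(dibh_elevation_mm, "dibh_elevation_mm")
  drift_mm_per_s <- fix_mat(drift_mm_per_s, "drift_mm_per_s")
  if (any(n_markers < 0L) || sum(n_markers) < 1L) {
    stop("at least one marker is required", call. = FALSE)
  }
  if (any(fb_amplitude_mm < 0) || any(dibh_elevation_mm < 0)) {
    stop("amplitudes and elevations must be non-negative", call. = FALSE)
  }
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (dibhs_per_session < 4L) {
    stop("each session must contain at least 4 breath holds", call. = FALSE)
  }
  if (length(plateau_duration_s) != 2L || plateau_duration_s[1] <= 0 ||
      diff(plateau_duration_s) < 0) {
    stop("plateau_duration_s must be an increasing positive range",
         call. = FALSE)
  }
  min_plateau <- plateau_duration_s[1]
  if (min_plateau < 4 / sample_rate) {
    stop("requested plateau duration is shorter than four sample periods",
         call. = FALSE)
  }
  if (n_fb_cycles < 1L) {
    stop("each breath hold needs at least one preceding free-breathing cycle",
         call. = FALSE)
  }
  gw <- compute_gating_window(max_inspiratory_capacity)
  if (volume_wiggle_l >= 0.5 * (gw$upper - gw$lower)) {
    stop("volume_wiggle_l must be smaller than the gating half-width",
         call. = FALSE)
  }
  stopifnot(all(c("cc", "ap") %in% names(volume_coupling)),
            all(volume_coupling[c("cc", "ap")] > 0),
            noise_sd_mm >= 0, dropout_rate >= 0, dropout_rate < 1,
            dibh_offset_sd_mm >= 0, marker_scatter_sd_mm >= 0,
            session_offset_sd_mm >= 0, drift_brownian_sd >= 0)
  if (!is.null(session_transform)) {
    if (inherits(session_transform, "rigid_transform")) {
      session_transform <- rep(list(session_transform), n_sessions)
    }
    stopifnot(is.list(session_transform),
              length(session_transform) == n_sessions,
              all(vapply(session_transform, inherits, logical(1),
                         "rigid_transform")))
  }
  if (!is.null(setup_shift_mm)) {
    if (is.null(dim(setup_shift_mm))) {
      stopifnot(length(setup_shift_mm) == 3L)
      setup_shift_mm <- matrix(setup_shift_mm, n_sessions, 3L, byrow = TRUE)
    }
    stopifnot(nrow(setup_shift_mm) == n_sessions, ncol(setup_shift_mm) == 3L)
    if (any(abs(setup_shift_mm - round(setup_shift_mm)) > 1e-9)) {
      stop("setup shifts are couch corrections and must be multiples of 1 mm",
           call. = FALSE)
    }
  }
  cfg <- list(
    n_markers = n_markers, n_sessions = as.integer(n_sessions),
    dibhs_per_session = as.integer(dibhs_per_session),
    sample_rate = sample_rate, fb_period = fb_period,
    fb_amplitude_mm = fb_amplitude_mm, dibh_elevation_mm = dibh_elevation_mm,
    drift_mm_per_s = drift_mm_per_s, drift_brownian_sd = drift_brownian_sd,
    plateau_duration_s = plateau_duration_s,
    max_inspiratory_capacity = max_inspiratory_capacity,
    gating = gw, volume_coupling = volume_coupling,
    alpha_split = alpha_split, alpha_dibh_sd = alpha_dibh_sd,
    alpha_session_sd = alpha_session_sd,
    dibh_offset_sd_mm = dibh_offset_sd_mm,
    marker_scatter_sd_mm = marker_scatter_sd_mm,
    session_offset_sd_mm = session_offset_sd_mm,
    session_transform = session_transform,
    setup_shift_mm = setup_shift_mm,
    n_fb_cycles = as.integer(n_fb_cycles), fb_jitter_cv = fb_jitter_cv,
    volume_jitter_sd_l = volume_jitter_sd_l,
    volume_wiggle_l = volume_wiggle_l,
    ramp_up_s = ramp_up_s, ramp_down_s = ramp_down_s,
    noise_sd_mm = noise_sd_mm, dropout_rate = dropout_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Planning marker layout for a simulation configuration
#'
#' Deterministic marker placement in the linac frame: breast markers on the
#' left chest wall, thoracic markers across the sternum/upper chest, and
#' abdominal markers below the submammary line. These double as the
#' "planning CT" marker positions of the simulated patient.
#'
#' @param config A [simulation_config()].
#' @return Data frame: `marker_id`, `region`, `ll`, `ap`, `cc` (mm).
#' @export
marker_layout <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  centers <- rbind(breast = c(60, 90, 20),
                   thorax = c(0, 70, 70),
                   abdomen = c(-10, 100, -120))
  spreads <- rbind(breast = c(35, 8, 25),
                   thorax = c(55, 10, 30),
                   abdomen = c(50, 12, 35))
  rows <- list()
  for (r in rownames(centers)) {
    k <- config$n_markers[[r]]
    if (k == 0L) next
    u <- if (k == 1L) 0 else seq(-1, 1, length.out = k)
    # alternate off-axis offsets give the constellation full 3D extent
    v <- if (k == 1L) 0 else rep_len(c(-1, 1, 0), k) * 0.6
    pos <- cbind(centers[r, 1] + u * spreads[r, 1],
                 centers[r, 2] + v * spreads[r, 2],
                 centers[r, 3] + rev(u) * spreads[r, 3] * 0.8 +
                   v * spreads[r, 3] * 0.2)
    rows[[r]] <- data.frame(
      marker_id = paste0(substr(r, 1, 2), seq_len(k)),
      region = r,
      ll = pos[, 1], ap = pos[, 2], cc = pos[, 3]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Planning (DIBH CT) marker positions
#'
#' The planning CT is acquired within a breath hold, so the planning marker
#' positions are the base layout plus the nominal plateau displacement: the
#' configured elevations, with the thoracic-CC / abdominal-AP compartments
#' at the nominal volume partition of the gating-center volume. A cohort
#' simulated with identity session transforms therefore registers to its
#' planning constellation with near-zero rotations and translations.
#'
#' @param config A [simulation_config()].
#' @return Matrix (marker x 3, mm) with marker ids as row names.
#' @export
planning_positions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- marker_layout(config)
  base <- as.matrix(layout[, linac_axes()])
  rownames(base) <- layout$marker_id
  elev <- config$dibh_elevation_mm
  elev["thorax", "cc"] <- config$alpha_split * config$gating$center /
    config$volume_coupling[["cc"]]
  elev["abdomen", "ap"] <- (1 - config$alpha_split) *
    config$gating$center / config$volume_coupling[["ap"]]
  base + elev[layout$region, ]
}

# Internal: deterministic per-session seed derived from the cohort seed.
derive_seed <- function(seed, session_index) {
  as.integer((as.numeric(seed) * 48271 + session_index * 30103) %% 2147483629)
}

# Internal: raised-cosine-squared breathing waveform on phase [0, 1).
fb_waveform <- function(phase) ((1 - cos(2 * pi * phase)) / 2)^2

#' Simulate one monitored treatment session
#'
#' Generates the optical-tracking record of a single session: marker
#' trajectories at the configured sample rate, the synchronized spirometric
#' volume signal, breath-hold window annotations with their preceding
#' free-breathing cycles, the applied couch setup shift, and a ground-truth
#' sidecar holding every injected quantity plus the noise-free intra-DIBH
#' and free-breathing positions (medians of the noise-free coordinates over
#' the annotated intervals).
#'
#' The first two breath holds (SSD check, portal acquisition) are acquired
#' before the couch correction: their samples — trajectories and the
#' free-breathing segments between them — are displaced by minus the setup
#' shift. Ground-truth intra-DIBH positions are stored setup-corrected.
#'
#' @param config A [simulation_config()].
#' @param session_index Session number (1-based).
#' @return List with elements `session` (a `session_record`) and
#'   `truth` (list of injected parameters and noise-free positions).
#' @export
simulate_session <- function(config, session_index) {
  stopifnot(inherits(config, "simulation_config"),
            session_index >= 1L, session_index <= config$n_sessions)
  cfg <- config
  set.seed(derive_seed(cfg$seed, session_index))
  axes <- linac_axes()
  dt <- 1 / cfg$sample_rate
  gw <- cfg$gating
  n_dibh <- cfg$dibhs_per_session

  ## --- session-level draws (order fixed for reproducibility) -------------
  session_offset <- stats::rnorm(3, 0, cfg$session_offset_sd_mm)
  alpha_session <- stats::rnorm(1, 0, cfg$alpha_session_sd)
  if (is.null(cfg$setup_shift_mm)) {
    setup_shift <- round(stats::rnorm(3, 0, 2))   # couch resolution 1 mm
  } else {
    setup_shift <- as.numeric(cfg$setup_shift_mm[session_index, ])
  }
  transform <- if (is.null(cfg$session_transform)) {
    rigid_transform()
  } else {
    cfg$session_transform[[session_index]]
  }

  layout <- marker_layout(cfg)
  n_mark <- nrow(layout)
  planning <- as.matrix(layout[, axes])
  rownames(planning) <- layout$marker_id

  types <- c("ssd", "portal", rep("field", n_dibh - 2L))[seq_len(n_dibh)]

  ## --- per-block draws and segment assembly ------------------------------
  # Each block: n_fb_cycles free-breathing cycles, inhale ramp, plateau,
  # exhale ramp. Segment lengths are whole numbers of samples.
  ramp_cap <- gw$lower - 0.02  # inhale ramp tops out just below the window
  vol_margin <- cfg$volume_wiggle_l + 0.005
  w_cc <- cfg$volume_coupling[["cc"]]
  w_ap <- cfg$volume_coupling[["ap"]]
  fb_vol_amp <- w_cc * cfg$fb_amplitude_mm["thorax", "cc"] +
    w_ap * cfg$fb_amplitude_mm["abdomen", "ap"]

  seg_vol <- list(); seg_cyc <- list(); seg_env <- list()
  seg_tau <- list(); seg_blk <- list(); seg_wig <- list()
  windows <- vector("list", n_dibh)
  blocks <- vector("list", n_dibh)
  t_cursor <- 0; idx_cursor <- 0L
  push <- function(n) {
    # returns global sample times for a segment of n samples
    tt <- t_cursor + (seq_len(n) - 1L) * dt
    t_cursor <<- t_cursor + n * dt
    idx_cursor <<- idx_cursor + n
    tt
  }
  for (i in seq_len(n_dibh)) {
    pre_fb <- matrix(NA_real_, cfg$n_fb_cycles, 2L)
    for (j in seq_len(cfg$n_fb_cycles)) {
      period <- cfg$fb_period * (1 + cfg$fb_jitter_cv * stats::rnorm(1))
      amp <- max(0.2, 1 + cfg$fb_jitter_cv * stats::rnorm(1))
      n_s <- max(4L, round(period / dt))
      tt <- push(n_s)
      phase <- (seq_len(n_s) - 1L) / n_s
      cyc <- amp * fb_waveform(phase)
      pre_fb[j, ] <- c(tt[1], tt[n_s] + dt)  # cycle spans up to next segment
      seg_vol[[length(seg_vol) + 1L]] <- fb_vol_amp * cyc
      seg_cyc[[length(seg_cyc) + 1L]] <- cyc
      seg_env[[length(seg_env) + 1L]] <- numeric(n_s)
      seg_tau[[length(seg_tau) + 1L]] <- numeric(n_s)
      seg_wig[[length(seg_wig) + 1L]] <- numeric(n_s)
      seg_blk[[length(seg_blk) + 1L]] <- rep.int(i, n_s)
    }
    # inhale ramp
    n_up <- max(2L, round(cfg$ramp_up_s / dt))
    tt <- push(n_up)
    s_up <- (1 - cos(pi * seq_len(n_up) / n_up)) / 2
    seg_vol[[length(seg_vol) + 1L]] <- ramp_cap * s_up
    seg_cyc[[length(seg_cyc) + 1L]] <- numeric(n_up)
    seg_env[[length(seg_env) + 1L]] <- s_up
    seg_tau[[length(seg_tau) + 1L]] <- numeric(n_up)
    seg_wig[[length(seg_wig) + 1L]] <- numeric(n_up)
    seg_blk[[length(seg_blk) + 1L]] <- rep.int(i, n_up)
    # plateau
    dur <- stats::runif(1, cfg$plateau_duration_s[1], cfg$plateau_duration_s[2])
    n_pl <- max(4L, round(dur / dt))
    v_hold <- gw$center + stats::rnorm(1, 0, cfg$volume_jitter_sd_l)
    v_hold <- min(max(v_hold, gw$lower + vol_margin), gw$upper - vol_margin)
    alpha <- cfg$alpha_split + alpha_session +
      stats::rnorm(1, 0, cfg$alpha_dibh_sd)
    alpha <- min(max(alpha, 0.05), 0.95)
    dibh_offset <- stats::rnorm(3, 0, cfg$dibh_offset_sd_mm)
    scatter <- matrix(stats::rnorm(n_mark * 3, 0, cfg$marker_scatter_sd_mm),
                      n_mark, 3L)
    tt <- push(n_pl)
    tau <- (seq_len(n_pl) - 1L) * dt
    wig <- cfg$volume_wiggle_l * sin(2 * pi * tau / 3)
    brown <- if (cfg$drift_brownian_sd > 0) {
      matrix(stats::rnorm(n_pl * 3, 0, cfg$drift_brownian_sd * sqrt(dt)),
             n_pl, 3L)
    } else NULL
    seg_vol[[length(seg_vol) + 1L]] <- v_hold + wig
    seg_cyc[[length(seg_cyc) + 1L]] <- numeric(n_pl)
    seg_env[[length(seg_env) + 1L]] <- rep.int(1, n_pl)
    seg_tau[[length(seg_tau) + 1L]] <- tau
    seg_wig[[length(seg_wig) + 1L]] <- wig
    seg_blk[[length(seg_blk) + 1L]] <- rep.int(i, n_pl)
    windows[[i]] <- list(start_s = tt[1], end_s = tt[n_pl], type = types[i],
                         pre_fb = pre_fb)
    blocks[[i]] <- list(v_hold = v_hold, alpha = alpha,
                        dibh_offset = dibh_offset, scatter = scatter,
                        brown = if (is.null(brown)) NULL else apply(brown, 2, cumsum),
                        plateau_idx = (idx_cursor - n_pl + 1L):idx_cursor)
    # exhale ramp
    n_dn <- max(2L, round(cfg$ramp_down_s / dt))
    push(n_dn)
    s_dn <- (1 - cos(pi * seq_len(n_dn) / n_dn)) / 2
    seg_vol[[length(seg_vol) + 1L]] <- ramp_cap * (1 - s_dn)
    seg_cyc[[length(seg_cyc) + 1L]] <- numeric(n_dn)
    seg_env[[length(seg_env) + 1L]] <- 1 - s_dn
    seg_tau[[length(seg_tau) + 1L]] <- numeric(n_dn)
    seg_wig[[length(seg_wig) + 1L]] <- numeric(n_dn)
    seg_blk[[length(seg_blk) + 1L]] <- rep.int(i, n_dn)
  }

  vol <- unlist(seg_vol, use.names = FALSE)
  cycfac <- unlist(seg_cyc, use.names = FALSE)
  env <- unlist(seg_env, use.names = FALSE)
  tau_pl <- unlist(seg_tau, use.names = FALSE)
  wig_v <- unlist(seg_wig, use.names = FALSE)
  blk <- unlist(seg_blk, use.names = FALSE)
  n_tot <- length(vol)
  times <- (seq_len(n_tot) - 1L) * dt

  v_hold_b <- vapply(blocks, `[[`, numeric(1), "v_hold")
  alpha_b <- vapply(blocks, `[[`, numeric(1), "alpha")
  off_b <- t(vapply(blocks, `[[`, numeric(3), "dibh_offset"))
  alpha_s <- alpha_b[blk]

  # regional displacement fields shared by all markers of a region
  disp_region <- array(0, dim = c(n_tot, 3L, 3L),
                       dimnames = list(NULL, rownames(cfg$fb_amplitude_mm),
                                       axes))
  for (ri in 1:3) {
    r <- rownames(cfg$fb_amplitude_mm)[ri]
    for (ai in 1:3) {
      a <- axes[ai]
      if (r == "thorax" && a == "cc") {
        plat <- alpha_s * (v_hold_b[blk] / w_cc)
        d <- cfg$fb_amplitude_mm[r, a] * cycfac + env * plat +
          alpha_s * wig_v / w_cc
      } else if (r == "abdomen" && a == "ap") {
        plat <- (1 - alpha_s) * (v_hold_b[blk] / w_ap)
        d <- cfg$fb_amplitude_mm[r, a] * cycfac + env * plat +
          (1 - alpha_s) * wig_v / w_ap
      } else {
        d <- cfg$fb_amplitude_mm[r, a] * cycfac +
          env * cfg$dibh_elevation_mm[r, a]
      }
      d <- d + env * (off_b[blk, ai] + session_offset[ai]) +
        cfg$drift_mm_per_s[r, a] * tau_pl
      if (cfg$drift_brownian_sd > 0) {
        for (i in seq_len(n_dibh)) {
          pidx <- blocks[[i]]$plateau_idx
          d[pidx] <- d[pidx] + blocks[[i]]$brown[, ai]
        }
      }
      disp_region[, ri, ai] <- d
    }
  }

  ## --- assemble marker trajectories --------------------------------------
  region_index <- match(layout$region, rownames(cfg$fb_amplitude_mm))
  identity_tf <- all(transform$rotations_deg == 0) &&
    all(transform$translations_mm == 0)
  setup_end_idx <- {
    first_field <- match("field", types)
    min(which(blk == first_field)) - 1L   # correction applied before block 3
  }
  d_true <- array(NA_real_, dim = c(n_mark, n_dibh, 3L),
                  dimnames = list(layout$marker_id, NULL, axes))
  b_true <- array(NA_real_, dim = c(n_mark, n_dibh, 3L),
                  dimnames = list(layout$marker_id, NULL, axes))
  trajectories <- vector("list", n_mark)
  fb_idx <- lapply(seq_len(n_dibh), function(i) {
    w <- windows[[i]]
    unlist(lapply(seq_len(nrow(w$pre_fb)), function(j) {
      which(times >= w$pre_fb[j, 1] & times < w$pre_fb[j, 2])
    }), use.names = FALSE)
  })
  for (m in seq_len(n_mark)) {
    coords <- matrix(planning[m, ], n_tot, 3L, byrow = TRUE) +
      disp_region[, region_index[m], ]
    for (i in seq_len(n_dibh)) {
      sc <- blocks[[i]]$scatter[m, ]
      sel <- blk == i
      coords[sel, ] <- coords[sel, ] + env[sel] %o% sc
    }
    if (!identity_tf) coords <- apply_transform(transform, coords)
    # noise-free references: intra-DIBH positions are stored setup-corrected
    for (i in seq_len(n_dibh)) {
      pidx <- blocks[[i]]$plateau_idx
      d_true[m, i, ] <- apply(coords[pidx, , drop = FALSE], 2, stats::median)
    }
    if (setup_end_idx >= 1L) {
      coords[seq_len(setup_end_idx), ] <-
        sweep(coords[seq_len(setup_end_idx), , drop = FALSE], 2, setup_shift)
    }
    for (i in seq_len(n_dibh)) {
      b_true[m, i, ] <- apply(coords[fb_idx[[i]], , drop = FALSE], 2,
                              stats::median)
    }
    if (cfg$noise_sd_mm > 0) {
      coords <- coords + matrix(stats::rnorm(n_tot * 3, 0, cfg$noise_sd_mm),
                                n_tot, 3L)
    }
    valid <- rep(TRUE, n_tot)
    if (cfg$dropout_rate > 0) {
      valid[stats::runif(n_tot) < cfg$dropout_rate] <- FALSE
    }
    colnames(coords) <- axes
    trajectories[[m]] <- marker_trajectory(
      marker_id = layout$marker_id[m], region = layout$region[m],
      time_s = times, coords = coords, valid = valid
    )
  }

  dibh_windows <- lapply(windows, function(w) {
    dibh_window(start_s = w$start_s, end_s = w$end_s, type = w$type,
                pre_fb_intervals = w$pre_fb)
  })
  session <- session_record(
    session_index = session_index,
    trajectories = trajectories,
    volume = data.frame(time_s = times, volume_l = vol),
    dibh_windows = dibh_windows,
    setup_shift_mm = setup_shift,
    gating = gw
  )
  truth <- list(
    session_index = session_index,
    planning = planning,
    session_offset_mm = stats::setNames(session_offset, axes),
    alpha_session = alpha_session,
    setup_shift_mm = stats::setNames(setup_shift, axes),
    transform = transform,
    v_hold_l = v_hold_b,
    alpha = alpha_b,
    dibh_offsets_mm = off_b,
    d_true = d_true,
    b_true = b_true,
    f_true = apply(b_true, c(1, 3), stats::median),
    windows = do.call(rbind, lapply(seq_along(windows), function(i) {
      data.frame(dibh = i, start_s = windows[[i]]$start_s,
                 end_s = windows[[i]]$end_s, type = windows[[i]]$type)
    })),
    pre_fb = lapply(windows, `[[`, "pre_fb"),
    gating = gw
  )
  list(session = session, truth = truth)
}

#' Simulate a full monitored cohort for one patient
#'
#' Runs [simulate_session()] for every configured session and optionally
#' writes the dataset to disk in the package's plain-text interchange
#' formats (per-session trajectory and volume CSV files plus JSON metadata
#' and ground-truth sidecars; see [write_session()]).
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; created if missing.
#' @return List with `sessions` (list of `session_record`), `truth`
#'   (per-session ground-truth sidecars), `planning` (marker layout data
#'   frame) and `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  out <- lapply(seq_len(config$n_sessions),
                function(n) simulate_session(config, n))
  planning_df <- marker_layout(config)
  planning_df[, linac_axes()] <- planning_positions(config)
  cohort <- list(
    sessions = lapply(out, `[[`, "session"),
    truth = lapply(out, `[[`, "truth"),
    planning = planning_df,
    config = config
  )
  class(cohort) <- "dibh_cohort"
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.dibh_cohort <- function(x, ...) {
  n_w <- sum(vapply(x$sessions, function(s) length(s$dibh_windows), integer(1)))
  cat(sprintf(
    "DIBH cohort: %d sessions, %d markers (%s), %d breath-hold windows\n",
    length(x$sessions), nrow(x$planning),
    paste(names(x$config$n_markers), x$config$n_markers,
          sep = "=", collapse = ", "),
    n_w))
  invisible(x)
}
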