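#' Intra-DIBH marker position
#'
#' Per-axis median of a marker's coordinates over the valid samples of one
#' breath-hold window. The median makes the position robust to isolated
#' spikes; at least half of the in-window samples must be valid, otherwise
#' the position is returned as missing.
#'
#' @param traj A [marker_trajectory()].
#' @param window A [dibh_window()] (or any list with `start_s`, `end_s`).
#' @return Object of class `intra_dibh_position`: list with `d` (named
#'   3-vector, mm; `NA` when insufficient data), `corrected` (logical),
#'   `type`, `n_valid`, `n_total`.
#' @export
intra_dibh_position <- function(traj, window) {
  stopifnot(inherits(traj, "marker_trajectory"))
  sel <- time_slice(traj$time_s, window$start_s, window$end_s)
  n_total <- length(sel)
  use <- sel[traj$valid[sel]]
  n_valid <- length(use)
  d <- if (n_total == 0L || n_valid < 0.5 * n_total) {
    stats::setNames(rep(NA_real_, 3), linac_axes())
  } else {
    apply(traj$coords[use, , drop = FALSE], 2, stats::median)
  }
  structure(list(d = d, corrected = FALSE,
                 type = if (!is.null(window$type)) window$type else "field",
                 n_valid = n_valid, n_total = n_total),
            class = "intra_dibh_position")
}

#' Intra-DIBH stability index (S)
#'
#' 5th-95th percentile range of a marker coordinate within a single breath
#' hold, per axis — the within-hold positional excursion (drift plus noise).
#' Requires at least half of the in-window samples to be valid.
#'
#' @inheritParams intra_dibh_position
#' @return Named non-negative 3-vector (mm), `NA` on insufficient data.
#' @export
intra_dibh_stability <- function(traj, window) {
  stopifnot(inherits(traj, "marker_trajectory"))
  sel <- time_slice(traj$time_s, window$start_s, window$end_s)
  use <- sel[traj$valid[sel]]
  if (length(sel) == 0L || length(use) < 0.5 * length(sel)) {
    return(stats::setNames(rep(NA_real_, 3), linac_axes()))
  }
  apply(traj$coords[use, , drop = FALSE], 2, percentile_range)
}

#' Correct a pre-setup breath-hold position for the applied couch shift
#'
#' Breath holds acquired during the SSD check and portal imaging precede
#' the couch correction; adding the applied shift (expressed as the patient
#' displacement it produced) makes them comparable with post-setup holds.
#' Field-delivery holds pass through unchanged. Correcting twice is an
#' error.
#'
#' @param position An `intra_dibh_position`.
#' @param shift_mm Length-3 couch shift (patient displacement, mm).
#' @return The position with `d + shift` (for ssd/portal types) and
#'   `corrected = TRUE`.
#' @export
correct_setup_shift <- function(position, shift_mm) {
  stopifnot(inherits(position, "intra_dibh_position"),
            length(shift_mm) == 3L, all(is.finite(shift_mm)))
  if (isTRUE(position$corrected)) {
    stop("position is already setup-corrected", call. = FALSE)
  }
  if (position$type %in% c("ssd", "portal")) {
    position$d <- position$d + as.numeric(shift_mm)
  }
  position$corrected <- TRUE
  position
}

#' Free-breathing position preceding a breath hold
#'
#' Per-axis median of the marker coordinates over the union of the complete
#' free-breathing cycles annotated (or detected) before the hold. Missing
#' when no cycle is available.
#'
#' @inheritParams intra_dibh_position
#' @return Named 3-vector (mm) or all-`NA`.
#' @export
free_breathing_position <- function(traj, window) {
  stopifnot(inherits(traj, "marker_trajectory"))
  iv <- window$pre_fb_intervals
  if (is.null(iv) || nrow(iv) == 0L) {
    return(stats::setNames(rep(NA_real_, 3), linac_axes()))
  }
  sel <- unlist(lapply(seq_len(nrow(iv)), function(k) {
    time_slice(traj$time_s, iv[k, 1], iv[k, 2], incl_end = FALSE)
  }), use.names = FALSE)
  use <- sel[traj$valid[sel]]
  if (length(use) == 0L) {
    return(stats::setNames(rep(NA_real_, 3), linac_axes()))
  }
  apply(traj$coords[use, , drop = FALSE], 2, stats::median)
}

#' Session free-breathing baseline
#'
#' Per-axis median of the per-hold free-breathing positions of one session;
#' subtracted from intra-DIBH positions before pooling across sessions to
#' cancel marker-replacement inaccuracies and residual setup errors.
#'
#' @param b_values Matrix (holds x 3) of free-breathing positions, mm.
#' @return Named 3-vector (mm); `NA` per axis when no valid value exists.
#' @export
session_baseline <- function(b_values) {
  b_values <- matrix(as.numeric(as.matrix(b_values)), ncol = 3L)
  stats::setNames(apply(b_values, 2, med_or_na), linac_axes())
}

#' Intrafraction reproducibility (V)
#'
#' 5th-95th percentile range, per axis, of the setup-corrected intra-DIBH
#' positions of all breath holds within one session.
#'
#' @param d_values Matrix (holds x 3) of corrected intra-DIBH positions.
#' @return Named 3-vector (mm); `NA` when fewer than two valid holds.
#' @export
intrafraction_reproducibility <- function(d_values) {
  d_values <- matrix(as.numeric(as.matrix(d_values)), ncol = 3L)
  stats::setNames(apply(d_values, 2, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) NA_real_ else percentile_range(x)
  }), linac_axes())
}

#' Interfraction reproducibility (W)
#'
#' 5th-95th percentile range, per axis, of the baseline-subtracted
#' intra-DIBH positions pooled over all breath holds of all sessions:
#' `d - f` where `f` is each session's free-breathing baseline. Sessions
#' without a valid baseline are excluded.
#'
#' @param d_by_session List of per-session (holds x 3) matrices of
#'   corrected intra-DIBH positions.
#' @param f_by_session List (same length) of session baselines (3-vectors).
#' @return Named 3-vector (mm); `NA` when fewer than two sessions
#'   contribute.
#' @export
interfraction_reproducibility <- function(d_by_session, f_by_session) {
  stopifnot(length(d_by_session) == length(f_by_session))
  pooled <- vector("list", length(d_by_session))
  contributing <- logical(length(d_by_session))
  for (n in seq_along(d_by_session)) {
    f <- as.numeric(f_by_session[[n]])
    d <- matrix(as.numeric(as.matrix(d_by_session[[n]])), ncol = 3L)
    if (any(!is.finite(f)) || nrow(d) == 0L) next
    pooled[[n]] <- sweep(d, 2, f)
    contributing[n] <- TRUE
  }
  if (sum(contributing) < 2L) {
    return(stats::setNames(rep(NA_real_, 3), linac_axes()))
  }
  pool <- do.call(rbind, pooled[contributing])
  stats::setNames(apply(pool, 2, percentile_range), linac_axes())
}

#' Free-breathing stability (F)
#'
#' Median, per axis, of the absolute deviations between each session's
#' free-breathing baseline and the per-hold free-breathing positions,
#' pooled over all holds of all sessions. Small values validate the use of
#' free-breathing positions as a session baseline.
#'
#' @inheritParams interfraction_reproducibility
#' @param b_by_session List of per-session (holds x 3) matrices of
#'   free-breathing positions.
#' @return Named non-negative 3-vector (mm).
#' @export
free_breathing_stability <- function(b_by_session, f_by_session) {
  stopifnot(length(b_by_session) == length(f_by_session))
  devs <- list()
  for (n in seq_along(b_by_session)) {
    f <- as.numeric(f_by_session[[n]])
    b <- matrix(as.numeric(as.matrix(b_by_session[[n]])), ncol = 3L)
    if (any(!is.finite(f)) || nrow(b) == 0L) next
    devs[[length(devs) + 1L]] <- abs(sweep(b, 2, f))
  }
  if (length(devs) == 0L) {
    return(stats::setNames(rep(NA_real_, 3), linac_axes()))
  }
  pool <- do.call(rbind, devs)
  stats::setNames(apply(pool, 2, med_or_na), linac_axes())
}

#' Pearson correlation of intra-DIBH positions with inspired volume
#'
#' Linear correlation between a marker's intra-DIBH positions and the mean
#' volumes inspired during the corresponding holds, across all monitored
#' sessions. Undefined (missing) when either variable has zero variance or
#' fewer than three pairs exist.
#'
#' @param d Numeric vector of intra-DIBH positions along one axis, mm.
#' @param volume Numeric vector of mean plateau volumes, litres.
#' @return Pearson r in `[-1, 1]` or `NA`.
#' @export
volume_correlation <- function(d, volume) {
  ok <- is.finite(d) & is.finite(volume)
  d <- d[ok]; volume <- volume[ok]
  if (length(d) < 3L) return(NA_real_)
  if (stats::sd(d) == 0 || stats::sd(volume) == 0) return(NA_real_)
  stats::cor(d, volume)
}

#' Compute all variability indices for a monitored cohort
#'
#' End-to-end evaluation of one patient's sessions: extracts per-hold
#' intra-DIBH positions (median over the window) and stability indices
#' (5th-95th percentile range within the window), corrects pre-setup holds
#' for the applied couch shifts, computes free-breathing positions and
#' session baselines, and derives the intrafraction (V), interfraction (W)
#' and free-breathing stability (F) indices plus the volume-correlation
#' analysis.
#'
#' Window annotations from the session records are used when present;
#' otherwise windows are detected from the volume signal
#' ([detect_dibh_windows()]) and free-breathing cycles extracted
#' ([extract_free_breathing()]). Holds or sessions failing their
#' preconditions are excluded and listed in `$log`, never imputed.
#'
#' @param sessions List of [session_record()] objects (or a cohort from
#'   [simulate_cohort()]).
#' @param n_cycles Free-breathing cycles per hold used for the baseline.
#' @param min_duration_s Minimum hold duration for detection fallback, s.
#' @return Object of class `variability_report`: list of data frames
#'   `positions` (per marker x hold x axis: `d`, `b`, `S`, mean volume),
#'   `intrafraction` (V per marker x session x axis), `interfraction`
#'   (W per marker x axis), `fb_stability` (F per marker x axis),
#'   `pearson` (r per marker x axis and marker-median r per axis),
#'   plus `markers` and `log`.
#' @export
compute_variability <- function(sessions, n_cycles = 2, min_duration_s = 3) {
  if (inherits(sessions, "dibh_cohort")) sessions <- sessions$sessions
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "session_record")))
  axes <- linac_axes()
  log <- character(0)
  pos_rows <- list()
  for (s in sessions) {
    windows <- s$dibh_windows
    if (length(windows) == 0L) {
      if (is.null(s$gating)) {
        log <- c(log, sprintf("session %d: no windows and no gating window",
                              s$session_index))
        next
      }
      det <- detect_dibh_windows(s$volume, s$gating, min_duration_s)
      fb <- extract_free_breathing(s$volume, det, n_cycles)
      n_det <- nrow(det)
      types <- c("ssd", "portal", rep("field", max(0L, n_det - 2L)))
      windows <- lapply(seq_len(n_det), function(i) {
        dibh_window(det$start_s[i], det$end_s[i], types[i], fb[[i]])
      })
    }
    for (i in seq_along(windows)) {
      w <- windows[[i]]
      for (tr in s$trajectories) {
        p <- intra_dibh_position(tr, w)
        if (any(!is.finite(p$d))) {
          log <- c(log, sprintf(
            "session %d hold %d marker %s: insufficient valid samples",
            s$session_index, i, tr$marker_id))
        }
        p <- correct_setup_shift(p, s$setup_shift_mm)
        S <- intra_dibh_stability(tr, w)
        b <- free_breathing_position(tr, w)
        if (any(!is.finite(b))) {
          log <- c(log, sprintf(
            "session %d hold %d marker %s: free-breathing position missing",
            s$session_index, i, tr$marker_id))
        }
        in_w <- time_slice(s$volume$time_s, w$start_s, w$end_s)
        vmean <- if (length(in_w)) mean(s$volume$volume_l[in_w]) else NA_real_
        pos_rows[[length(pos_rows) + 1L]] <- data.frame(
          session = s$session_index, dibh = i, type = w$type,
          marker_id = tr$marker_id, region = tr$region, axis = axes,
          d = as.numeric(p$d), b = as.numeric(b), S = as.numeric(S),
          volume_mean = vmean, corrected = p$corrected
        )
      }
    }
  }
  positions <- do.call(rbind, pos_rows)
  if (is.null(positions)) stop("no breath-hold data found", call. = FALSE)
  markers <- unique(positions[, c("marker_id", "region")])
  session_ids <- sort(unique(positions$session))

  per_ms <- function(mk, fun_col) {
    lapply(session_ids, function(n) {
      sub <- positions[positions$marker_id == mk & positions$session == n, ]
      t(vapply(split(sub, sub$dibh),
               function(df) df[[fun_col]][match(axes, df$axis)],
               numeric(3)))
    })
  }

  v_rows <- list(); w_rows <- list(); f_rows <- list(); r_rows <- list()
  for (mk in markers$marker_id) {
    region <- markers$region[markers$marker_id == mk][1]
    d_by_s <- per_ms(mk, "d")
    b_by_s <- per_ms(mk, "b")
    f_by_s <- lapply(b_by_s, session_baseline)
    for (j in seq_along(session_ids)) {
      V <- intrafraction_reproducibility(d_by_s[[j]])
      v_rows[[length(v_rows) + 1L]] <- data.frame(
        marker_id = mk, region = region, session = session_ids[j],
        axis = axes, V = as.numeric(V))
    }
    W <- interfraction_reproducibility(d_by_s, f_by_s)
    w_rows[[length(w_rows) + 1L]] <- data.frame(
      marker_id = mk, region = region, axis = axes, W = as.numeric(W))
    FF <- free_breathing_stability(b_by_s, f_by_s)
    f_rows[[length(f_rows) + 1L]] <- data.frame(
      marker_id = mk, region = region, axis = axes, F = as.numeric(FF))
    sub <- positions[positions$marker_id == mk, ]
    for (a in axes) {
      sa <- sub[sub$axis == a, ]
      r_rows[[length(r_rows) + 1L]] <- data.frame(
        marker_id = mk, region = region, axis = a,
        r = volume_correlation(sa$d, sa$volume_mean), n = sum(is.finite(sa$d)))
    }
  }
  pearson <- do.call(rbind, r_rows)
  pearson_by_axis <- do.call(rbind, lapply(axes, function(a) {
    data.frame(axis = a, r_median = med_or_na(pearson$r[pearson$axis == a]))
  }))
  out <- list(
    positions = positions,
    intrafraction = do.call(rbind, v_rows),
    interfraction = do.call(rbind, w_rows),
    fb_stability = do.call(rbind, f_rows),
    pearson = pearson,
    pearson_by_axis = pearson_by_axis,
    markers = markers,
    log = log
  )
  class(out) <- "variability_report"
  out
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf("DIBH variability report: %d markers, %d sessions, %d holds\n",
              nrow(x$markers), length(unique(x$positions$session)),
              length(unique(interaction(x$positions$session,
                                        x$positions$dibh)))))
  agg <- aggregate_report(x)
  cat("Cohort medians over markers (mm):\n")
  print(agg[agg$group == "all", c("index", "axis", "median", "q25", "q75")],
        row.names = FALSE, digits = 3)
  if (length(x$log)) cat(length(x$log), "exclusions logged\n")
  invisible(x)
}

# Internal: one summary value per marker for each index.
marker_level_indices <- function(report) {
  axes <- linac_axes()
  pos <- report$positions
  rows <- list()
  for (mk in report$markers$marker_id) {
    region <- report$markers$region[report$markers$marker_id == mk][1]
    for (a in axes) {
      S_m <- med_or_na(pos$S[pos$marker_id == mk & pos$axis == a])
      v_sub <- report$intrafraction
      V_m <- med_or_na(v_sub$V[v_sub$marker_id == mk & v_sub$axis == a])
      W_m <- report$interfraction$W[
        report$interfraction$marker_id == mk &
          report$interfraction$axis == a]
      F_m <- report$fb_stability$F[
        report$fb_stability$marker_id == mk &
          report$fb_stability$axis == a]
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = mk, region = region, axis = a,
        S = S_m, V = V_m, W = W_m, F = F_m)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate variability indices over markers
#'
#' Marker-level indices (the per-marker median over holds for S and over
#' sessions for V; W and F directly) are summarised as median and
#' 25th-75th quartiles over markers — for the whole patient (`group =
#' "all"`) and separately for the breast, thorax and abdomen marker groups.
#'
#' @param report A `variability_report`.
#' @param by `"region"`, `"patient"` or both (default reports both).
#' @return Data frame: `group`, `index` (S/V/W/F), `axis`, `median`,
#'   `q25`, `q75`, `n_markers`. Empty groups are omitted with a warning.
#' @export
aggregate_report <- function(report, by = c("patient", "region")) {
  stopifnot(inherits(report, "variability_report"))
  by <- match.arg(by, c("patient", "region"), several.ok = TRUE)
  ml <- marker_level_indices(report)
  groups <- list()
  if ("patient" %in% by) groups[["all"]] <- ml
  if ("region" %in% by) {
    for (r in c("breast", "thorax", "abdomen")) {
      sub <- ml[ml$region == r, ]
      if (nrow(sub) == 0L) {
        warning("no markers in region ", r, "; group omitted", call. = FALSE)
        next
      }
      groups[[r]] <- sub
    }
  }
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    for (idx in c("S", "V", "W", "F")) {
      for (a in linac_axes()) {
        vals <- sub[[idx]][sub$axis == a]
        mq <- median_quartiles(vals)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, index = idx, axis = a,
          median = mq[["median"]], q25 = mq[["q25"]], q75 = mq[["q75"]],
          n_markers = sum(is.finite(vals)))
      }
    }
  }
  do.call(rbind, rows)
}
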