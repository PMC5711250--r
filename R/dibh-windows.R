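#' Gating window for breath-hold detection
#'
#' @param center Accepted volume level, litres (defaults to the band middle).
#' @param lower,upper Acceptance band bounds, litres (`lower < upper`).
#' @param min_duration_s Minimum in-window run length accepted as a breath
#'   hold, s. The default of 3 s accepts the short (about 5 s) verification
#'   holds as well as full field deliveries while rejecting transients.
#' @return Object of class `gating_window`.
#' @export
gating_window <- function(center = NULL, lower, upper, min_duration_s = 3) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper,
            min_duration_s > 0)
  if (is.null(center)) center <- (lower + upper) / 2
  if (center <= lower || center >= upper) {
    stop("gating center must lie strictly inside the band", call. = FALSE)
  }
  structure(list(center = center, lower = lower, upper = upper,
                 min_duration_s = min_duration_s),
            class = "gating_window")
}

#' Detect breath-hold windows from the spirometric volume signal
#'
#' Finds maximal runs of consecutive volume samples inside the gating band
#' `[lower, upper]` lasting at least `min_duration_s`. Used as a fallback
#' when a session record carries no window annotations (clinical records
#' normally log beam-on windows directly). Returned windows are
#' non-overlapping and time-ordered; every sample inside a returned window
#' satisfies the in-band predicate.
#'
#' @param volume Data frame `time_s`, `volume_l`, uniformly sampled.
#' @param gw A [gating_window()] (or the list from
#'   [compute_gating_window()], in which case `min_duration_s` applies).
#' @param min_duration_s Minimum duration; when `NULL` (default) it is
#'   taken from `gw` if available, else 3 s.
#' @return Data frame with columns `start_s`, `end_s`, `n_samples`; zero
#'   rows for an empty or never-in-window signal.
#' @export
detect_dibh_windows <- function(volume, gw, min_duration_s = NULL) {
  stopifnot(is.data.frame(volume),
            all(c("time_s", "volume_l") %in% names(volume)))
  if (is.null(min_duration_s)) {
    min_duration_s <- if (inherits(gw, "gating_window")) {
      gw$min_duration_s
    } else 3
  }
  lower <- gw$lower; upper <- gw$upper
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  n <- nrow(volume)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_samples = integer(0))
  if (n == 0L) return(empty)
  dt <- if (n > 1L) stats::median(diff(volume$time_s)) else Inf
  inside <- volume$volume_l >= lower & volume$volume_l <= upper
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths - 1L) * dt >= min_duration_s - 1e-9
  if (!any(keep)) return(empty)
  data.frame(start_s = volume$time_s[starts[keep]],
             end_s = volume$time_s[ends[keep]],
             n_samples = r$lengths[keep])
}

# Internal: moving-average smoothing over a time width (seconds).
smooth_signal <- function(x, dt, width_s = 0.5) {
  k <- max(1L, round(width_s / dt))
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L || k >= length(x)) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) -> sm
  # fill filter edge NAs with the raw signal
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Internal: end-exhale trough times in a volume segment.
# Coarse candidates come from local minima of the smoothed signal; each is
# refined on the raw signal by the first negative-to-nonnegative transition
# of the finite difference (exact on noise-free traces).
find_troughs <- function(time_s, vol, dt, smooth_width_s = 0.5,
                         prominence_frac = 0.10, min_separation_s = 1.5) {
  n <- length(vol)
  if (n < 5L) return(numeric(0))
  sm <- smooth_signal(vol, dt, smooth_width_s)
  amp <- max(sm) - min(sm)
  if (amp <= 0) return(numeric(0))
  lo_level <- min(sm) + prominence_frac * amp
  sep <- max(1L, round(min_separation_s / dt))
  # cluster the low-level samples; one trough candidate per cluster
  low <- which(sm <= lo_level)
  if (length(low) == 0L) return(numeric(0))
  cluster <- cumsum(c(1L, diff(low) > sep))
  cand <- vapply(split(low, cluster), function(ix) {
    ix[which.min(sm[ix])]
  }, integer(1))
  # refine each candidate on the raw signal
  refined <- vapply(cand, function(j) {
    lo <- max(2L, j - sep); hi <- min(n - 1L, j + sep)
    if (hi <= lo) return(j)
    d_prev <- diff(vol)[(lo - 1L):(hi - 1L)]   # vol[k] - vol[k-1]
    d_next <- diff(vol)[lo:hi]                 # vol[k+1] - vol[k]
    trans <- which(d_prev < 0 & d_next >= 0)
    if (length(trans) == 0L) {
      lo - 1L + which.min(vol[lo:hi])
    } else {
      kk <- lo - 1L + trans
      kk[which.min(vol[kk])]
    }
  }, numeric(1))
  time_s[unique(sort(refined))]
}

#' Free-breathing cycles preceding each breath hold
#'
#' For every breath-hold window, delimits complete free-breathing cycles in
#' the volume signal between the previous window (or the record start) and
#' the window's inhale ramp, and returns the last `n_cycles` of them. Cycles
#' are delimited end-exhale to end-exhale: trough candidates are picked on a
#' moving-average-smoothed signal (0.5 s window, prominence threshold 10% of
#' the local breathing amplitude) and refined on the raw samples, so that on
#' clean traces boundaries are exact to one sample. The inhale ramp into the
#' plateau is excluded. Smoothing is internal to detection only; all
#' variability indices are computed on raw coordinates.
#'
#' A window with no complete preceding cycle is flagged (`fb_missing`), and
#' its free-breathing position is treated as missing downstream.
#'
#' @param volume Data frame `time_s`, `volume_l`.
#' @param windows Data frame with `start_s`, `end_s` (from
#'   [detect_dibh_windows()]) or a list of [dibh_window()] objects.
#' @param n_cycles Number of complete cycles to return per window.
#' @param smooth_width_s,prominence_frac Detection tuning; see above.
#' @return List, one element per window: a k x 2 matrix of cycle intervals
#'   (k <= `n_cycles`) or a 0 x 2 matrix when none is available.
#' @export
extract_free_breathing <- function(volume, windows, n_cycles = 2,
                                   smooth_width_s = 0.5,
                                   prominence_frac = 0.10) {
  stopifnot(is.data.frame(volume), n_cycles >= 1)
  if (is.list(windows) && !is.data.frame(windows)) {
    windows <- data.frame(
      start_s = vapply(windows, `[[`, numeric(1), "start_s"),
      end_s = vapply(windows, `[[`, numeric(1), "end_s"))
  }
  nw <- nrow(windows)
  out <- vector("list", nw)
  if (nw == 0L) return(out)
  n <- nrow(volume)
  dt <- if (n > 1L) stats::median(diff(volume$time_s)) else 1
  prev_ends <- c(min(volume$time_s) - dt, windows$end_s[-nw])
  for (i in seq_len(nw)) {
    sel <- volume$time_s > prev_ends[i] & volume$time_s < windows$start_s[i]
    seg_t <- volume$time_s[sel]
    seg_v <- volume$volume_l[sel]
    res <- matrix(numeric(0), 0, 2)
    if (length(seg_v) >= 5L) {
      troughs <- find_troughs(seg_t, seg_v, dt, smooth_width_s,
                              prominence_frac)
      # the record start counts as a boundary if it sits at end-exhale level
      amp <- max(seg_v) - min(seg_v)
      if (amp > 0 && seg_v[1] <= min(seg_v) + prominence_frac * amp &&
          (length(troughs) == 0L || troughs[1] > seg_t[1] + dt / 2)) {
        troughs <- c(seg_t[1], troughs)
      }
      if (length(troughs) >= 2L) {
        cyc <- cbind(troughs[-length(troughs)], troughs[-1])
        # a valid cycle must contain a real breath (prominence check)
        keep <- vapply(seq_len(nrow(cyc)), function(k) {
          s <- seg_v[seg_t >= cyc[k, 1] & seg_t <= cyc[k, 2]]
          length(s) >= 3L && (max(s) - min(s)) >= prominence_frac * amp
        }, logical(1))
        cyc <- cyc[keep, , drop = FALSE]
        if (nrow(cyc) > n_cycles) {
          cyc <- cyc[(nrow(cyc) - n_cycles + 1L):nrow(cyc), , drop = FALSE]
        }
        res <- cyc
      }
    }
    out[[i]] <- res
  }
  out
}
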