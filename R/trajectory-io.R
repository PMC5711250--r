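#' Marker trajectory for one session
#'
#' One passive marker's time-stamped 3D coordinates in the linac frame, with
#' a validity mask for tracker dropouts (invalid samples are masked, never
#' dropped, so time stays a regular grid).
#'
#' @param marker_id Marker label.
#' @param region One of `"breast"`, `"thorax"`, `"abdomen"` (markers are
#'   assigned to thorax or abdomen by the submammary-sulcus line encoded in
#'   the label at acquisition time).
#' @param time_s Strictly increasing sample times, s.
#' @param coords n x 3 matrix (LL, AP, CC), mm.
#' @param valid Logical mask, same length as `time_s`.
#' @return Object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(marker_id, region, time_s, coords,
                              valid = rep(TRUE, length(time_s))) {
  region <- match.arg(region, c("breast", "thorax", "abdomen"))
  coords <- as_points(coords)
  time_s <- as.numeric(time_s)
  valid <- as.logical(valid)
  if (length(time_s) != nrow(coords) || length(valid) != length(time_s)) {
    stop("time, coordinates and validity mask lengths differ", call. = FALSE)
  }
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  structure(list(marker_id = as.character(marker_id), region = region,
                 time_s = time_s, coords = coords, valid = valid),
            class = "marker_trajectory")
}

#' Breath-hold window annotation
#'
#' A temporal interval covering one accepted breath hold, its acquisition
#' type (`ssd` = source-skin-distance check, `portal` = portal image
#' acquisition, `field` = treatment field delivery) and the preceding
#' complete free-breathing cycles.
#'
#' @param start_s,end_s Window bounds, s (`end_s > start_s`).
#' @param type Window type.
#' @param pre_fb_intervals k x 2 matrix of (start, end) times of the
#'   free-breathing cycles preceding the hold; may have zero rows when no
#'   complete cycle was available (the window is then flagged).
#' @return Object of class `dibh_window`.
#' @export
dibh_window <- function(start_s, end_s, type = c("field", "ssd", "portal"),
                        pre_fb_intervals = matrix(numeric(0), 0, 2)) {
  type <- match.arg(type)
  stopifnot(is.finite(start_s), is.finite(end_s))
  if (end_s <= start_s) stop("window end must exceed start", call. = FALSE)
  pre_fb_intervals <- matrix(as.numeric(pre_fb_intervals), ncol = 2L)
  if (nrow(pre_fb_intervals) > 0 && any(pre_fb_intervals[, 2] > start_s)) {
    stop("free-breathing intervals must precede the window start",
         call. = FALSE)
  }
  structure(list(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                 type = type, pre_fb_intervals = pre_fb_intervals,
                 fb_missing = nrow(pre_fb_intervals) == 0L),
            class = "dibh_window")
}

#' Record of one monitored treatment session
#'
#' Bundles the marker trajectories, the spirometric volume signal, the
#' breath-hold window annotations, the applied couch setup shift and the
#' gating window of one fraction.
#'
#' @param session_index Session number (1-based).
#' @param trajectories List of [marker_trajectory()] objects.
#' @param volume Data frame `time_s`, `volume_l`.
#' @param dibh_windows List of [dibh_window()] objects, time-ordered.
#' @param setup_shift_mm Couch correction applied after the portal breath
#'   hold (patient displacement, mm).
#' @param gating Gating window list (`center`, `lower`, `upper`, litres).
#' @param couch_derived If `TRUE` (default) the setup shift must be a
#'   multiple of the 1 mm couch resolution.
#' @return Object of class `session_record`.
#' @export
session_record <- function(session_index, trajectories, volume, dibh_windows,
                           setup_shift_mm = c(0, 0, 0), gating = NULL,
                           couch_derived = TRUE) {
  stopifnot(length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, logical(1), "marker_trajectory")),
            is.data.frame(volume),
            all(c("time_s", "volume_l") %in% names(volume)),
            all(vapply(dibh_windows, inherits, logical(1), "dibh_window")),
            length(setup_shift_mm) == 3L, all(is.finite(setup_shift_mm)))
  if (couch_derived &&
      any(abs(setup_shift_mm - round(setup_shift_mm)) > 1e-9)) {
    stop("couch-derived setup shifts must be multiples of 1 mm",
         call. = FALSE)
  }
  t_max <- max(vapply(trajectories, function(tr) max(tr$time_s), numeric(1)),
               max(volume$time_s))
  t_min <- min(vapply(trajectories, function(tr) min(tr$time_s), numeric(1)),
               min(volume$time_s))
  for (w in dibh_windows) {
    if (w$start_s < t_min - 1e-9 || w$end_s > t_max + 1e-9) {
      stop(sprintf("breath-hold window [%.3f, %.3f] s lies outside the %s",
                   w$start_s, w$end_s,
                   sprintf("recorded time span [%.3f, %.3f] s", t_min, t_max)),
           call. = FALSE)
    }
  }
  structure(list(session_index = as.integer(session_index),
                 trajectories = trajectories, volume = volume,
                 dibh_windows = dibh_windows,
                 setup_shift_mm = stats::setNames(as.numeric(setup_shift_mm),
                                                  linac_axes()),
                 gating = gating),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "Session %d: %d markers, %d breath holds (%s), %.1f s recorded\n",
    x$session_index, length(x$trajectories), length(x$dibh_windows),
    paste(vapply(x$dibh_windows, `[[`, character(1), "type"),
          collapse = ", "),
    max(x$volume$time_s)))
  invisible(x)
}

#' Write / read a session record on disk
#'
#' The on-disk dialect is plain text: a long-form trajectory CSV
#' (`time_s, marker_id, region, x_ll_mm, y_ap_mm, z_cc_mm, valid`), a volume
#' CSV (`time_s, volume_l`) and a JSON metadata file carrying the session
#' index, breath-hold windows with their free-breathing intervals, the
#' setup shift and the gating window.
#'
#' @param session A [session_record()].
#' @param trajectory_path,volume_path,metadata_path File paths.
#' @return `write_session()` returns the paths invisibly; `read_session()`
#'   returns a validated [session_record()].
#' @export
write_session <- function(session, trajectory_path, volume_path,
                          metadata_path) {
  stopifnot(inherits(session, "session_record"))
  traj <- do.call(rbind, lapply(session$trajectories, function(tr) {
    data.frame(time_s = tr$time_s, marker_id = tr$marker_id,
               region = tr$region,
               x_ll_mm = tr$coords[, 1], y_ap_mm = tr$coords[, 2],
               z_cc_mm = tr$coords[, 3], valid = as.integer(tr$valid))
  }))
  utils::write.csv(traj, trajectory_path, row.names = FALSE)
  utils::write.csv(session$volume, volume_path, row.names = FALSE)
  meta <- list(
    schema = "dibhtrack-session/1",
    session_index = session$session_index,
    setup_shift_mm = as.numeric(session$setup_shift_mm),
    gating = session$gating,
    dibh_windows = lapply(session$dibh_windows, function(w) {
      list(start_s = w$start_s, end_s = w$end_s, type = w$type,
           pre_fb_intervals = unname(apply(w$pre_fb_intervals, 1, as.list,
                                           simplify = FALSE)))
    })
  )
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(trajectory = trajectory_path, volume = volume_path,
              metadata = metadata_path))
}

#' @rdname write_session
#' @export
read_session <- function(trajectory_path, volume_path, metadata_path) {
  for (p in c(trajectory_path, volume_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  traj <- utils::read.csv(trajectory_path, stringsAsFactors = FALSE)
  need <- c("time_s", "marker_id", "region", "x_ll_mm", "y_ap_mm",
            "z_cc_mm", "valid")
  if (!all(need %in% names(traj))) {
    stop("trajectory file ", trajectory_path, " lacks columns: ",
         paste(setdiff(need, names(traj)), collapse = ", "), call. = FALSE)
  }
  bad_region <- setdiff(unique(traj$region),
                        c("breast", "thorax", "abdomen"))
  if (length(bad_region)) {
    stop("trajectory file ", trajectory_path, ": unknown region(s) ",
         paste(bad_region, collapse = ", "), call. = FALSE)
  }
  vol <- utils::read.csv(volume_path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "volume_l") %in% names(vol))) {
    stop("volume file ", volume_path, " must have columns time_s, volume_l",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  trajectories <- lapply(split(traj, traj$marker_id), function(df) {
    df <- df[order(df$time_s), , drop = FALSE]
    if (any(duplicated(df$time_s))) {
      stop("trajectory file ", trajectory_path, ": marker ",
           df$marker_id[1], " has non-increasing sample times",
           call. = FALSE)
    }
    marker_trajectory(marker_id = df$marker_id[1], region = df$region[1],
                      time_s = df$time_s,
                      coords = cbind(df$x_ll_mm, df$y_ap_mm, df$z_cc_mm),
                      valid = df$valid != 0)
  })
  # preserve first-appearance order of markers
  order_ids <- unique(traj$marker_id)
  trajectories <- trajectories[order_ids]
  windows <- lapply(meta$dibh_windows, function(w) {
    pf <- w$pre_fb_intervals
    pf <- if (length(pf)) {
      do.call(rbind, lapply(pf, function(iv) as.numeric(unlist(iv))))
    } else matrix(numeric(0), 0, 2)
    dibh_window(start_s = w$start_s, end_s = w$end_s, type = w$type,
                pre_fb_intervals = pf)
  })
  gating <- meta$gating
  session_record(
    session_index = meta$session_index,
    trajectories = trajectories,
    volume = vol,
    dibh_windows = windows,
    setup_shift_mm = as.numeric(meta$setup_shift_mm),
    gating = if (is.null(gating)) NULL else
      list(center = gating$center, lower = gating$lower,
           upper = gating$upper)
  )
}

#' Write / read a simulated cohort
#'
#' One sub-file set per session (`session-<n>-trajectories.csv`,
#' `session-<n>-volume.csv`, `session-<n>-metadata.json`), the planning
#' marker table (`planning.csv`) and a ground-truth JSON sidecar.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a list with `sessions` and `planning`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dibh_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) {
    n <- s$session_index
    write_session(s,
                  file.path(dir, sprintf("session-%d-trajectories.csv", n)),
                  file.path(dir, sprintf("session-%d-volume.csv", n)),
                  file.path(dir, sprintf("session-%d-metadata.json", n)))
  }
  utils::write.csv(cohort$planning, file.path(dir, "planning.csv"),
                   row.names = FALSE)
  truth <- lapply(cohort$truth, function(tr) {
    list(session_index = tr$session_index,
         session_offset_mm = as.numeric(tr$session_offset_mm),
         setup_shift_mm = as.numeric(tr$setup_shift_mm),
         v_hold_l = tr$v_hold_l, alpha = tr$alpha,
         d_true = tr$d_true, b_true = tr$b_true)
  })
  jsonlite::write_json(truth, file.path(dir, "ground-truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_files <- list.files(dir, pattern = "^session-[0-9]+-metadata\\.json$")
  idx <- sort(as.integer(sub("^session-([0-9]+)-.*$", "\\1", meta_files)))
  if (length(idx) == 0L) stop("no session files found in ", dir, call. = FALSE)
  sessions <- lapply(idx, function(n) {
    read_session(file.path(dir, sprintf("session-%d-trajectories.csv", n)),
                 file.path(dir, sprintf("session-%d-volume.csv", n)),
                 file.path(dir, sprintf("session-%d-metadata.json", n)))
  })
  planning_path <- file.path(dir, "planning.csv")
  planning <- if (file.exists(planning_path)) {
    utils::read.csv(planning_path, stringsAsFactors = FALSE)
  } else NULL
  list(sessions = sessions, planning = planning)
}

#' Read a planning marker position table
#'
#' @param path CSV with columns `marker_id, ll, ap, cc` (or
#'   `x_ll_mm, y_ap_mm, z_cc_mm`), mm.
#' @return Matrix of positions with marker ids as row names.
#' @export
read_planning <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- if (all(c("ll", "ap", "cc") %in% names(df))) {
    c("ll", "ap", "cc")
  } else if (all(c("x_ll_mm", "y_ap_mm", "z_cc_mm") %in% names(df))) {
    c("x_ll_mm", "y_ap_mm", "z_cc_mm")
  } else {
    stop("planning file ", path,
         " must have ll/ap/cc or x_ll_mm/y_ap_mm/z_cc_mm columns",
         call. = FALSE)
  }
  m <- as.matrix(df[, cols])
  colnames(m) <- linac_axes()
  rownames(m) <- df$marker_id
  m
}

#' Write / read an analysis report as JSON
#'
#' Serialises a variability/registration report (nested lists and data
#' frames) to schema-versioned JSON with full numeric precision.
#'
#' @param report Report list (e.g. from [compute_variability()] or
#'   [run_pipeline()]).
#' @param path Output path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed report with data-frame blocks restored.
#' @export
write_report <- function(report, path) {
  payload <- list(schema = "dibhtrack-report/1", report = unclass(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "dibhtrack-report/1")) {
    stop("not a dibhtrack report: ", path, call. = FALSE)
  }
  payload$report
}
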