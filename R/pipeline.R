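#' Per-session and mean treatment marker positions
#'
#' The treatment position of a marker in one session is the per-axis median
#' of its intra-DIBH positions over the field-delivery breath holds of that
#' session; the all-sessions treatment position is the mean of the
#' per-session values. Sessions without field holds yield missing rows.
#'
#' @param positions The `positions` data frame of a
#'   [compute_variability()] report (setup-corrected intra-DIBH positions).
#' @return List: `per_session` (list of marker x 3 matrices, one per
#'   session), `overall` (marker x 3 matrix), `marker_ids`.
#' @export
treatment_positions <- function(positions) {
  stopifnot(is.data.frame(positions),
            all(c("session", "marker_id", "axis", "d", "type") %in%
                  names(positions)))
  axes <- linac_axes()
  field <- positions[positions$type == "field", ]
  if (nrow(field) == 0L) stop("no field-delivery breath holds", call. = FALSE)
  marker_ids <- unique(positions$marker_id)
  sessions <- sort(unique(positions$session))
  per_session <- lapply(sessions, function(n) {
    m <- matrix(NA_real_, length(marker_ids), 3,
                dimnames = list(marker_ids, axes))
    sub <- field[field$session == n, ]
    for (mk in marker_ids) {
      for (a in axes) {
        m[mk, a] <- med_or_na(sub$d[sub$marker_id == mk & sub$axis == a])
      }
    }
    m
  })
  names(per_session) <- as.character(sessions)
  overall <- Reduce(`+`, per_session) / length(per_session)
  list(per_session = per_session, overall = overall, marker_ids = marker_ids,
       sessions = sessions)
}

#' Mean treatment position of one marker
#'
#' Convenience accessor: the marker's per-session treatment positions
#' (median over field holds) and their all-sessions mean.
#'
#' @inheritParams treatment_positions
#' @param marker_id Marker label.
#' @return List: `per_session` (sessions x 3), `overall` (3-vector, mm).
#' @export
mean_treatment_position <- function(positions, marker_id) {
  tp <- treatment_positions(positions)
  if (!marker_id %in% tp$marker_ids) {
    stop("unknown marker: ", marker_id, call. = FALSE)
  }
  per <- t(vapply(tp$per_session, function(m) m[marker_id, ], numeric(3)))
  list(per_session = per, overall = tp$overall[marker_id, ])
}

# Internal: per-field-hold rigid transform parameter table for one patient.
per_hold_transforms <- function(positions, planning) {
  axes <- linac_axes()
  field <- positions[positions$type == "field", ]
  keys <- unique(field[, c("session", "dibh")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- field[field$session == keys$session[k] &
                   field$dibh == keys$dibh[k], ]
    m <- matrix(NA_real_, nrow(planning), 3,
                dimnames = list(rownames(planning), axes))
    for (mk in rownames(planning)) {
      for (a in axes) {
        v <- sub$d[sub$marker_id == mk & sub$axis == a]
        if (length(v) == 1L) m[mk, a] <- v
      }
    }
    if (any(!is.finite(m))) next
    tf <- fit_rigid(planning, m)
    rows[[length(rows) + 1L]] <- data.frame(
      session = keys$session[k], dibh = keys$dibh[k],
      t_ll = tf$translations_mm[1], t_ap = tf$translations_mm[2],
      t_cc = tf$translations_mm[3],
      r_ll = tf$rotations_deg[1], r_ap = tf$rotations_deg[2],
      r_cc = tf$rotations_deg[3])
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline for one patient
#'
#' Simulates (or takes) a monitored cohort, computes all variability
#' indices and their aggregations, and registers the planning marker
#' constellation to the treatment positions: the all-sessions rigid
#' transform, per-session 3D planning-to-treatment distances with
#' worst-session selection, residual displacements after rigid correction,
#' and per-field-hold transform parameters (the input to the population
#' error decomposition).
#'
#' @param input A [simulation_config()], a cohort from [simulate_cohort()],
#'   or a directory written by [write_cohort()].
#' @param planning Optional planning position matrix (marker x 3, mm);
#'   taken from the cohort/directory when available.
#' @param n_cycles Free-breathing cycles used for baselines.
#' @param register Set `FALSE` to skip the registration stage.
#' @return Object of class `dibh_pipeline`: list with `report`
#'   (variability_report), `aggregates`, `registration` (or `NULL`),
#'   `per_hold_transforms`, `meta`.
#' @export
run_pipeline <- function(input, planning = NULL, n_cycles = 2,
                         register = TRUE) {
  if (inherits(input, "simulation_config")) {
    cohort <- simulate_cohort(input)
    sessions <- cohort$sessions
    if (is.null(planning)) {
      planning <- as.matrix(cohort$planning[, linac_axes()])
      rownames(planning) <- cohort$planning$marker_id
    }
    meta <- list(source = "simulation", seed = input$seed,
                 n_sessions = input$n_sessions)
  } else if (inherits(input, "dibh_cohort")) {
    sessions <- input$sessions
    if (is.null(planning) && !is.null(input$planning)) {
      planning <- as.matrix(input$planning[, linac_axes()])
      rownames(planning) <- input$planning$marker_id
    }
    meta <- list(source = "cohort", seed = input$config$seed,
                 n_sessions = length(sessions))
  } else if (is.character(input) && length(input) == 1L) {
    loaded <- read_cohort(input)
    sessions <- loaded$sessions
    if (is.null(planning) && !is.null(loaded$planning)) {
      planning <- as.matrix(loaded$planning[, c("ll", "ap", "cc")])
      rownames(planning) <- loaded$planning$marker_id
    }
    meta <- list(source = input, n_sessions = length(sessions))
  } else {
    stop("input must be a simulation_config, a cohort, or a directory",
         call. = FALSE)
  }
  report <- compute_variability(sessions, n_cycles = n_cycles)
  aggregates <- aggregate_report(report)
  registration <- NULL
  hold_tf <- NULL
  if (register) {
    if (is.null(planning)) {
      stop("registration requested but no planning positions available",
           call. = FALSE)
    }
    tp <- treatment_positions(report$positions)
    planning <- planning[tp$marker_ids, , drop = FALSE]
    ws <- worst_session(planning, tp$per_session)
    tf_all <- fit_rigid(planning, tp$overall)
    res_all <- residual_displacements(planning, tp$overall, tf_all)
    worst_mat <- tp$per_session[[ws$session]]
    tf_worst <- fit_rigid(planning, worst_mat)
    res_worst <- residual_displacements(planning, worst_mat, tf_worst)
    registration <- list(
      transform_all_sessions = tf_all,
      residuals_all = res_all,
      mean_3d_distance_mm = mean(row_norms(tp$overall - planning)),
      per_session_mean_distance_mm = ws$mean_distance_mm,
      worst_session = ws$session,
      transform_worst_session = tf_worst,
      residuals_worst = res_worst
    )
    hold_tf <- per_hold_transforms(report$positions, planning)
  }
  out <- list(report = report, aggregates = aggregates,
              registration = registration,
              per_hold_transforms = hold_tf, meta = meta)
  class(out) <- "dibh_pipeline"
  out
}

#' @export
print.dibh_pipeline <- function(x, ...) {
  cat(summarize_report(x), sep = "\n")
  invisible(x)
}

#' Multi-patient study with population error decomposition
#'
#' Runs [run_pipeline()] for `n_patients` simulated patients (the base
#' configuration is reused with patient-specific seeds) whose planning-to-
#' treatment displacement is drawn per patient: a rigid transform with
#' translation / rotation components sampled from zero-mean normals with
#' the given systematic SDs. Per-field-hold transform parameters are pooled
#' into the population decomposition (group mean M, systematic Sigma,
#' random sigma).
#'
#' @param config Base [simulation_config()].
#' @param n_patients Number of simulated patients.
#' @param patient_translation_sd_mm,patient_rotation_sd_deg SDs of the
#'   per-patient systematic transform components.
#' @return List: `patients` (per-patient pipeline bundles),
#'   `transform_table` (Table-style per-patient all-sessions transforms and
#'   residuals), `population` (M/Sigma/sigma per parameter).
#' @export
run_cohort_study <- function(config, n_patients = 7,
                             patient_translation_sd_mm = 3.6,
                             patient_rotation_sd_deg = 1.0) {
  stopifnot(inherits(config, "simulation_config"), n_patients >= 2L)
  patients <- vector("list", n_patients)
  tf_rows <- list()
  pooled <- list()
  for (p in seq_len(n_patients)) {
    set.seed(derive_seed(config$seed, 100000L + p))
    tf_p <- rigid_transform(
      rotations_deg = stats::rnorm(3, 0, patient_rotation_sd_deg),
      translations_mm = stats::rnorm(3, 0, patient_translation_sd_mm))
    cfg_p <- config
    cfg_p$seed <- derive_seed(config$seed, 200000L + p)
    cfg_p$session_transform <- rep(list(tf_p), config$n_sessions)
    patients[[p]] <- run_pipeline(cfg_p)
    reg <- patients[[p]]$registration
    tf_rows[[p]] <- data.frame(
      patient = p,
      t_ll = reg$transform_all_sessions$translations_mm[1],
      t_ap = reg$transform_all_sessions$translations_mm[2],
      t_cc = reg$transform_all_sessions$translations_mm[3],
      r_ll = reg$transform_all_sessions$rotations_deg[1],
      r_ap = reg$transform_all_sessions$rotations_deg[2],
      r_cc = reg$transform_all_sessions$rotations_deg[3],
      residual_median_mm = reg$residuals_all$median_mm,
      residual_iqr_mm = reg$residuals_all$iqr_mm,
      worst_session = reg$worst_session)
    ph <- patients[[p]]$per_hold_transforms
    ph$patient <- p
    pooled[[p]] <- ph
  }
  pooled <- do.call(rbind, pooled)
  pop <- population_errors(
    pooled[, c("patient", "t_ll", "t_ap", "t_cc", "r_ll", "r_ap", "r_cc")])
  list(patients = patients,
       transform_table = do.call(rbind, tf_rows),
       population = pop)
}

#' Human-readable summary of a pipeline bundle
#'
#' @param bundle A `dibh_pipeline` (or a bare `variability_report`).
#' @return Character vector of formatted lines (also usable with
#'   `cat(..., sep = "\n")`). Deterministic for a given bundle.
#' @export
summarize_report <- function(bundle) {
  lines <- c("DIBH surface reproducibility summary",
             "====================================")
  report <- if (inherits(bundle, "dibh_pipeline")) bundle$report else bundle
  if (is.null(report)) return(lines)
  agg <- if (inherits(bundle, "dibh_pipeline")) bundle$aggregates else
    aggregate_report(bundle)
  lines <- c(lines, "", "Variability indices, median (q25-q75) over markers [mm]:",
             sprintf("  %-8s %-6s %-22s", "group", "index", "LL / AP / CC"))
  for (g in unique(agg$group)) {
    for (idx in c("S", "V", "W", "F")) {
      sub <- agg[agg$group == g & agg$index == idx, ]
      if (nrow(sub) == 0L) next
      fmt <- vapply(linac_axes(), function(a) {
        r <- sub[sub$axis == a, ]
        sprintf("%.2f (%.2f-%.2f)", r$median, r$q25, r$q75)
      }, character(1))
      lines <- c(lines, sprintf("  %-8s %-6s %s", g, idx,
                                paste(fmt, collapse = " | ")))
    }
  }
  pa <- report$pearson_by_axis
  lines <- c(lines, "", sprintf(
    "Volume correlation, marker-median Pearson r: LL %.2f, AP %.2f, CC %.2f",
    pa$r_median[pa$axis == "ll"], pa$r_median[pa$axis == "ap"],
    pa$r_median[pa$axis == "cc"]))
  if (inherits(bundle, "dibh_pipeline") && !is.null(bundle$registration)) {
    reg <- bundle$registration
    tf <- reg$transform_all_sessions
    lines <- c(lines, "", "Planning-to-treatment registration (all sessions):",
               sprintf("  translations: %.2f / %.2f / %.2f mm",
                       tf$translations_mm[1], tf$translations_mm[2],
                       tf$translations_mm[3]),
               sprintf("  rotations:    %.2f / %.2f / %.2f deg",
                       tf$rotations_deg[1], tf$rotations_deg[2],
                       tf$rotations_deg[3]),
               sprintf("  residuals: median %.2f mm, IQR %.2f mm",
                       reg$residuals_all$median_mm, reg$residuals_all$iqr_mm),
               sprintf("  mean 3D distance %.2f mm; worst session %d (%.2f mm)",
                       reg$mean_3d_distance_mm, reg$worst_session,
                       reg$per_session_mean_distance_mm[reg$worst_session]))
  }
  lines
}
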