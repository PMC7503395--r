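# End-to-end orchestration: cohort -> per-cell features -> derived
# biophysics -> group statistics, with per-cell failure isolation and a
# reproducibility manifest.

#' Read a cohort directory written by [generate_cohort()]
#'
#' @param dir Cohort root (contains `manifest.csv` and
#'   `group/animal/cell/` subdirectories).
#' @return A cohort list (`manifest`, `cells`) as returned by
#'   [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    stop("not a cohort directory (no manifest.csv): ", dir, call. = FALSE)
  }
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cdir <- file.path(dir, row$group, row$animal, row$cell)
    cell <- list(group = row$group, animal = row$animal, cell = row$cell,
                 truth = as.list(row))
    tryCatch(read_cell_files(cell, cdir), error = function(e) {
      cell$read_error <- conditionMessage(e)
      cell
    })
  })
  list(manifest = manifest, cells = cells)
}

read_cell_files <- function(cell, cdir) {
  {
    st <- file.path(cdir, "sealtest.csv")
    if (file.exists(st)) cell$sealtest <- read_trace_table(st)
    sdir <- file.path(cdir, "steps")
    if (dir.exists(sdir)) {
      files <- sort(list.files(sdir, pattern = "^step_.*\\.csv$",
                               full.names = TRUE))
      traces <- lapply(files, read_trace_table)
      amps <- vapply(traces, function(tr) tr$step_amplitude, numeric(1))
      o <- order(amps)
      w <- traces[[1]]$step_window
      cell$steps <- step_protocol_set(traces[o], amps[o],
                                      step_duration = w[2] - w[1])
    }
    ap <- file.path(cdir, "ap.csv")
    if (file.exists(ap)) cell$ap <- read_trace_table(ap)
    pr <- file.path(cdir, "ais_profile.csv")
    if (file.exists(pr)) cell$ais <- read_intensity_profile(pr)
    cell
  }
}

# Full feature extraction for one cell; any NULL input yields NA features.
analyze_cell <- function(cell, config = list()) {
  ais_threshold <- config$ais_threshold %||% 0.3
  feat <- list(group = cell$group, animal = cell$animal, cell = cell$cell,
               Rs_mohm = NA_real_, Rin_mohm = NA_real_, Cm_pF = NA_real_,
               tau_ms = NA_real_, erest_mV = NA_real_,
               rheobase_pA = NA_real_, max_freq_hz = NA_real_,
               gain_hz_per_pA = NA_real_, threshold_mV = NA_real_,
               max_dvdt_vps = NA_real_, min_dvdt_vps = NA_real_,
               half_width_ms = NA_real_, is_vps = NA_real_,
               sd_vps = NA_real_, is_sd_ratio = NA_real_,
               biphasic = NA, ahp_shape = NA_character_,
               ahp_slow_mono_mV = NA_real_,
               ais_length_um = NA_real_, ais_start_um = NA_real_,
               c_ais_pF = NA_real_, est_i_in_ais_pA = NA_real_,
               depol_at_rheobase_mV = NA_real_)
  if (!is.null(cell$sealtest)) {
    pp <- analyze_seal_test(cell$sealtest)
    feat$Rs_mohm <- pp$Rs; feat$Rin_mohm <- pp$Rin
    feat$Cm_pF <- pp$Cm; feat$tau_ms <- pp$tau
  }
  if (!is.null(cell$steps)) {
    feat$erest_mV <- as.numeric(measure_erest(cell$steps$traces[[1]]))
    feat$rheobase_pA <- as.numeric(find_rheobase(cell$steps))
    feat$max_freq_hz <- max_firing_frequency(cell$steps)
    fi <- fi_curve(cell$steps)
    if (length(fi$currents) >= 3L) {
      feat$gain_hz_per_pA <- io_gain(fi)$gain
    }
  }
  if (!is.null(cell$ap)) {
    sp <- detect_spikes(cell$ap)
    if (length(sp$spike_peak_indices)) {
      pk <- sp$spike_peak_indices[1]
      php <- phase_plot(cell$ap, pk, window_ms = c(6, 10), smooth = TRUE)
      feat$threshold_mV <- ap_threshold(php)
      ex <- slope_extrema(php)
      feat$max_dvdt_vps <- ex$max_dvdt
      feat$min_dvdt_vps <- ex$min_dvdt
      feat$half_width_ms <- ap_half_width(cell$ap, feat$threshold_mV, pk)
      issd <- is_sd_components(php)
      feat$is_vps <- issd$is_peak
      feat$sd_vps <- issd$sd_peak
      feat$is_sd_ratio <- issd$ratio
      feat$biphasic <- issd$biphasic
      ahp <- ahp_adp_profile(cell$ap, pk, feat$threshold_mV)
      feat$ahp_shape <- ahp$shape_class
      feat$ahp_slow_mono_mV <- ahp$ahp_slow_mono
    }
  }
  if (!is.null(cell$ais)) {
    m <- measure_ais(cell$ais, threshold_fraction = ais_threshold)
    feat$ais_length_um <- m$length_um
    feat$ais_start_um <- m$start_um
    if (!is.null(cell$truth$ais_diameter)) {
      cap <- ais_capacitance(m$length_um, cell$truth$ais_diameter)
      feat$c_ais_pF <- cap$c_ais
      if (is.finite(feat$is_vps)) {
        feat$est_i_in_ais_pA <-
          estimate_ais_current(cap, feat$is_vps)$i_in_ais
      }
    }
  }
  if (is.finite(feat$erest_mV) && is.finite(feat$threshold_mV) &&
      feat$threshold_mV > feat$erest_mV) {
    feat$depol_at_rheobase_mV <-
      depolarization_at_rheobase(feat$erest_mV, feat$threshold_mV)
  }
  feat
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages: (1) obtain the cohort (an in-memory cohort list, a
#' [cohort_spec()] to generate, or a directory to read); (2) per-cell
#' feature extraction (passive properties, firing, AP waveform, AIS
#' morphometry) with per-cell failure isolation: a failing cell is logged
#' and skipped, the run continues; (3) derived biophysics (AIS capacitance,
#' estimated AIS inward current, rheobase-Rin hyperbola); (4) group
#' statistics per feature. Deterministic given (config, cohort seed).
#'
#' @param cohort A cohort list, [cohort_spec()], or directory path.
#' @param config Optional list: `ais_threshold` (relative intensity
#'   threshold, default 0.3), `stat_vars` (features to compare across
#'   groups), `alpha`.
#' @param out_dir Optional output directory for `features.csv`,
#'   `stats_<var>.json` and `manifest.json`.
#' @return List of class `"pipeline_result"`: `features` (data.frame, one
#'   row per cell), `hyperbola` ([fit_rheobase_hyperbola()] result or
#'   `NULL`), `stats` (named list of [compare_groups()] results),
#'   `failures` (named list of error messages).
#' @export
run_pipeline <- function(cohort, config = list(), out_dir = NULL) {
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  failures <- list()
  rows <- list()
  for (cell in cohort$cells) {
    id <- paste(cell$group, cell$animal, cell$cell, sep = "/")
    if (!is.null(cell$read_error)) {
      failures[[id]] <- cell$read_error
      next
    }
    res <- tryCatch(analyze_cell(cell, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      rows[[id]] <- as.data.frame(res, stringsAsFactors = FALSE)
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(features) <- NULL

  hyp <- NULL
  if (nrow(features) >= 2L) {
    ok <- is.finite(features$Rin_mohm) & is.finite(features$rheobase_pA)
    if (sum(ok) >= 2L) {
      hyp <- fit_rheobase_hyperbola(features$Rin_mohm[ok],
                                    features$rheobase_pA[ok])
    }
  }

  stat_vars <- config$stat_vars %||%
    c("Cm_pF", "Rin_mohm", "rheobase_pA", "threshold_mV",
      "ais_length_um", "est_i_in_ais_pA")
  alpha <- config$alpha %||% 0.05
  stats_out <- list()
  if (nrow(features) && length(unique(features$group)) >= 2L) {
    for (v in stat_vars) {
      if (!v %in% names(features)) next
      ok <- is.finite(features[[v]])
      if (!any(ok)) next
      mode <- if (v == "ais_length_um") "animal_mean_as_unit" else
        "cell_as_unit"
      gm <- grouped_measurements(features$group[ok], features[[v]][ok],
                                 features$animal[ok], replicate_mode = mode)
      stats_out[[v]] <- tryCatch(
        compare_groups(gm, alpha = alpha, posthoc_always = TRUE),
        error = function(e) NULL)
    }
  }

  out <- structure(list(features = features, hyperbola = hyp,
                        stats = stats_out, failures = failures,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(features, file.path(out_dir, "features.csv"))
    for (v in names(stats_out)) {
      rs <- render_summary(stats_out[[v]])
      jsonlite::write_json(rs, file.path(out_dir,
                                         paste0("stats_", v, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("aismature")),
      n_cells = nrow(features),
      n_failures = length(failures),
      config = config,
      hyperbola_V_mV = if (!is.null(hyp)) hyp$V)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cells analyzed, %d failures\n",
              nrow(x$features), length(x$failures)))
  if (!is.null(x$hyperbola)) print(x$hyperbola)
  invisible(x)
}
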