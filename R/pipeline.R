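# End-to-end orchestration: simulate (optional) -> read -> contact detection
# -> stabilisation indices -> EMG patterns -> scalar ANOVA + waveform SPM.
# All randomness flows from one seed; outputs of the deterministic stages are
# bit-identical across reruns with the same inputs, and every output carries
# the run id (a hash of the configuration).

#' Pipeline run configuration
#'
#' Either `dataset_dir` (a directory holding `manifest.csv` in the package's
#' layout) or `sim` (a [sim_config()], in which case the dataset is generated
#' under `out_dir/dataset`) must be supplied.
#'
#' @param out_dir Output directory for all logs, tables and reports.
#' @param dataset_dir Existing dataset directory, or `NULL`.
#' @param sim A [sim_config()] to simulate from, or `NULL`.
#' @param windows_s Post-contact analysis windows, s.
#' @param alpha Significance level for both statistics layers.
#' @param n_perm Permutations per SPM effect.
#' @param seed Seed for the statistical (permutation / Monte-Carlo) stages.
#' @param n_mc_ks Monte-Carlo draws for the normality screen.
#' @param qc_amplitude_mV EMG amplitude exclusion bound.
#' @param tts_variant Time-to-stabilisation threshold variant (see [tts()]).
#' @param emg_norm_whole_trial Use whole-trial AS maxima for EMG
#'   normalisation instead of analysis-window maxima.
#' @param overwrite Allow regenerating a dataset over an existing manifest.
#' @return A validated `run_config` object.
#' @export
run_config <- function(out_dir, dataset_dir = NULL, sim = NULL,
                       windows_s = c(3, 1), alpha = 0.05, n_perm = 1000,
                       seed = 1, n_mc_ks = 10000, qc_amplitude_mV = 3,
                       tts_variant = "tail_sd",
                       emg_norm_whole_trial = FALSE, overwrite = FALSE) {
  if (is.null(dataset_dir) == is.null(sim))
    stop_ls("landstab_invalid_config",
            "exactly one of dataset_dir or sim must be given")
  if (any(!is.finite(windows_s)) || any(windows_s <= 0))
    stop_ls("landstab_invalid_config", "windows_s must be positive")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_ls("landstab_invalid_config", "alpha must be in (0, 1)")
  if (!is_count(n_perm) || !is_count(n_mc_ks))
    stop_ls("landstab_invalid_config", "n_perm and n_mc_ks must be counts")
  structure(list(out_dir = out_dir, dataset_dir = dataset_dir, sim = sim,
                 windows_s = sort(windows_s, decreasing = TRUE),
                 alpha = alpha, n_perm = as.integer(n_perm), seed = seed,
                 n_mc_ks = as.integer(n_mc_ks),
                 qc_amplitude_mV = qc_amplitude_mV,
                 tts_variant = tts_variant,
                 emg_norm_whole_trial = isTRUE(emg_norm_whole_trial),
                 overwrite = isTRUE(overwrite)),
            class = "run_config")
}

# hash of the run's scientific inputs; output and dataset locations are
# deliberately excluded so reruns of the same configuration share an id
run_id_of <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$dataset_dir <- NULL
  cfg$sim <- if (!is.null(cfg$sim)) flatten_config(cfg$sim) else NULL
  fnv1a_hex(unlist(lapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","))))
}

#' Run the full pipeline
#'
#' Stages: (1) simulate the dataset if a [sim_config()] was given;
#' (2) per subject, read each trial, detect contact, compute the 24
#' stabilisation indices, quality-screen and process the EMG, normalise to
#' the participant's AS maximum and integrate the 30-node patterns;
#' (3) scalar layer - per-outcome within-subject ANOVA, normality screen and
#' Bonferroni post hocs; (4) waveform layer - permutation SPM per muscle.
#' Writes `contact_log.csv`, `qc_log.csv`, `indices.csv`, `patterns.csv`,
#' `scalar_stats.csv`, `scalar_stats.json`, `spm.json` and
#' `run_manifest.json` under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return List with the main tables and report objects, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_id <- run_id_of(config)

  dataset_dir <- config$dataset_dir
  if (!is.null(config$sim)) {
    dataset_dir <- file.path(config$out_dir, "dataset")
    stage("simulate", generate_dataset(config$sim, dataset_dir,
                                       overwrite = config$overwrite))
  }
  man <- stage("discover",
               discover_dataset(file.path(dataset_dir, "manifest.csv")))

  proc <- stage("process", process_dataset(man, config, run_id))
  stats_out <- stage("stats", compute_study_stats(proc$indices,
                                                  proc$patterns, man,
                                                  config, run_id))

  manifest <- list(run_id = run_id, seed = config$seed,
                   n_trials = nrow(man),
                   alpha = config$alpha, n_perm = config$n_perm,
                   windows_s = config$windows_s,
                   tts_variant = config$tts_variant,
                   dataset_dir = dataset_dir,
                   qc_excluded = sum(!proc$qc_log$keep),
                   tts_censored = sum(proc$indices$tts_censored),
                   warnings = proc$warnings)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(proc, stats_out, list(run_id = run_id, manifest = manifest)))
}

stage <- function(name, expr) {
  tryCatch(expr, landstab_error = function(e) {
    stop_ls("landstab_stage_error", "stage '%s' failed: %s", name,
            conditionMessage(e))
  })
}

# read every trial, detect contact, compute indices, process + normalise EMG
process_dataset <- function(man, config, run_id) {
  contact_rows <- list(); qc_rows <- list(); idx_rows <- list()
  pat_rows <- list(); warn <- character()
  for (sub in unique(man$subject_id)) {
    rows <- man[man$subject_id == sub, ]
    processed <- list()  # per muscle: list of kept trials
    for (r in seq_len(nrow(rows))) {
      row <- rows[r, ]
      trial <- read_trial_row(row)
      ct <- detect_contact(trial$imu)
      contact_rows[[length(contact_rows) + 1]] <-
        tibble(run_id = run_id, trial_id = row$trial_id,
               contact_time_s = ct$time_s,
               n_flight_phases = ct$flight_intervals_found)
      idx <- compute_indices(trial$imu, ct, config$windows_s,
                             row$imu_rate_hz, config$tts_variant)
      idx_rows[[length(idx_rows) + 1]] <-
        tibble(run_id = run_id, trial_id = row$trial_id, idx)
      emg <- process_emg_trial_qc(trial, config$qc_amplitude_mV)
      for (m in emg_muscles()) {
        qc_rows[[length(qc_rows) + 1]] <-
          tibble(run_id = run_id, trial_id = row$trial_id, muscle = m,
                 keep = emg[[m]]$keep, reason = emg[[m]]$reason)
        if (emg[[m]]$keep)
          processed[[m]][[length(processed[[m]]) + 1]] <-
            list(x = emg[[m]]$x, contact_s = ct$time_s, task = row$task,
                 trial_id = row$trial_id, gaze = row$gaze,
                 repetition = row$repetition)
      }
    }
    for (m in emg_muscles()) {
      trs <- processed[[m]]
      if (is.null(trs) || !length(trs)) next
      norm <- tryCatch(normalise_to_as_max(trs,
                                           config$emg_norm_whole_trial),
                       landstab_normalisation_error = function(e) {
                         warn <<- c(warn, sprintf(
                           "subject %s, muscle %s: %s", sub, m,
                           conditionMessage(e)))
                         NULL
                       })
      if (is.null(norm)) next
      for (tr in norm$trials) {
        nodes <- extract_pattern(tr$x, tr$contact_s)
        pat_rows[[length(pat_rows) + 1]] <-
          tibble(run_id = run_id, trial_id = tr$trial_id, subject_id = sub,
                 task = tr$task, gaze = tr$gaze, repetition = tr$repetition,
                 muscle = m, node = seq_len(30), value = nodes)
      }
    }
  }
  out <- list(contact_log = dplyr::bind_rows(contact_rows),
              qc_log = dplyr::bind_rows(qc_rows),
              indices = dplyr::bind_rows(idx_rows),
              patterns = dplyr::bind_rows(pat_rows),
              warnings = warn)
  data.table::fwrite(out$contact_log,
                     file.path(config$out_dir, "contact_log.csv"))
  data.table::fwrite(out$qc_log, file.path(config$out_dir, "qc_log.csv"))
  data.table::fwrite(out$indices, file.path(config$out_dir, "indices.csv"))
  data.table::fwrite(out$patterns, file.path(config$out_dir, "patterns.csv"))
  out
}

process_emg_trial_qc <- function(trial, amplitude_limit_mV) {
  out <- list()
  for (m in emg_muscles()) {
    raw <- trial$emg[[m]]
    qc <- qc_check(raw, amplitude_limit_mV)
    if (!qc$keep) {
      out[[m]] <- list(keep = FALSE, reason = qc$reason)
    } else {
      x <- rectify(bandpass_30_350(
        resample_to_1000hz(raw, trial$meta$emg_rate_hz)))
      out[[m]] <- list(keep = TRUE, reason = "ok", x = x)
    }
  }
  out
}

#' Trial-level stabilisation outcomes in long format
#'
#' Joins the indices table with trial metadata and reshapes to one row per
#' (trial, outcome), with outcome names like `dsi_acc_ap_3s` and
#' `tts_gyro_sagittal_1s`.
#'
#' @param indices Indices tibble from the processing stage.
#' @param man Manifest tibble ([discover_dataset()]).
#' @return Long tibble ready for [aggregate_reps()].
#' @export
indices_to_outcomes <- function(indices, man) {
  j <- dplyr::inner_join(indices,
                         man[c("trial_id", "subject_id", "task", "gaze",
                               "repetition")], by = "trial_id")
  wl <- function(w) sub("\\.", "p", sprintf("%gs", w))
  dsi_rows <- tibble(subject_id = j$subject_id, task = j$task, gaze = j$gaze,
                     repetition = j$repetition,
                     outcome = sprintf("dsi_%s_%s", j$channel, wl(j$window_s)),
                     value = j$dsi)
  tts_rows <- tibble(subject_id = j$subject_id, task = j$task, gaze = j$gaze,
                     repetition = j$repetition,
                     outcome = sprintf("tts_%s_%s", j$channel, wl(j$window_s)),
                     value = j$tts_s)
  dplyr::bind_rows(dsi_rows, tts_rows)
}

# scalar + waveform statistics, written as JSON + flat CSV
compute_study_stats <- function(indices, patterns, man, config, run_id) {
  outcomes <- indices_to_outcomes(indices, man)
  table <- aggregate_reps(outcomes)
  scalar <- list(); flat <- list()
  for (oc in sort(unique(table$outcome))) {
    an <- rm_anova_2way(table, oc)
    Y <- study_array(table, oc)
    resid <- as.vector(Y - rep(apply(Y, c(2, 3), mean),
                               each = dim(Y)[1]))
    ks <- tryCatch(
      ks_normality(resid, n_mc = config$n_mc_ks, seed = config$seed),
      landstab_degenerate = function(e)
        list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
    post <- list()
    for (e in an$effect[an$p < config$alpha]) {
      post[[e]] <- bonferroni_posthoc(table, oc, e)
      if (e == "interaction")
        post$interaction_simple_effects <-
          interaction_simple_effects(table, oc)
    }
    scalar[[oc]] <- list(anova = an, ks_normality = ks, posthoc = post)
    flat[[oc]] <- tibble(run_id = run_id, outcome = oc, effect = an$effect,
                         F = an$F, df_num = an$df_num, df_den = an$df_den,
                         p = an$p)
  }
  flat <- dplyr::bind_rows(flat)
  data.table::fwrite(flat, file.path(config$out_dir, "scalar_stats.csv"))
  jsonlite::write_json(list(run_id = run_id, outcomes = scalar),
                       file.path(config$out_dir, "scalar_stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  spm <- list()
  if (nrow(patterns)) {
    for (m in intersect(emg_muscles(), unique(patterns$muscle))) {
      pat_m <- complete_pattern_subjects(patterns, m)
      if (is.null(pat_m)) next
      stack <- pattern_stack(pat_m, m)
      spm[[m]] <- spm_infer(stack, n_perm = config$n_perm,
                            seed = config$seed, alpha = config$alpha)
    }
  }
  jsonlite::write_json(list(run_id = run_id, muscles = spm),
                       file.path(config$out_dir, "spm.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  list(study_table = table, scalar_stats = scalar, scalar_flat = flat,
       spm = spm)
}

# keep only subjects with a complete task x gaze design for this muscle
# (quality exclusions can empty cells); NULL if fewer than 3 remain
complete_pattern_subjects <- function(patterns, muscle) {
  pm <- patterns[patterns$muscle == muscle, ]
  cells <- unique(pm[c("subject_id", "task", "gaze")])
  n_cells <- table(cells$subject_id)
  full <- length(unique(pm$task)) * length(unique(pm$gaze))
  keep <- names(n_cells)[n_cells == full]
  if (length(keep) < 3) return(NULL)
  pm[pm$subject_id %in% keep, ]
}
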