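# Dataset layout: one EMG CSV and one IMU CSV per trial (the two streams run
# at different rates), referenced from a manifest CSV. Time columns are
# seconds from acquisition start; EMG and IMU share that origin (synchronised
# acquisition).

#' Trial metadata
#'
#' Identifies one landing attempt: subject, motor task (`DL` drop landing,
#' `SB` backward somersault, `SF` forward somersault, `AS` backward acrobatic
#' series), instructed gaze direction (`down` or `ahead`), repetition number
#' and the native sampling rates of the two streams.
#'
#' @param subject_id Character subject token.
#' @param task One of `landing_tasks()`.
#' @param gaze One of `gaze_levels()`.
#' @param repetition Positive integer repetition index within the cell.
#' @param emg_rate_hz EMG native sampling rate in Hz (Delsys sensors run at
#'   1926 or 1111 Hz depending on sensor version).
#' @param imu_rate_hz IMU sampling rate in Hz (370.4 Hz).
#' @return A `trial_meta` object (named list).
#' @export
trial_meta <- function(subject_id, task, gaze, repetition,
                       emg_rate_hz = 1926, imu_rate_hz = 370.4) {
  assert_task(task)
  assert_gaze(gaze)
  if (!is_count(repetition))
    stop_ls("landstab_meta_error", "repetition must be a positive integer")
  if (emg_rate_hz <= 0 || imu_rate_hz <= 0)
    stop_ls("landstab_meta_error", "sampling rates must be positive")
  structure(list(subject_id = as.character(subject_id), task = task,
                 gaze = gaze, repetition = as.integer(repetition),
                 emg_rate_hz = emg_rate_hz, imu_rate_hz = imu_rate_hz),
            class = "trial_meta")
}

trial_id <- function(meta) {
  sprintf("%s_%s_%s_r%d", meta$subject_id, meta$task, meta$gaze,
          meta$repetition)
}

#' Raw trial container
#'
#' Bundles the two synchronised streams of one landing attempt: six EMG
#' channels in mV on the native-rate time base and six IMU channels
#' (specific force in g, angular velocity in deg/s) at 370.4 Hz.
#'
#' @param meta A [trial_meta()].
#' @param emg Data frame `time_s` + the six columns of [emg_muscles()].
#' @param imu Data frame `time_s` + the six columns of [imu_channels()].
#' @return A `raw_trial` object.
#' @export
raw_trial <- function(meta, emg, imu) {
  check_block(emg, emg_muscles(), "EMG")
  check_block(imu, imu_channels(), "IMU")
  structure(list(meta = meta, emg = as_tibble(emg), imu = as_tibble(imu)),
            class = "raw_trial")
}

check_block <- function(df, channels, label) {
  missing <- setdiff(c("time_s", channels), names(df))
  if (length(missing))
    stop_ls("landstab_malformed_file", "%s block missing column(s): %s",
            label, paste(missing, collapse = ", "))
  vals <- as.matrix(df[c("time_s", channels)])
  if (!all(is.finite(vals)))
    stop_ls("landstab_malformed_file", "%s block contains non-finite values",
            label)
  dt <- diff(df$time_s)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6))
    stop_ls("landstab_malformed_file",
            "%s time base is not uniform (jitter above 1e-6 s)", label)
  invisible(df)
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial %s: %d EMG samples @ %g Hz, %d IMU samples @ %g Hz>\n",
              trial_id(x$meta), nrow(x$emg), x$meta$emg_rate_hz,
              nrow(x$imu), x$meta$imu_rate_hz))
  invisible(x)
}

#' Write / read one trial
#'
#' `write_trial()` stores a trial as two CSV files (EMG and IMU blocks) with
#' at least 9 significant digits so that a write-then-read round trip is the
#' identity to within text precision. `read_trial()` validates the header
#' against the channel schema, checks time-base uniformity (jitter below
#' 1e-6 s) and fails loudly on missing channels rather than returning NAs.
#'
#' @param trial A [raw_trial()].
#' @param emg_path,imu_path CSV file paths for the two blocks.
#' @param meta A [trial_meta()] describing the files being read.
#' @return `read_trial()` returns a [raw_trial()]; `write_trial()` the paths,
#'   invisibly.
#' @export
write_trial <- function(trial, emg_path, imu_path) {
  stopifnot(inherits(trial, "raw_trial"))
  data.table::fwrite(trial$emg, emg_path)
  data.table::fwrite(trial$imu, imu_path)
  invisible(c(emg = emg_path, imu = imu_path))
}

#' @rdname write_trial
#' @export
read_trial <- function(emg_path, imu_path, meta) {
  for (p in c(emg_path, imu_path)) {
    if (!file.exists(p))
      stop_ls("landstab_dataset_integrity", "trial file does not exist: %s", p)
  }
  emg <- as_tibble(data.table::fread(emg_path))
  imu <- as_tibble(data.table::fread(imu_path))
  raw_trial(meta, emg, imu)
}

#' Discover a dataset from its manifest
#'
#' Reads a manifest CSV (`trial_id,subject_id,task,gaze,repetition,emg_path,
#' imu_path,emg_rate_hz,imu_rate_hz`), validates the metadata, checks that
#' every referenced file exists, rejects duplicate
#' (subject, task, gaze, repetition) keys, and returns the entries in a stable
#' order (subject, task, gaze, repetition) regardless of row order on disk.
#'
#' @param manifest_path Path to the manifest CSV. Relative trial paths are
#'   resolved against the manifest's directory.
#' @return A tibble, one row per trial, ordered.
#' @export
discover_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_ls("landstab_dataset_integrity", "manifest not found: %s",
            manifest_path)
  man <- as_tibble(data.table::fread(manifest_path,
                                     colClasses = list(character = "subject_id")))
  need <- c("trial_id", "subject_id", "task", "gaze", "repetition",
            "emg_path", "imu_path", "emg_rate_hz", "imu_rate_hz")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop_ls("landstab_malformed_file", "manifest missing column(s): %s",
            paste(missing, collapse = ", "))
  for (tk in unique(man$task)) assert_task(tk)
  for (gz in unique(man$gaze)) assert_gaze(gz)
  key <- paste(man$subject_id, man$task, man$gaze, man$repetition)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    rows <- which(key %in% dup)
    stop_ls("landstab_dataset_integrity",
            "duplicate (subject, task, gaze, repetition) key(s) in manifest rows %s: %s",
            paste(rows, collapse = ", "), paste(unique(dup), collapse = "; "))
  }
  root <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  man$emg_path <- resolve(man$emg_path)
  man$imu_path <- resolve(man$imu_path)
  for (p in c(man$emg_path, man$imu_path)) {
    if (!file.exists(p))
      stop_ls("landstab_dataset_integrity",
              "manifest references a missing file: %s", p)
  }
  ord <- order(man$subject_id, match(man$task, landing_tasks()),
               match(man$gaze, gaze_levels()), man$repetition)
  man[ord, ]
}

#' @rdname write_trial
#' @param row One row of a [discover_dataset()] tibble.
#' @export
read_trial_row <- function(row) {
  meta <- trial_meta(row$subject_id, row$task, row$gaze, row$repetition,
                     row$emg_rate_hz, row$imu_rate_hz)
  read_trial(row$emg_path, row$imu_path, meta)
}
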