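# Synthetic raw-trial generator. Emulates the signal structure the analysis
# assumes: quiet stance, one or two flight phases of near-zero specific force,
# a half-sine impact transient, a damped post-impact oscillation decaying back
# into quiet stance, and EMG as band-limited noise carriers under burst
# envelopes with task-dependent pre-contact onset. Every trial carries its
# ground truth (contact time, flight intervals, analytic post-impact RMS,
# envelope onsets) so downstream detectors and indices can be tested exactly.

#' Simulation configuration
#'
#' Defines one synthetic study. Defaults reproduce the study design this
#' package targets: 18 subjects x 4 motor tasks x 2 gaze directions x 3
#' repetitions, EMG at 1926 Hz, IMU at 370.4 Hz, with task-graded flight
#' durations, impact magnitudes and post-impact oscillation amplitudes, and a
#' null gaze effect (`gaze_effect = 0`).
#'
#' Task and gaze effects are proportional shifts of the post-impact
#' oscillation amplitude (`amp * (1 + task_effect + gaze_effect)`), so one
#' scalar moves all six IMU channels coherently despite their different units.
#' Between-subject and between-repetition variability enter as log-normal
#' amplitude factors.
#'
#' @param n_subjects Number of subjects.
#' @param tasks Subset of `landing_tasks()`.
#' @param reps_per_cell Successful repetitions per subject x task x gaze cell
#'   (2 or 3 in the emulated protocol).
#' @param seed Master seed; per-trial, per-stream seeds are derived from it by
#'   a stated hash so adding trials never perturbs existing ones.
#' @param emg_rate_hz EMG native rate, 1926 or 1111 Hz.
#' @param imu_rate_hz IMU rate in Hz.
#' @param stance_pre_s Quiet stance before the (first) flight phase, s.
#' @param post_contact_s Post-contact signal length, s (must exceed the
#'   longest analysis window).
#' @param flight_duration_s Named per-task flight duration, s.
#' @param impact_amplitude_g Named per-task impact peak, g.
#' @param impact_width_s Full width of the half-sine impact transient, s.
#' @param as_first_flight If `TRUE`, AS trials carry a first short flight and
#'   an intermediate ground contact before the final somersault flight
#'   (the acrobatic series may omit the handspring, hence the switch).
#' @param as_first_flight_s,as_ground_s First-flight and intermediate ground
#'   durations for AS, s.
#' @param rot_rate_dps Named per-task sagittal rotation rate during flight,
#'   deg/s.
#' @param osc_amp Named per-channel post-impact oscillation amplitude
#'   (g for accelerometers, deg/s for gyros). A scalar is recycled.
#' @param osc_freq_hz,osc_tau_s Frequency (Hz) and exponential decay constant
#'   (s) of the post-impact damped oscillation.
#' @param noise_sd Named vector with elements `acc` (g), `gyro` (deg/s),
#'   `emg` (mV): measurement-noise standard deviations.
#' @param subject_sd,rep_sd Log-scale SDs of the subject-level and
#'   repetition-level amplitude factors.
#' @param task_effect Named per-task proportional shift of oscillation
#'   amplitude.
#' @param gaze_effect Proportional oscillation-amplitude shift applied to the
#'   `ahead` gaze condition; 0 reproduces the null-gaze regime.
#' @param emg_amp_mV Named per-muscle envelope peak, mV.
#' @param emg_task_amp Named per-task EMG amplitude factor.
#' @param emg_preactivation_s 6 x 4 matrix (muscle x task) of envelope onset
#'   lead times before contact, s.
#' @param emg_peak_offset_s Envelope peak time relative to contact, s.
#' @param emg_decay_s Post-peak envelope exponential decay constant, s.
#' @return A `sim_config` object (validated named list).
#' @export
sim_config <- function(n_subjects = 18,
                       tasks = landing_tasks(),
                       reps_per_cell = 3,
                       seed = 1,
                       emg_rate_hz = 1926,
                       imu_rate_hz = 370.4,
                       stance_pre_s = 1.5,
                       post_contact_s = 4.2,
                       flight_duration_s = c(DL = 0.25, SB = 0.55,
                                             SF = 0.60, AS = 0.70),
                       impact_amplitude_g = c(DL = 4, SB = 6, SF = 7, AS = 8),
                       impact_width_s = 0.06,
                       as_first_flight = TRUE,
                       as_first_flight_s = 0.45,
                       as_ground_s = 0.35,
                       rot_rate_dps = c(DL = 0, SB = 500, SF = 520, AS = 560),
                       osc_amp = c(acc_ml = 0.35, acc_ap = 0.45, acc_v = 0.80,
                                   gyro_sagittal = 40, gyro_frontal = 25,
                                   gyro_transverse = 30),
                       osc_freq_hz = 6,
                       osc_tau_s = 0.4,
                       noise_sd = c(acc = 0.02, gyro = 1.5, emg = 0.02),
                       subject_sd = 0.15,
                       rep_sd = 0.08,
                       task_effect = c(DL = 0, SB = 0.25, SF = 0.15, AS = 0.35),
                       gaze_effect = 0,
                       emg_amp_mV = c(rectus_femoris = 0.70,
                                      vastus_medialis = 0.60,
                                      biceps_femoris = 0.50,
                                      tibialis_anterior = 0.60,
                                      peroneus_longus = 0.55,
                                      gastrocnemius_medialis = 0.65),
                       emg_task_amp = c(DL = 0.7, SB = 0.9, SF = 1.0, AS = 1.0),
                       emg_preactivation_s = default_preactivation(),
                       emg_peak_offset_s = 0.03,
                       emg_decay_s = 0.12) {
  tasks <- match.arg(tasks, landing_tasks(), several.ok = TRUE)
  if (!is_count(n_subjects) || !is_count(reps_per_cell))
    stop_ls("landstab_invalid_config",
            "n_subjects and reps_per_cell must be positive integers")
  if (!emg_rate_hz %in% c(1926, 1111))
    stop_ls("landstab_invalid_config",
            "emg_rate_hz must be 1926 or 1111 (native Delsys rates)")
  if (length(osc_amp) == 1) {
    osc_amp <- stats::setNames(rep(osc_amp, 6), imu_channels())
  }
  cfg <- list(n_subjects = as.integer(n_subjects), tasks = tasks,
              gaze_levels = gaze_levels(),
              reps_per_cell = as.integer(reps_per_cell), seed = seed,
              emg_rate_hz = emg_rate_hz, imu_rate_hz = imu_rate_hz,
              stance_pre_s = stance_pre_s, post_contact_s = post_contact_s,
              flight_duration_s = flight_duration_s,
              impact_amplitude_g = impact_amplitude_g,
              impact_width_s = impact_width_s,
              as_first_flight = isTRUE(as_first_flight),
              as_first_flight_s = as_first_flight_s,
              as_ground_s = as_ground_s,
              rot_rate_dps = rot_rate_dps,
              osc_amp = osc_amp[imu_channels()],
              osc_freq_hz = osc_freq_hz, osc_tau_s = osc_tau_s,
              noise_sd = noise_sd, subject_sd = subject_sd, rep_sd = rep_sd,
              task_effect = task_effect, gaze_effect = gaze_effect,
              emg_amp_mV = emg_amp_mV[emg_muscles()],
              emg_task_amp = emg_task_amp,
              emg_preactivation_s = emg_preactivation_s,
              emg_peak_offset_s = emg_peak_offset_s,
              emg_decay_s = emg_decay_s)
  durs <- c(cfg$stance_pre_s, cfg$post_contact_s, cfg$impact_width_s,
            cfg$flight_duration_s[tasks], cfg$osc_freq_hz, cfg$osc_tau_s,
            cfg$emg_rate_hz, cfg$imu_rate_hz)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop_ls("landstab_invalid_config",
            "all durations, rates and frequencies must be strictly positive")
  if (any(cfg$flight_duration_s[tasks] < 3 / cfg$imu_rate_hz))
    stop_ls("landstab_invalid_config",
            "flight_duration_s shorter than 3 IMU samples")
  if (cfg$post_contact_s < 3 + 0.5)
    stop_ls("landstab_invalid_config",
            "post_contact_s must cover the 3-s analysis window plus margin")
  if (any(cfg$noise_sd < 0) || any(cfg$osc_amp < 0))
    stop_ls("landstab_invalid_config", "noise_sd and osc_amp must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Envelope onset lead times before contact (s): forward somersaults drive
# earlier shank/posterior-chain preactivation, backward somersaults earlier
# tibialis/rectus activity; the drop landing is latest overall.
default_preactivation <- function() {
  m <- matrix(0.12, nrow = 6, ncol = 4,
              dimnames = list(emg_muscles(), landing_tasks()))
  m[c("peroneus_longus", "gastrocnemius_medialis", "biceps_femoris"), "SF"] <- 0.18
  m[c("tibialis_anterior", "rectus_femoris"), "SB"] <- 0.18
  m[, "DL"] <- 0.10
  m
}

subject_index <- function(subject_id) {
  d <- gsub("[^0-9]", "", subject_id)
  if (nzchar(d)) as.integer(d) else sum(utf8ToInt(subject_id))
}

# Continuous-time trial timeline for one task. All boundaries in seconds.
trial_timeline <- function(config, task) {
  t1 <- config$stance_pre_s
  w <- config$impact_width_s
  flights <- list()
  if (task == "AS" && config$as_first_flight) {
    f1 <- c(t1, t1 + config$as_first_flight_s)
    flights[[1]] <- f1
    t2 <- f1[2] + w + config$as_ground_s
  } else {
    t2 <- t1
  }
  t3 <- t2 + config$flight_duration_s[[task]]
  flights[[length(flights) + 1]] <- c(t2, t3)
  tc <- t3 + w / 2
  list(flights = flights, spike_start = t3, contact = tc,
       total = tc + config$post_contact_s)
}

#' Analytic RMS of a damped sinusoid
#'
#' Closed-form root-mean-square of `A * exp(-t / tau) * sin(2 pi f t + phi)`
#' over `[0, T]`, used as per-channel ground truth for the post-impact
#' oscillation.
#'
#' @param A,f_hz,tau_s Amplitude, frequency (Hz) and decay constant (s).
#' @param T_s Averaging window length, s.
#' @param phi Phase, rad.
#' @return The RMS value (same units as `A`).
#' @export
damped_sine_rms <- function(A, f_hz, tau_s, T_s, phi = 0) {
  a <- 2 / tau_s
  b <- 4 * pi * f_hz
  int_exp <- (1 - exp(-a * T_s)) / a
  int_expcos <- (exp(-a * T_s) * (-a * cos(b * T_s + 2 * phi) +
                                    b * sin(b * T_s + 2 * phi)) +
                   a * cos(2 * phi) - b * sin(2 * phi)) / (a^2 + b^2)
  ms <- A^2 / T_s * 0.5 * (int_exp - int_expcos)
  sqrt(pmax(ms, 0))
}

# Phase that zeroes the infinite-horizon integral of the damped sinusoid
# (integral of exp(-t/tau) sin(wt + phi) dt over [0, Inf) = 0). Post-impact
# deviations of a settling body have near-zero net area - the impulse is
# absorbed, not accumulated - and the sequential-average stabilisation time
# is only meaningful under that property.
zero_area_phase <- function(f_hz, tau_s) -atan(2 * pi * f_hz * tau_s)

# Log-normal amplitude factors; separate streams so IMU and EMG noise draws
# do not shift when factors change.
trial_factors <- function(config, cell) {
  si <- subject_index(cell$subject_id)
  subj_seed <- stream_seed(config$seed, si, "DL", "down", 1, 90)
  subj <- withr_rng(subj_seed, function() exp(rnorm(1, 0, config$subject_sd)))
  rep_seed <- stream_seed(config$seed, si, cell$task, cell$gaze,
                          cell$repetition, 91)
  repf <- withr_rng(rep_seed, function() exp(rnorm(1, 0, config$rep_sd)))
  list(subject = subj, rep = repf)
}

# run f under a local RNG state
withr_rng <- function(seed, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

#' Generate the IMU part of one synthetic trial
#'
#' Builds a piecewise lower-back IMU record for one landing attempt: quiet
#' stance (vertical specific force near +1 g), the task's flight phase(s)
#' (specific force near 0 g), a half-sine impact transient peaking at contact,
#' and a damped oscillation `A exp(-t/tau) sin(2 pi f t)` per channel decaying
#' into terminal quiet stance. AS trials optionally carry two flight phases
#' separated by an intermediate ground contact, so contact time is defined by
#' the *last* flight phase.
#'
#' @param config A [sim_config()].
#' @param cell A [trial_meta()] (or list with the same fields); `cell$task`
#'   must be in `config$tasks`.
#' @param seed Integer seed for this trial's IMU stream; defaults to a hash of
#'   (master seed, subject, task, gaze, repetition).
#' @return List with elements `imu` (tibble `time_s` + `imu_channels()`) and
#'   `truth`: `contact_time_s`, `flight_intervals` (list of `c(start, end)`),
#'   `channel_rms` (closed-form damped-sinusoid RMS per channel over the 3-s
#'   window), `osc_amp` (effective per-channel amplitudes) and
#'   `impact_peak_g`.
#' @export
generate_imu_trial <- function(config, cell, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  task <- assert_task(cell$task)
  if (!task %in% config$tasks)
    stop_ls("landstab_invalid_config", "cell task %s not in config$tasks", task)
  seed <- seed %||% stream_seed(config$seed, subject_index(cell$subject_id),
                                task, cell$gaze, cell$repetition, 1)
  tl <- trial_timeline(config, task)
  rate <- config$imu_rate_hz
  n <- floor(tl$total * rate) + 1
  t <- time_base(n, rate)
  w <- config$impact_width_s
  tc <- tl$contact

  fac <- trial_factors(config, cell)
  shift <- 1 + config$task_effect[[task]] +
    config$gaze_effect * (cell$gaze == "ahead")
  amp <- config$osc_amp * shift * fac$subject * fac$rep
  A_imp <- config$impact_amplitude_g[[task]] * fac$rep

  in_any <- function(tt, iv) tt >= iv[1] & tt < iv[2]
  flight_mask <- Reduce(`|`, lapply(tl$flights, function(iv) in_any(t, iv)))

  # Impact transient with rebound: positive half-sine (amplitude A, width w)
  # peaking at contact, followed by a negative unloading half-sine (amplitude
  # A/4, width 2w). The undershoot area equals the post-contact half of the
  # loading lobe (A w / pi), so the transient deposits no net area inside the
  # analysis window - the settling body absorbs the impulse rather than
  # accumulating it.
  spike_val <- numeric(n)
  grav <- as.numeric(!flight_mask)
  add_spike <- function(spike_val, grav, t0, A) {
    up <- t >= t0 & t < t0 + w
    spike_val[up] <- spike_val[up] + A * sin(pi * (t[up] - t0) / w)
    dn <- t >= t0 + w & t < t0 + 3 * w
    spike_val[dn] <- spike_val[dn] -
      (A / 4) * sin(pi * (t[dn] - t0 - w) / (2 * w))
    ramp <- t >= t0 & t < t0 + w / 2
    grav[ramp] <- (t[ramp] - t0) / (w / 2)
    list(spike_val, grav)
  }
  if (length(tl$flights) == 2) {
    tmp <- add_spike(spike_val, grav, tl$flights[[1]][2], A_imp * 0.5)
    spike_val <- tmp[[1]]; grav <- tmp[[2]]
  }
  tmp <- add_spike(spike_val, grav, tl$spike_start, A_imp)
  spike_val <- tmp[[1]]; grav <- tmp[[2]]
  grav[flight_mask] <- 0

  tau <- config$osc_tau_s
  fo <- config$osc_freq_hz
  phi <- zero_area_phase(fo, tau)
  osc_shape <- ifelse(t >= tc,
                      exp(-(t - tc) / tau) *
                        sin(2 * pi * fo * (t - tc) + phi), 0)

  rot <- numeric(n)
  last_fl <- tl$flights[[length(tl$flights)]]
  rot[in_any(t, last_fl)] <- config$rot_rate_dps[[task]]
  if (length(tl$flights) == 2)
    rot[in_any(t, tl$flights[[1]])] <- config$rot_rate_dps[[task]] * 0.6

  ns <- config$noise_sd
  sig <- withr_rng(seed, function() {
    ch <- list(
      acc_ml = amp[["acc_ml"]] * osc_shape + rnorm(n, 0, ns[["acc"]]),
      acc_ap = amp[["acc_ap"]] * osc_shape + rnorm(n, 0, ns[["acc"]]),
      acc_v = grav + spike_val + amp[["acc_v"]] * osc_shape +
        rnorm(n, 0, ns[["acc"]]),
      gyro_sagittal = rot + amp[["gyro_sagittal"]] * osc_shape +
        rnorm(n, 0, ns[["gyro"]]),
      gyro_frontal = amp[["gyro_frontal"]] * osc_shape +
        rnorm(n, 0, ns[["gyro"]]),
      gyro_transverse = amp[["gyro_transverse"]] * osc_shape +
        rnorm(n, 0, ns[["gyro"]]))
    ch
  })
  imu <- tibble(time_s = t, !!!sig)

  rms <- vapply(imu_channels(), function(c_)
    damped_sine_rms(amp[[c_]], fo, tau, 3, phi), numeric(1))
  truth <- list(contact_time_s = tc, flight_intervals = tl$flights,
                channel_rms = rms, osc_amp = amp, osc_phi = phi,
                impact_peak_g = A_imp)
  list(imu = imu, truth = truth)
}

#' Generate the EMG part of one synthetic trial
#'
#' Each muscle is a Gaussian-noise carrier band-limited to 30-350 Hz at the
#' native rate (so the downstream 30-350 Hz band-pass is approximately
#' transparent and envelope-level tests are isolated from filter effects),
#' multiplied by a deterministic burst envelope that ramps up a task- and
#' muscle-specific lead time before contact, peaks just after contact and
#' decays exponentially; additive measurement noise sits under everything.
#'
#' @inheritParams generate_imu_trial
#' @param contact_time_s Contact instant on the shared time base, s.
#' @param duration_s Total trial span, s (defaults to the task timeline).
#' @param amp_scale Extra multiplicative factor on every envelope (used e.g.
#'   to provoke the downstream 3 mV quality screen).
#' @return List with `emg` (tibble `time_s` + `emg_muscles()`, mV),
#'   `envelopes` (noise-free envelope matrix, one column per muscle) and
#'   `onset_s` (named true envelope onsets, s).
#' @export
generate_emg_trial <- function(config, cell, contact_time_s, seed = NULL,
                               duration_s = NULL, amp_scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  task <- assert_task(cell$task)
  if (!config$emg_rate_hz %in% c(1926, 1111))
    stop_ls("landstab_invalid_config", "emg_rate_hz must be 1926 or 1111")
  duration_s <- duration_s %||% trial_timeline(config, task)$total
  if (contact_time_s <= 0 || contact_time_s >= duration_s)
    stop_ls("landstab_invalid_config",
            "contact_time_s must lie inside the trial span")
  seed <- seed %||% stream_seed(config$seed, subject_index(cell$subject_id),
                                task, cell$gaze, cell$repetition, 2)
  rate <- config$emg_rate_hz
  n <- floor(duration_s * rate) + 1
  t <- time_base(n, rate)
  fac <- trial_factors(config, cell)

  bp <- butter(4, c(30, 350) / (rate / 2), type = "pass")
  env <- matrix(0, n, 6, dimnames = list(NULL, emg_muscles()))
  onset <- stats::setNames(numeric(6), emg_muscles())
  for (m in emg_muscles()) {
    pre <- config$emg_preactivation_s[m, task]
    t_on <- contact_time_s - pre
    t_pk <- contact_time_s + config$emg_peak_offset_s
    A <- config$emg_amp_mV[[m]] * config$emg_task_amp[[task]] *
      fac$subject * fac$rep * amp_scale
    e <- numeric(n)
    ris <- t >= t_on & t < t_pk
    e[ris] <- 0.5 * (1 - cos(pi * (t[ris] - t_on) / (t_pk - t_on)))
    dec <- t >= t_pk
    e[dec] <- exp(-(t[dec] - t_pk) / config$emg_decay_s)
    env[, m] <- A * e
    onset[m] <- t_on
  }
  ns_emg <- config$noise_sd[["emg"]]
  sig <- withr_rng(seed, function() {
    out <- matrix(0, n, 6, dimnames = list(NULL, emg_muscles()))
    for (m in emg_muscles()) {
      carrier <- zero_phase_filter(bp$b, bp$a, rnorm(n))
      carrier <- carrier / sqrt(mean(carrier^2))
      out[, m] <- env[, m] * carrier + rnorm(n, 0, ns_emg)
    }
    out
  })
  emg <- tibble(time_s = t, !!!as.data.frame(sig))
  list(emg = emg, envelopes = env, onset_s = onset)
}

#' Generate one full synthetic trial
#'
#' Convenience wrapper combining [generate_imu_trial()] and
#' [generate_emg_trial()] into a [raw_trial()] plus its ground truth.
#'
#' @inheritParams generate_imu_trial
#' @return List with `trial` (a [raw_trial()]) and `truth` (IMU ground truth
#'   plus `emg_onset_s`).
#' @export
generate_trial <- function(config, cell) {
  meta <- trial_meta(cell$subject_id, cell$task, cell$gaze, cell$repetition,
                     config$emg_rate_hz, config$imu_rate_hz)
  im <- generate_imu_trial(config, meta)
  em <- generate_emg_trial(config, meta, im$truth$contact_time_s)
  truth <- im$truth
  truth$emg_onset_s <- em$onset_s
  list(trial = raw_trial(meta, em$emg, im$imu), truth = truth)
}

#' Generate and write a full synthetic dataset
#'
#' Writes every trial of the configured design (`n_subjects x tasks x 2 gaze
#' x reps_per_cell`) in the package's CSV layout, plus `manifest.csv`,
#' `ground_truth.csv` (contact time, flight count, per-channel analytic RMS,
#' EMG onsets, keyed by trial id) and `config.txt` (flat key-value dump).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return The manifest tibble, invisibly.
#' @export
generate_dataset <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  man_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(man_path) && !overwrite)
    stop_ls("landstab_exists",
            "manifest already exists at %s (use overwrite = TRUE)", man_path)
  dir.create(file.path(out_dir, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  grid <- expand.grid(repetition = seq_len(config$reps_per_cell),
                      gaze = config$gaze_levels, task = config$tasks,
                      subject_id = sprintf("S%02d", seq_len(config$n_subjects)),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  truths <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    meta <- trial_meta(g$subject_id, g$task, g$gaze, g$repetition,
                       config$emg_rate_hz, config$imu_rate_hz)
    gt <- generate_trial(config, meta)
    id <- trial_id(meta)
    emg_rel <- file.path("trials", paste0(id, "_emg.csv"))
    imu_rel <- file.path("trials", paste0(id, "_imu.csv"))
    write_trial(gt$trial, file.path(out_dir, emg_rel),
                file.path(out_dir, imu_rel))
    rows[[i]] <- tibble(trial_id = id, subject_id = g$subject_id,
                        task = g$task, gaze = g$gaze,
                        repetition = g$repetition,
                        emg_path = emg_rel, imu_path = imu_rel,
                        emg_rate_hz = config$emg_rate_hz,
                        imu_rate_hz = config$imu_rate_hz)
    tr <- gt$truth
    truths[[i]] <- tibble(trial_id = id,
                          contact_time_s = tr$contact_time_s,
                          n_flight_phases = length(tr$flight_intervals),
                          !!!stats::setNames(as.list(tr$channel_rms),
                                             paste0("rms_", imu_channels())),
                          !!!stats::setNames(as.list(tr$emg_onset_s),
                                             paste0("onset_", emg_muscles())))
  }
  manifest <- dplyr::bind_rows(rows)
  data.table::fwrite(manifest, man_path)
  data.table::fwrite(dplyr::bind_rows(truths),
                     file.path(out_dir, "ground_truth.csv"))
  writeLines(flatten_config(config), file.path(out_dir, "config.txt"))
  invisible(manifest)
}

# flat key=value serialisation (vectors comma-joined, matrices row-major with
# dimnames)
flatten_config <- function(config) {
  unlist(lapply(names(config), function(k) {
    v <- config[[k]]
    if (is.matrix(v)) {
      vals <- apply(v, 1, paste, collapse = ",")
      paste0(k, ".", rownames(v), "=", vals)
    } else {
      paste0(k, "=", paste(format(v, digits = 15, scientific = FALSE,
                                  trim = TRUE), collapse = ","))
    }
  }))
}
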