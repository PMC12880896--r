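test_that("identical config and seed give bit-identical trials", {
  cfg <- small_config()
  meta <- trial_meta("S01", "SB", "down", 1)
  a <- generate_trial(cfg, meta)
  b <- generate_trial(cfg, meta)
  expect_identical(a$trial$imu, b$trial$imu)
  expect_identical(a$trial$emg, b$trial$emg)
  expect_identical(a$truth, b$truth)
})

test_that("AS trials carry two flight phases ending at contact", {
  cfg <- small_config()
  g <- generate_imu_trial(cfg, trial_meta("S01", "AS", "down", 1))
  expect_length(g$truth$flight_intervals, 2)
  expect_equal(g$truth$contact_time_s,
               g$truth$flight_intervals[[2]][2] + cfg$impact_width_s / 2)
  # the handspring can be omitted
  cfg1 <- small_config(as_first_flight = FALSE)
  g1 <- generate_imu_trial(cfg1, trial_meta("S01", "AS", "down", 1))
  expect_length(g1$truth$flight_intervals, 1)
})

test_that("zero oscillation and zero noise leave channels silent after the transient", {
  cfg <- small_config(osc_amp = 0, noise_sd = c(acc = 0, gyro = 0, emg = 0))
  g <- generate_imu_trial(cfg, trial_meta("S01", "DL", "down", 1))
  tc <- g$truth$contact_time_s
  after <- g$imu$time_s > tc + 3 * cfg$impact_width_s
  for (ch in setdiff(imu_channels(), "acc_v")) {
    expect_identical(unique(g$imu[[ch]][after]), 0)
  }
  expect_identical(unique(g$imu$acc_v[after]), 1) # gravity only
  expect_true(all(g$truth$channel_rms < 1e-12))
})

test_that("ground-truth channel RMS matches dense quadrature within 1%", {
  cfg <- small_config()
  g <- generate_imu_trial(cfg, trial_meta("S04", "SF", "ahead", 2))
  for (ch in imu_channels()) {
    ref <- oracle_damped_rms(g$truth$osc_amp[[ch]], cfg$osc_freq_hz,
                             cfg$osc_tau_s, 3, g$truth$osc_phi)
    expect_lt(abs(g$truth$channel_rms[[ch]] - ref) / max(ref, 1e-12), 0.01)
  }
})

test_that("specific-force magnitude stays below 0.3 g inside every flight interval", {
  cfg <- sim_config(n_subjects = 3, reps_per_cell = 1, seed = 7)
  for (task in landing_tasks()) {
    g <- generate_imu_trial(cfg, trial_meta("S02", task, "ahead", 1))
    mag <- sqrt(g$imu$acc_ml^2 + g$imu$acc_ap^2 + g$imu$acc_v^2)
    for (iv in g$truth$flight_intervals) {
      inside <- g$imu$time_s >= iv[1] & g$imu$time_s < iv[2]
      expect_true(all(mag[inside] < 0.3))
    }
  }
})

test_that("EMG envelope onset tracks the configured preactivation lead", {
  cfg50 <- small_config()
  cfg50$emg_preactivation_s[] <- 0.05
  cfg150 <- small_config()
  cfg150$emg_preactivation_s[] <- 0.15
  meta <- trial_meta("S01", "SF", "down", 1)
  tc <- 2.5
  e50 <- generate_emg_trial(cfg50, meta, tc, seed = 5, duration_s = 6)
  e150 <- generate_emg_trial(cfg150, meta, tc, seed = 5, duration_s = 6)
  onset_of <- function(env) {
    # threshold crossing on the stored noise-free envelope
    (which(env > 0.05 * max(env))[1] - 1) / cfg50$emg_rate_hz
  }
  for (m in emg_muscles()) {
    expect_lt(onset_of(e150$envelopes[, m]), onset_of(e50$envelopes[, m]))
    expect_equal(e50$onset_s[[m]], tc - 0.05)
    expect_equal(e150$onset_s[[m]], tc - 0.15)
  }
  # zero envelope amplitude leaves pure baseline noise
  cfg0 <- small_config()
  cfg0$emg_amp_mV[] <- 0
  e0 <- generate_emg_trial(cfg0, meta, tc, seed = 5, duration_s = 6)
  expect_lt(max(abs(e0$emg$rectus_femoris)),
            6 * cfg0$noise_sd[["emg"]])
  # amplitude pushed over 3 mV is caught by the downstream quality screen
  ebig <- generate_emg_trial(small_config(), meta, tc, seed = 5,
                             duration_s = 6, amp_scale = 8)
  expect_gt(max(abs(ebig$emg$rectus_femoris)), 3)
  expect_false(qc_check(ebig$emg$rectus_femoris)$keep)
})

test_that("an injected gaze effect propagates to a detectable ANOVA signal", {
  cfg <- sim_config(n_subjects = 6, reps_per_cell = 2, seed = 11,
                    gaze_effect = 0.5)
  rows <- list()
  for (s in sprintf("S%02d", 1:6)) for (task in landing_tasks())
    for (gz in gaze_levels()) for (rep in 1:2) {
      meta <- trial_meta(s, task, gz, rep)
      g <- generate_imu_trial(cfg, meta)
      ct <- detect_contact(g$imu)
      idx <- compute_indices(g$imu, ct, windows_s = 3)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = s, task = task, gaze = gz, repetition = rep,
        outcome = "dsi_acc_ap_3s",
        value = idx$dsi[idx$channel == "acc_ap"])
    }
  tab <- aggregate_reps(dplyr::bind_rows(rows))
  an <- rm_anova_2way(tab, "dsi_acc_ap_3s")
  expect_lt(an$p[an$effect == "gaze"], 0.05)
  expect_gt(mean(tab$value[tab$gaze == "ahead"]),
            mean(tab$value[tab$gaze == "down"]))
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(emg_rate_hz = 1200), class = "landstab_invalid_config")
  expect_error(sim_config(flight_duration_s = c(DL = 0.004, SB = 0.5,
                                                SF = 0.5, AS = 0.5)),
               class = "landstab_invalid_config")
  expect_error(sim_config(osc_freq_hz = -1), class = "landstab_invalid_config")
  cfg <- small_config()
  expect_error(generate_emg_trial(cfg, trial_meta("S01", "DL", "down", 1),
                                  contact_time_s = 99, duration_s = 6),
               class = "landstab_invalid_config")
  cfg_dl <- sim_config(tasks = "DL", n_subjects = 2, reps_per_cell = 2)
  expect_error(generate_imu_trial(cfg_dl, trial_meta("S01", "SB", "down", 1)),
               class = "landstab_invalid_config")
})

test_that("generate_dataset writes the full design and is reproducible", {
  dir1 <- file.path(tempdir(), "ds-a")
  dir2 <- file.path(tempdir(), "ds-b")
  unlink(c(dir1, dir2), recursive = TRUE)
  cfg <- small_config()
  man <- generate_dataset(cfg, dir1)
  expect_equal(nrow(man), 2 * 4 * 2 * 2)
  expect_true(file.exists(file.path(dir1, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir1, "config.txt")))
  # same config + seed -> identical bytes
  man2 <- generate_dataset(cfg, dir2)
  files <- list.files(dir1, recursive = TRUE)
  expect_identical(
    unname(tools::md5sum(file.path(dir1, files))),
    unname(tools::md5sum(file.path(dir2, files))))
  # collision refused without overwrite
  expect_error(generate_dataset(cfg, dir1), class = "landstab_exists")
  expect_silent(generate_dataset(cfg, dir1, overwrite = TRUE))
})
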