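test_that("contact is recovered near ground truth, after the last flight", {
  cfg <- small_config()
  g <- generate_imu_trial(cfg, trial_meta("S01", "SB", "down", 1))
  ct <- detect_contact(g$imu)
  expect_lt(abs(ct$time_s - g$truth$contact_time_s), 0.005)
  # two-flight acrobatic series anchors on the second flight
  g2 <- generate_imu_trial(cfg, trial_meta("S01", "AS", "down", 1))
  ct2 <- detect_contact(g2$imu)
  expect_identical(ct2$flight_intervals_found, 2L)
  expect_gt(ct2$time_s, g2$truth$flight_intervals[[2]][2])
  expect_lt(abs(ct2$time_s - g2$truth$contact_time_s), 0.005)
})

test_that("quiet stance alone raises a no-flight error", {
  set.seed(5)
  n <- 3000
  imu <- tibble::tibble(time_s = (0:(n - 1)) / 370.4,
                        acc_ml = rnorm(n, 0, 0.02),
                        acc_ap = rnorm(n, 0, 0.02),
                        acc_v = rnorm(n, 1, 0.02),
                        gyro_sagittal = rnorm(n, 0, 1),
                        gyro_frontal = rnorm(n, 0, 1),
                        gyro_transverse = rnorm(n, 0, 1))
  expect_error(detect_contact(imu), class = "landstab_no_flight")
  # flight with no subsequent impact peak raises a no-impact error
  imu2 <- imu
  fl <- imu2$time_s > 3 & imu2$time_s < 3.5
  imu2$acc_v[fl] <- rnorm(sum(fl), 0, 0.02)
  after <- imu2$time_s >= 3.5
  imu2$acc_v[after] <- rnorm(sum(after), 1, 0.02)
  expect_error(detect_contact(imu2), class = "landstab_no_impact")
})

test_that("30 Hz low-pass passes DC, kills 100 Hz, keeps pulse peaks in place", {
  expect_equal(lowpass_30(rep(0.7, 2000)), rep(0.7, 2000), tolerance = 1e-9)
  t <- (0:1999) / 370.4
  y <- lowpass_30(sin(2 * pi * 100 * t))
  expect_lt(fit_amplitude(y, 100, 370.4, 800:1200), 0.05)
  pulse <- exp(-((seq_len(2000) - 1000)^2) / (2 * 40^2))
  expect_identical(which.max(lowpass_30(pulse)), 1000L)
})

test_that("baseline zeroing removes the terminal mean and is idempotent", {
  rate <- 370.4
  seg3 <- rep(0.7, floor(3 * rate))
  expect_equal(baseline_subtract(seg3, 3), rep(0, length(seg3)))
  set.seed(6)
  for (w in c(3, 1)) {
    seg <- rnorm(floor(w * rate)) + 0.3
    z <- baseline_subtract(seg, w)
    n_tail <- floor(ifelse(w == 3, 0.5, 0.25) * rate)
    expect_lt(abs(mean(tail(z, n_tail))), 1e-12)
    # independent loop oracle
    s <- 0
    for (v in tail(seg, n_tail)) s <- s + v
    expect_equal(z, seg - s / n_tail, tolerance = 1e-12)
    expect_equal(baseline_subtract(z, w), z, tolerance = 1e-12)
  }
})

test_that("DSI is the RMS deviation from zero with its symmetries", {
  expect_identical(dsi(numeric(100)), 0)
  rate <- 370.4
  t <- (0:(floor(3 * rate) - 1)) / rate
  # whole number of periods of a 0.5 g sinusoid
  x <- 0.5 * sin(2 * pi * 2 * t[t < 1.5])
  expect_lt(abs(dsi(x) - 0.5 / sqrt(2)) / (0.5 / sqrt(2)), 0.005)
  set.seed(7)
  for (i in 1:20) {
    seg <- rnorm(200)
    expect_lt(abs(dsi(seg) - oracle_rms(seg)), 1e-12)
    expect_equal(dsi(3.7 * seg), 3.7 * dsi(seg), tolerance = 1e-12)
    expect_equal(dsi(rev(seg)), dsi(seg), tolerance = 1e-12)
  }
  expect_error(dsi(numeric(0)), class = "landstab_signal_error")
})

test_that("TTS handles the degenerate and sentinel conventions", {
  rate <- 370.4
  n <- floor(1 * rate)
  # identically zero signal stabilises immediately
  expect_equal(tts(numeric(n), rate, 1), list(tts_s = 0, censored = FALSE))
  # constant offset above any threshold never stabilises -> sentinel
  off <- c(rep(0.5, n - 92), rnorm(92, 0, 1e-3))
  off <- baseline_subtract(off, 1, rate) + 0.5
  r <- tts(off, rate, 1)
  expect_equal(r$tts_s, 1)
  expect_true(r$censored)
  # zero threshold with non-zero signal warns and censors
  expect_warning(r2 <- tts(c(rep(1, n - 92), rep(0, 92)), rate, 1),
                 "zero stabilisation threshold")
  expect_true(r2$censored)
})

test_that("TTS agrees exactly with the exhaustive-scan oracle", {
  rate <- 370.4
  set.seed(8)
  for (i in 1:40) {
    n <- floor(1 * rate)
    t <- (0:(n - 1)) / rate
    A <- runif(1, 0.2, 1.5)
    seg <- A * exp(-t / runif(1, 0.1, 0.5)) *
      sin(2 * pi * runif(1, 4, 9) * t + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 0.01)
    seg <- baseline_subtract(seg, 1, rate)
    got <- tts(seg, rate, 1)
    ref <- oracle_tts(seg, rate, 1)
    expect_identical(got, ref)
  }
})

test_that("TTS never decreases when the transient is amplified", {
  rate <- 370.4
  n <- floor(3 * rate)
  t <- (0:(n - 1)) / rate
  phi <- -atan(2 * pi * 6 * 0.4)
  base <- exp(-t / 0.4) * sin(2 * pi * 6 * t + phi)
  tail_n <- floor(0.5 * rate)
  base[(n - tail_n + 1):n] <- base[(n - tail_n + 1):n] +
    sin(2 * pi * 3 * t[1:tail_n]) * 1e-4 # fixed tiny tail so sd > 0
  prev <- -Inf
  for (c_ in c(1, 2, 4, 8)) {
    seg <- base
    seg[1:(n - tail_n)] <- c_ * seg[1:(n - tail_n)]
    cur <- tts(seg, rate, 3)$tts_s
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("per-trial indices match the generator's analytic RMS and bounds", {
  # noise-free narrow-impact trial: low-pass + windowing leave the damped
  # oscillation as the dominant term, so DSI tracks the closed form
  cfg <- sim_config(n_subjects = 2, reps_per_cell = 1, seed = 1,
                    noise_sd = c(acc = 0, gyro = 0, emg = 0),
                    impact_width_s = 0.008,
                    impact_amplitude_g = c(DL = 2.5, SB = 2.5, SF = 2.5,
                                           AS = 2.5))
  g <- generate_imu_trial(cfg, trial_meta("S01", "SB", "down", 1))
  ct <- detect_contact(g$imu)
  idx <- compute_indices(g$imu, ct)
  got <- idx$dsi[idx$channel == "acc_v" & idx$window_s == 3]
  expect_lt(abs(got - g$truth$channel_rms[["acc_v"]]) /
              g$truth$channel_rms[["acc_v"]], 0.02)
  # 1-s DSI >= 3-s DSI for decaying oscillations
  expect_true(all(idx$dsi[idx$window_s == 1] >= idx$dsi[idx$window_s == 3]))
  # zero post-impact motion: DSI at the noise floor, TTS at zero
  cfg0 <- sim_config(n_subjects = 2, reps_per_cell = 1, seed = 1,
                     osc_amp = 0, noise_sd = c(acc = 0, gyro = 0, emg = 0))
  g0 <- generate_imu_trial(cfg0, trial_meta("S01", "DL", "down", 1))
  ct0 <- detect_contact(g0$imu)
  # acc_v is degenerate here (exactly constant tail), which warns; the
  # moving channels are the ones under test
  idx0 <- suppressWarnings(compute_indices(g0$imu, ct0))
  quiet <- idx0[idx0$channel != "acc_v", ]
  expect_true(all(quiet$dsi < 1e-9))
  expect_true(all(quiet$tts_s == 0))
  # insufficient post-contact span is a loud error
  short <- g$imu[g$imu$time_s < ct$time_s + 1, ]
  expect_error(compute_indices(short, ct), class = "landstab_signal_error")
})
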