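# Contact detection and stabilisation indices from the lower-back IMU.
# Contact is the first local peak of vertical acceleration after the end of
# the last flight phase (flight = near-zero specific force). Indices are
# computed per channel over 3-s and 1-s post-contact windows after 30-Hz
# low-pass filtering and terminal-baseline zeroing:
#   DSI  = RMS deviation from the zero baseline,
#   TTS  = sequential-average time to stabilisation (cumulative
#          average, threshold 0.25 x SD of the quiet tail).

IMU_RATE <- 370.4

#' Detect foot-floor contact from the IMU record
#'
#' Flight phases are maximal runs where the specific-force magnitude
#' `sqrt(acc_ml^2 + acc_ap^2 + acc_v^2)` stays below `flight_g` for at least
#' `flight_min_s` (free fall reads ~0 g on a body-worn accelerometer).
#' Contact is the first local maximum of vertical acceleration exceeding
#' `peak_min_g` after the end of the *last* flight phase, searched within
#' `search_s`; multi-flight trials (e.g. an acrobatic series) therefore
#' anchor on the final landing.
#'
#' @param imu Data frame with `time_s` and the [imu_channels()] columns, at a
#'   uniform rate.
#' @param flight_g Flight-phase magnitude threshold, g (default 0.3).
#' @param flight_min_s Minimum flight duration, s (default 0.08).
#' @param peak_min_g Minimum impact peak, g (default 2).
#' @param search_s Search horizon after flight end, s (default 0.2).
#' @return List `time_s`, `index`, `flight_intervals_found`, and
#'   `flight_intervals` (list of `c(start, end)` times).
#' @export
detect_contact <- function(imu, flight_g = 0.3, flight_min_s = 0.08,
                           peak_min_g = 2, search_s = 0.2) {
  need <- c("time_s", "acc_ml", "acc_ap", "acc_v")
  if (!all(need %in% names(imu)))
    stop_ls("landstab_malformed_file", "IMU record lacks accelerometer columns")
  t <- imu$time_s
  rate <- 1 / stats::median(diff(t))
  mag <- sqrt(imu$acc_ml^2 + imu$acc_ap^2 + imu$acc_v^2)
  low <- mag < flight_g
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  min_n <- ceiling(flight_min_s * rate)
  keep <- r$values & r$lengths >= min_n
  if (!any(keep))
    stop_ls("landstab_no_flight", "no flight phase found in IMU record")
  fl_start <- starts[keep]; fl_end <- ends[keep]
  intervals <- Map(function(s, e) c(t[s], t[e]), fl_start, fl_end)
  last_end <- fl_end[length(fl_end)]
  v <- imu$acc_v
  hi <- min(length(v) - 1, last_end + ceiling(search_s * rate))
  idx <- NA_integer_
  for (i in seq(max(last_end, 2), hi)) {
    if (v[i] > peak_min_g && v[i] > v[i - 1] && v[i] >= v[i + 1]) {
      idx <- i
      break
    }
  }
  if (is.na(idx))
    stop_ls("landstab_no_impact",
            "no vertical-acceleration peak above %g g within %g s of flight end",
            peak_min_g, search_s)
  list(time_s = t[idx], index = idx,
       flight_intervals_found = length(intervals),
       flight_intervals = intervals)
}

#' Zero-phase 30 Hz low-pass (IMU)
#'
#' 4th-order Butterworth low-pass at 30 Hz applied forward and backward
#' (zero phase), matching the pre-index smoothing of the accelerations and
#' angular velocities.
#'
#' @param x Numeric channel at `rate_hz`.
#' @param rate_hz Sampling rate, default 370.4 Hz.
#' @return Filtered signal.
#' @export
lowpass_30 <- function(x, rate_hz = IMU_RATE) {
  if (length(x) < 30)
    stop_ls("landstab_signal_error", "signal too short to low-pass filter")
  b <- butter(4, 30 / (rate_hz / 2), type = "low")
  zero_phase_filter(b$b, b$a, x)
}

baseline_tail_s <- function(window_s) {
  if (isTRUE(all.equal(window_s, 3))) return(0.5)
  if (isTRUE(all.equal(window_s, 1))) return(0.25)
  window_s / 6
}

#' Terminal-baseline zeroing
#'
#' Subtracts the mean of the final 0.5 s (3-s window) or 0.25 s (1-s window)
#' so that indices measure deviation from terminal quiet stance ("zero"
#' baseline). For other window lengths the tail is `window_s / 6`, which
#' reproduces both stated pairs.
#'
#' @param segment Post-contact channel segment covering exactly the analysis
#'   window, uniform rate.
#' @param window_s Analysis window length, s (3 or 1).
#' @param rate_hz Sampling rate, default 370.4 Hz.
#' @return The zeroed segment.
#' @export
baseline_subtract <- function(segment, window_s, rate_hz = IMU_RATE) {
  n_tail <- max(1L, floor(baseline_tail_s(window_s) * rate_hz))
  if (n_tail > length(segment))
    stop_ls("landstab_signal_error", "segment shorter than its baseline tail")
  segment - mean(tail(segment, n_tail))
}

#' Dynamic stability index
#'
#' Root-mean-square deviation of a baseline-zeroed post-contact segment from
#' zero: `sqrt(sum((0 - x_i)^2) / N)`. Units follow the input channel (g for
#' accelerations, deg/s for angular velocities); smaller is more stable.
#'
#' @param segment Baseline-subtracted segment.
#' @return Non-negative scalar.
#' @export
dsi <- function(segment) {
  if (!length(segment))
    stop_ls("landstab_signal_error", "empty segment")
  sqrt(sum(segment^2) / length(segment))
}

#' Time to stabilisation (sequential-average method)
#'
#' The sequential average `seq(k) = mean(x[1:k])` is tracked from contact
#' onward; the stabilisation threshold is `0.25 x SD` of the segment's quiet
#' tail (the same 0.5 s / 0.25 s used for baseline zeroing). TTS is the
#' earliest time `t*` such that `|seq(k)| <= T` for every sample at or after
#' `t*`. If the condition is never met the window length is returned as a
#' bounded sentinel and the result is flagged censored; a zero threshold with
#' non-zero signal is likewise censored, with a warning.
#'
#' @param segment Baseline-subtracted segment at uniform rate, first sample
#'   at contact (time 0).
#' @param rate_hz Sampling rate, default 370.4 Hz.
#' @param window_s Analysis window length, s.
#' @param variant Threshold base: `"tail_sd"` (default; SD of the quiet
#'   baseline tail) or `"series_sd"` (SD of the whole segment, the original
#'   sequential-average formulation).
#' @return List `tts_s` and `censored`.
#' @export
tts <- function(segment, rate_hz = IMU_RATE, window_s = 3,
                variant = c("tail_sd", "series_sd")) {
  variant <- match.arg(variant)
  if (!length(segment))
    stop_ls("landstab_signal_error", "empty segment")
  n_tail <- max(1L, floor(baseline_tail_s(window_s) * rate_hz))
  thr <- 0.25 * if (variant == "tail_sd") sd(tail(segment, n_tail)) else
    sd(segment)
  if (!is.finite(thr) || thr == 0) {
    if (any(segment != 0)) {
      warning("zero stabilisation threshold with non-zero signal; censored")
      return(list(tts_s = window_s, censored = TRUE))
    }
    return(list(tts_s = 0, censored = FALSE))
  }
  seq_avg <- cumsum(segment) / seq_along(segment)
  viol <- which(abs(seq_avg) > thr)
  if (!length(viol)) return(list(tts_s = 0, censored = FALSE))
  k_last <- viol[length(viol)]
  if (k_last == length(segment))
    return(list(tts_s = window_s, censored = TRUE))
  list(tts_s = k_last / rate_hz, censored = FALSE)
}

#' Stabilisation indices for one trial
#'
#' For each of the six IMU channels and each analysis window (3 s and 1 s
#' after contact): 30-Hz zero-phase low-pass on the full channel, windowing
#' from the contact sample, terminal-baseline zeroing, then [dsi()] and
#' [tts()] - 24 numbers per trial.
#'
#' @param imu Data frame with `time_s` + [imu_channels()].
#' @param contact A [detect_contact()] result (or list with `index`).
#' @param windows_s Analysis window lengths, s.
#' @param rate_hz Sampling rate, default 370.4 Hz.
#' @param tts_variant Passed to [tts()].
#' @return Tidy tibble `window_s, channel, dsi, tts_s, tts_censored`.
#' @export
compute_indices <- function(imu, contact, windows_s = c(3, 1),
                            rate_hz = IMU_RATE, tts_variant = "tail_sd") {
  ic <- contact$index
  n_need <- floor(max(windows_s) * rate_hz)
  if (ic + n_need - 1 > nrow(imu))
    stop_ls("landstab_signal_error",
            "insufficient post-contact data: need %.2f s after contact",
            max(windows_s))
  out <- list()
  for (ch in imu_channels()) {
    filt <- lowpass_30(imu[[ch]], rate_hz)
    for (w in windows_s) {
      seg <- filt[ic:(ic + floor(w * rate_hz) - 1)]
      seg0 <- baseline_subtract(seg, w, rate_hz)
      ts <- tts(seg0, rate_hz, w, variant = tts_variant)
      out[[length(out) + 1]] <- tibble(window_s = w, channel = ch,
                                       dsi = dsi(seg0), tts_s = ts$tts_s,
                                       tts_censored = ts$censored)
    }
  }
  dplyr::bind_rows(out)
}
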