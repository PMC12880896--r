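# EMG processing chain: resample -> band-pass -> rectify, with the quality
# screen applied to the raw (unfiltered) amplitude, then participant-level
# AS-maximum normalisation and 20-ms integration into 30-node patterns.
# The order is fixed; normalising after integration is not equivalent and is
# asserted against in the tests.

EMG_RATE_OUT <- 1000

#' Resample a signal to the unified 1000 Hz grid
#'
#' The two EMG sensor generations run at 1926 and 1111 Hz; analysis happens on
#' a common 1000 Hz grid. Resampling is cubic-spline interpolation onto the
#' uniform output grid (1111 -> 1000 is non-integer, so plain decimation is
#' not available); interpolation preserves envelope phase, which is what the
#' downstream +/-300 ms pattern windows depend on.
#'
#' @param x Numeric signal sampled uniformly at `native_rate_hz`, starting at
#'   time 0.
#' @param native_rate_hz Input rate; 1926 and 1111 Hz are the expected native
#'   rates, others are accepted with a warning.
#' @return Numeric signal at 1000 Hz spanning the input.
#' @export
resample_to_1000hz <- function(x, native_rate_hz) {
  if (length(x) < 10)
    stop_ls("landstab_signal_error", "input shorter than 10 samples")
  if (!native_rate_hz %in% c(1926, 1111))
    warning(sprintf("native rate %g Hz is not one of the expected 1926/1111 Hz",
                    native_rate_hz))
  t_in <- time_base(length(x), native_rate_hz)
  n_out <- floor(t_in[length(t_in)] * EMG_RATE_OUT) + 1
  t_out <- time_base(n_out, EMG_RATE_OUT)
  spline(t_in, x, xout = t_out, method = "fmm")$y
}

#' Zero-phase 30-350 Hz band-pass (EMG)
#'
#' 4th-order Butterworth band-pass with 30 and 350 Hz corners, applied
#' forward and backward ("bidirectional"): zero phase lag, effective order 8,
#' with reflection padding and steady-state initial conditions so constants
#' map to the DC gain (zero) without edge transients.
#'
#' @param x Numeric signal at 1000 Hz.
#' @return Filtered signal, same length.
#' @export
bandpass_30_350 <- function(x) {
  if (length(x) < 30)
    stop_ls("landstab_signal_error",
            "signal too short to band-pass filter (need >= 30 samples)")
  b <- butter(4, c(30, 350) / (EMG_RATE_OUT / 2), type = "pass")
  zero_phase_filter(b$b, b$a, x)
}

#' Full-wave rectification
#'
#' @param x Numeric signal.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Quality screen on a raw EMG channel
#'
#' Applied to the raw (unfiltered) signal in mV, since the 3 mV bound is a
#' physical electrode-level limit. A channel is excluded when its absolute
#' amplitude exceeds 3 mV, when it saturates (>= 50 consecutive samples within
#' 0.1% of the global extremum) or when it flatlines (>= 200 consecutive
#' identical values).
#'
#' @param x Raw EMG channel, mV.
#' @param amplitude_limit_mV Exclusion bound, default 3 mV.
#' @return List `keep` (logical) and `reason` (one of `ok`,
#'   `amplitude_over_3mV`, `artifact_saturation`, `artifact_flatline`).
#' @export
qc_check <- function(x, amplitude_limit_mV = 3) {
  verdict <- function(keep, reason) list(keep = keep, reason = reason)
  if (max(abs(x)) > amplitude_limit_mV)
    return(verdict(FALSE, "amplitude_over_3mV"))
  for (ext in c(max(x), min(x))) {
    near <- abs(x - ext) <= 0.001 * abs(ext)
    if (any(near) && max_run(near) >= 50)
      return(verdict(FALSE, "artifact_saturation"))
  }
  if (length(x) > 1 && max_run(diff(x) == 0) + 1 >= 200)
    return(verdict(FALSE, "artifact_flatline"))
  verdict(TRUE, "ok")
}

max_run <- function(b) {
  r <- rle(b)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Participant-level AS-maximum normalisation
#'
#' All of one participant's processed EMG (per muscle) is divided by the
#' maximal processed (band-passed, rectified) amplitude observed during that
#' participant's AS trials, pooling both gaze directions. By default the
#' maximum is taken within the -300..+300 ms analysis window of each AS trial;
#' `whole_trial = TRUE` uses the entire AS recordings instead.
#'
#' @param trials List, one entry per kept trial of one participant and one
#'   muscle: each a list with `x` (processed signal at 1000 Hz), `contact_s`
#'   (contact time on the signal's time base) and `task`.
#' @param whole_trial Use whole-trial maxima rather than analysis-window
#'   maxima.
#' @return List `divisor` (the scale factor) and `trials` (input list with
#'   each `x` divided by it).
#' @export
normalise_to_as_max <- function(trials, whole_trial = FALSE) {
  as_idx <- which(vapply(trials, function(tr) tr$task == "AS", logical(1)))
  if (!length(as_idx))
    stop_ls("landstab_normalisation_error",
            "no kept AS trial available to normalise against")
  maxima <- vapply(as_idx, function(i) {
    tr <- trials[[i]]
    if (whole_trial) return(max(tr$x))
    ic <- round(tr$contact_s * EMG_RATE_OUT) + 1
    lo <- ic - 300; hi <- ic + 299
    if (lo < 1 || hi > length(tr$x))
      stop_ls("landstab_signal_error",
              "AS trial does not cover the -300..+300 ms window")
    max(tr$x[lo:hi])
  }, numeric(1))
  divisor <- max(maxima)
  if (divisor <= 0)
    stop_ls("landstab_normalisation_error",
            "AS maximum is not positive; cannot normalise")
  trials <- lapply(trials, function(tr) { tr$x <- tr$x / divisor; tr })
  list(divisor = divisor, trials = trials)
}

#' Integrate a normalised signal into a 30-node pattern
#'
#' Thirty non-overlapping 20-ms windows spanning 300 ms before to 300 ms
#' after contact; window 16 starts exactly at the contact sample. Each node is
#' the rectangular-rule integral (sample sum x 1 ms) of the normalised
#' activity in its window, so a constant signal of 1 yields nodes of 0.020.
#'
#' @param x Normalised signal at 1000 Hz.
#' @param contact_time_s Contact instant on the signal's time base, s.
#' @return Numeric vector of 30 node values (units: normalised activity x s).
#' @export
extract_pattern <- function(x, contact_time_s) {
  ic <- round(contact_time_s * EMG_RATE_OUT) + 1
  lo <- ic - 300; hi <- ic + 299
  if (lo < 1 || hi > length(x))
    stop_ls("landstab_signal_error",
            "signal does not cover contact %+.0f..%+.0f ms (need %d..%d, have 1..%d)",
            -300, 300, lo, hi, length(x))
  seg <- x[lo:hi]
  nodes <- colSums(matrix(seg, nrow = 20)) / EMG_RATE_OUT
  stopifnot(length(nodes) == 30)
  nodes
}

#' Process all EMG channels of one trial
#'
#' Runs resample -> band-pass -> rectify per muscle, with the quality screen
#' on the raw channel first. Normalisation is a participant-level step and is
#' applied later (see [normalise_to_as_max()]).
#'
#' @param trial A [raw_trial()].
#' @return List per muscle: `keep`, `reason`, and (if kept) `x` the processed
#'   signal at 1000 Hz.
#' @export
process_emg_trial <- function(trial) {
  stopifnot(inherits(trial, "raw_trial"))
  out <- list()
  for (m in emg_muscles()) {
    raw <- trial$emg[[m]]
    qc <- qc_check(raw)
    if (!qc$keep) {
      out[[m]] <- list(keep = FALSE, reason = qc$reason)
      next
    }
    x <- resample_to_1000hz(raw, trial$meta$emg_rate_hz)
    x <- rectify(bandpass_30_350(x))
    out[[m]] <- list(keep = TRUE, reason = "ok", x = x)
  }
  out
}
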