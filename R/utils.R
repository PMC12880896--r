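# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ls <- function(class, msg, ...) {
  stop(structure(class = c(class, "landstab_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Deterministic per-stream seed derived from (master, subject, task, gaze,
# rep, stream). Iterated 31-bit multiplicative hash; all intermediates stay
# below 2^53 so double arithmetic is exact. Adding trials to a design never
# perturbs the streams of existing trials.
stream_seed <- function(master, subject_idx, task, gaze, rep, stream) {
  p <- 2147483647
  task_idx <- match(task, landing_tasks())
  gaze_idx <- match(gaze, gaze_levels())
  h <- master %% p
  for (x in c(subject_idx, task_idx, gaze_idx, rep, stream)) {
    h <- (h * 69069 + x + 1) %% p
  }
  as.integer(h)
}

# uniform time base at `rate` Hz starting at 0, n samples
time_base <- function(n, rate) (seq_len(n) - 1) / rate

# Zero-phase IIR filtering: odd-reflection padding plus step steady-state
# initial conditions, applied forward and backward. This is the classic
# bidirectional scheme (as in MATLAB's filtfilt): a constant input passes
# with exactly the filter's DC gain and edge transients are suppressed,
# which plain zero-padded forward-backward filtering does not guarantee.
zero_phase_filter <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  nb <- length(b); na_ <- length(a)
  nf <- 3 * (max(nb, na_) - 1)
  n <- length(x)
  if (n <= nf + 1)
    stop_ls("landstab_signal_error",
            "signal shorter than 3x the filter padding length")
  pre <- 2 * x[1] - x[(nf + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - nf)]
  run <- function(z) {
    y0 <- z[1] * sum(b) / sum(a)
    as.numeric(signal::filter(b, a, z, init.x = rep(z[1], nb - 1),
                              init.y = rep(y0, na_ - 1)))
  }
  y <- rev(run(rev(run(c(pre, x, post)))))
  y[(nf + 1):(nf + n)]
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 1

assert_task <- function(task) {
  if (!task %in% landing_tasks())
    stop_ls("landstab_meta_error", "unknown task token '%s'", task)
  task
}

assert_gaze <- function(gaze) {
  if (!gaze %in% gaze_levels())
    stop_ls("landstab_meta_error", "unknown gaze token '%s'", gaze)
  gaze
}

# FNV-1a 32-bit hash of a character vector, as hex. Used for run/config ids.
# Doubles stand in for uint32; the multiply is split so every intermediate
# stays exactly representable.
fnv1a_hex <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

xor32 <- function(a, b) {
  ab <- as.integer(a %% 65536); at <- as.integer(a %/% 65536)
  bb <- as.integer(b %% 65536); bt <- as.integer(b %/% 65536)
  bitwXor(at, bt) * 65536 + bitwXor(ab, bb)
}
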