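# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: plain loops, quadrature and exhaustive scans.

# root-mean-square by explicit loop
oracle_rms <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + v * v
  sqrt(acc / length(x))
}

# RMS of A exp(-t/tau) sin(2 pi f t + phi) over [0, T] by dense quadrature
oracle_damped_rms <- function(A, f, tau, T, phi = 0, n = 2e5) {
  t <- seq(0, T, length.out = n)
  y <- (A * exp(-t / tau) * sin(2 * pi * f * t + phi))^2
  sqrt(sum((y[-1] + y[-n]) / 2 * diff(t)) / T)
}

# exhaustive-scan time to stabilisation: smallest k* with |seq avg| <= T for
# every k >= k*; mirrors the definition, not the implementation
oracle_tts <- function(seg, rate, window_s) {
  n_tail <- max(1L, floor(landstab:::baseline_tail_s(window_s) * rate))
  thr <- 0.25 * sd(tail(seg, n_tail))
  n <- length(seg)
  sa <- numeric(n)
  s <- 0
  for (k in seq_len(n)) { s <- s + seg[k]; sa[k] <- s / k }
  ok <- abs(sa) <= thr
  for (kstar in seq_len(n)) {
    if (all(ok[kstar:n])) {
      return(list(tts_s = (kstar - 1) / rate, censored = FALSE))
    }
  }
  list(tts_s = window_s, censored = TRUE)
}

# direct-form IIR application (type-II transposed would be fancier; this is
# the naive difference equation), forward then backward, zero initial state
oracle_filtfilt <- function(b, a, x) {
  run <- function(x) {
    nb <- length(b); na <- length(a)
    y <- numeric(length(x))
    for (n in seq_along(x)) {
      acc <- 0
      for (i in seq_len(nb)) if (n - i + 1 >= 1) acc <- acc + b[i] * x[n - i + 1]
      for (j in 2:na) if (n - j + 1 >= 1) acc <- acc - a[j] * y[n - j + 1]
      y[n] <- acc / a[1]
    }
    y
  }
  rev(run(rev(run(x))))
}

# amplitude of the sinusoidal component at f in x (least squares on a window)
fit_amplitude <- function(x, f, rate, idx) {
  t <- (idx - 1) / rate
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- qr.solve(X, x[idx])
  sqrt(sum(cf^2))
}

# reference within-subject ANOVA through stats::aov error strata
oracle_aov <- function(tab) {
  d <- data.frame(subject_id = factor(tab$subject_id),
                  task = factor(tab$task), gaze = factor(tab$gaze),
                  value = tab$value)
  s <- summary(aov(value ~ task * gaze + Error(subject_id / (task * gaze)),
                   data = d))
  c(task = s[["Error: subject_id:task"]][[1]]["task", "F value"],
    gaze = s[["Error: subject_id:gaze"]][[1]]["gaze", "F value"],
    interaction = s[["Error: subject_id:task:gaze"]][[1]]["task:gaze",
                                                          "F value"])
}

oracle_aov_p <- function(tab) {
  d <- data.frame(subject_id = factor(tab$subject_id),
                  task = factor(tab$task), gaze = factor(tab$gaze),
                  value = tab$value)
  s <- summary(aov(value ~ task * gaze + Error(subject_id / (task * gaze)),
                   data = d))
  c(task = s[["Error: subject_id:task"]][[1]]["task", "Pr(>F)"],
    gaze = s[["Error: subject_id:gaze"]][[1]]["gaze", "Pr(>F)"],
    interaction = s[["Error: subject_id:task:gaze"]][[1]]["task:gaze",
                                                          "Pr(>F)"])
}

# textbook paired t
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, p = 2 * pt(-abs(tval), n - 1))
}

# brute-force sup |ECDF - fitted normal CDF| over sample points
oracle_ks_stat <- function(x) {
  n <- length(x)
  xs <- sort(x)
  Fh <- pnorm(xs, mean(x), sd(x))
  worst <- 0
  for (i in seq_len(n)) {
    worst <- max(worst, abs(i / n - Fh[i]), abs(Fh[i] - (i - 1) / n))
  }
  worst
}
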