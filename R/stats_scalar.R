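# Fully within-subject two-way (task x gaze) ANOVA with subject as the random
# blocking factor. Each effect is tested against its own effect-by-subject
# interaction mean square:
#   F_task = MS_task / MS_task:subject
#   F_gaze = MS_gaze / MS_gaze:subject
#   F_int  = MS_task:gaze / MS_task:gaze:subject
# The sums-of-squares engine is vectorised over an arbitrary number of
# response columns so the waveform (SPM) module can reuse it node-wise.

# Y: array (n_subjects, a_tasks, b_gaze, K responses). Returns SS table and
# F/p per effect, each a length-K vector.
rm_anova_engine <- function(Y) {
  dms <- dim(Y)
  n <- dms[1]; a <- dms[2]; b <- dms[3]; K <- if (length(dms) >= 4) dms[4] else 1
  N <- n * a * b
  M <- matrix(Y, nrow = N, ncol = K)
  ii <- rep(seq_len(n), times = a * b)
  jj <- rep(rep(seq_len(a), each = n), times = b)
  kk <- rep(seq_len(b), each = n * a)

  m <- colMeans(M)
  mm <- matrix(m, nrow = 1)
  S <- rowsum(M, ii) / (a * b)
  T_ <- rowsum(M, jj) / (n * b)
  G <- rowsum(M, kk) / (n * a)
  st_id <- (ii - 1L) * a + jj
  sg_id <- (ii - 1L) * b + kk
  tg_id <- (jj - 1L) * b + kk
  ST <- rowsum(M, st_id) / b
  SG <- rowsum(M, sg_id) / a
  TG <- rowsum(M, tg_id) / n
  st_i <- (seq_len(n * a) - 1L) %/% a + 1L
  st_j <- (seq_len(n * a) - 1L) %% a + 1L
  sg_i <- (seq_len(n * b) - 1L) %/% b + 1L
  sg_k <- (seq_len(n * b) - 1L) %% b + 1L
  tg_j <- (seq_len(a * b) - 1L) %/% b + 1L
  tg_k <- (seq_len(a * b) - 1L) %% b + 1L

  css <- function(X) colSums(X^2)
  sweep1 <- function(X, v) X - rep(v, each = nrow(X))

  ss_subj <- a * b * css(sweep1(S, m))
  ss_task <- n * b * css(sweep1(T_, m))
  ss_gaze <- n * a * css(sweep1(G, m))
  ss_tg <- n * css(TG - T_[tg_j, , drop = FALSE] - G[tg_k, , drop = FALSE] +
                     rep(m, each = a * b))
  ss_st <- b * css(ST - S[st_i, , drop = FALSE] - T_[st_j, , drop = FALSE] +
                     rep(m, each = n * a))
  ss_sg <- a * css(SG - S[sg_i, , drop = FALSE] - G[sg_k, , drop = FALSE] +
                     rep(m, each = n * b))
  R <- M - ST[st_id, , drop = FALSE] - SG[sg_id, , drop = FALSE] -
    TG[tg_id, , drop = FALSE] + S[ii, , drop = FALSE] +
    T_[jj, , drop = FALSE] + G[kk, , drop = FALSE] - rep(m, each = N)
  ss_stg <- css(R)
  ss_total <- css(sweep1(M, m))

  # Effects whose sums of squares are at numerical zero are reported as
  # F = 0, p = 1 rather than 0/0 rounding noise. The threshold is the
  # cancellation-error scale of the mean subtractions (eps x value scale,
  # squared, summed), not a fraction of ss_total: for constant input
  # ss_total cancels exactly while components keep O(eps^2) residue.
  tol <- 100 * N * .Machine$double.eps^2 * colMeans(M^2) +
    .Machine$double.xmin
  f_of <- function(ss_e, df_e, ss_r, df_r) {
    F <- ifelse(ss_e <= tol & ss_r <= tol, 0,
                ifelse(ss_r <= 0, Inf, (ss_e / df_e) / (ss_r / df_r)))
    p <- ifelse(is.infinite(F), 0, pf(F, df_e, df_r, lower.tail = FALSE))
    p[F == 0] <- 1
    list(F = F, p = p)
  }
  eff <- list(
    task = c(f_of(ss_task, a - 1, ss_st, (a - 1) * (n - 1)),
             list(df_num = a - 1, df_den = (a - 1) * (n - 1),
                  ss = ss_task, ss_err = ss_st)),
    gaze = c(f_of(ss_gaze, b - 1, ss_sg, (b - 1) * (n - 1)),
             list(df_num = b - 1, df_den = (b - 1) * (n - 1),
                  ss = ss_gaze, ss_err = ss_sg)),
    interaction = c(f_of(ss_tg, (a - 1) * (b - 1), ss_stg,
                         (a - 1) * (b - 1) * (n - 1)),
                    list(df_num = (a - 1) * (b - 1),
                         df_den = (a - 1) * (b - 1) * (n - 1),
                         ss = ss_tg, ss_err = ss_stg)))
  list(effects = eff,
       ss = list(subject = ss_subj, task = ss_task, gaze = ss_gaze,
                 interaction = ss_tg, task_subject = ss_st,
                 gaze_subject = ss_sg, interaction_subject = ss_stg,
                 total = ss_total))
}

# Build the (subject x task x gaze) cell-mean array for one outcome from a
# long study table; errors on imbalance.
study_array <- function(table, outcome, value_col = "value") {
  tab <- table[table$outcome == outcome, , drop = FALSE]
  if (!nrow(tab))
    stop_ls("landstab_stats_error", "outcome '%s' not present in table", outcome)
  subs <- sort(unique(tab$subject_id))
  tasks <- intersect(landing_tasks(), unique(tab$task))
  gazes <- intersect(gaze_levels(), unique(tab$gaze))
  Y <- array(NA_real_, c(length(subs), length(tasks), length(gazes)),
             dimnames = list(subs, tasks, gazes))
  Y[cbind(match(tab$subject_id, subs), match(tab$task, tasks),
          match(tab$gaze, gazes))] <- tab[[value_col]]
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    lab <- apply(miss, 1, function(r)
      paste(subs[r[1]], tasks[r[2]], gazes[r[3]], sep = "/"))
    stop_ls("landstab_imbalance",
            "design is unbalanced; missing cell(s): %s",
            paste(lab, collapse = ", "))
  }
  dup <- duplicated(tab[c("subject_id", "task", "gaze")])
  if (any(dup))
    stop_ls("landstab_stats_error",
            "more than one row per subject/task/gaze cell; aggregate repetitions first")
  Y
}

#' Aggregate repetitions into a study table
#'
#' Each subject x task x gaze cell value is the arithmetic mean of that
#' cell's available repetitions (designs with 2-3 successful landings per
#' cell are expected). The result feeds both the scalar ANOVA and the
#' waveform SPM layers; an empty cell is an error (no imputation).
#'
#' @param trials Long tibble with columns `subject_id`, `task`, `gaze`,
#'   `repetition`, `outcome`, `value` - one row per trial-level outcome.
#' @return Tibble `subject_id, task, gaze, outcome, value, n_reps`.
#' @export
aggregate_reps <- function(trials) {
  need <- c("subject_id", "task", "gaze", "repetition", "outcome", "value")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop_ls("landstab_stats_error", "trials table missing column(s): %s",
            paste(missing, collapse = ", "))
  out <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject_id, .data$task, .data$gaze,
                    .data$outcome),
    value = mean(.data$value), n_reps = dplyr::n(), .groups = "drop")
  for (oc in unique(out$outcome)) study_array(out, oc) # imbalance check
  out
}

#' Two-way fully within-subject ANOVA
#'
#' Task x gaze repeated-measures ANOVA with subject as random blocking
#' factor; each effect is tested against its own effect-by-subject
#' interaction (see the package vignette for the sums-of-squares
#' decomposition). No sphericity correction is applied by default;
#' `gg_correction = TRUE` applies Greenhouse-Geisser epsilon to the degrees
#' of freedom of each test.
#'
#' @param table Study table as returned by [aggregate_reps()] (one value per
#'   subject x task x gaze cell).
#' @param outcome Which outcome to analyse.
#' @param gg_correction Apply Greenhouse-Geisser adjustment.
#' @return Tibble with one row per effect (`task`, `gaze`, `interaction`):
#'   `F`, `df_num`, `df_den`, `p`.
#' @export
rm_anova_2way <- function(table, outcome, gg_correction = FALSE) {
  Y <- study_array(table, outcome)
  if (dim(Y)[1] < 3)
    stop_ls("landstab_stats_error", "need at least 3 subjects")
  fit <- rm_anova_engine(array(Y, c(dim(Y), 1)))
  rows <- lapply(names(fit$effects), function(e) {
    ef <- fit$effects[[e]]
    df1 <- ef$df_num; df2 <- ef$df_den; p <- ef$p
    if (gg_correction && ef$df_num > 1) {
      eps <- gg_epsilon(Y, e)
      p <- pf(ef$F, df1 * eps, df2 * eps, lower.tail = FALSE)
      if (ef$F == 0) p <- 1
      df1 <- df1 * eps; df2 <- df2 * eps
    }
    tibble(effect = e, F = ef$F, df_num = df1, df_den = df2, p = p)
  })
  dplyr::bind_rows(rows)
}

# Greenhouse-Geisser epsilon from the covariance of the subject-level
# contrast scores of the given effect.
gg_epsilon <- function(Y, effect) {
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  D <- switch(effect,
              task = apply(Y, c(1, 2), mean),
              gaze = apply(Y, c(1, 3), mean),
              interaction = {
                ce <- matrix(Y, n, a * b)
                tm <- apply(Y, c(1, 2), mean)[, rep(seq_len(a), times = b)]
                gm <- apply(Y, c(1, 3), mean)[, rep(seq_len(b), each = a)]
                sm <- rowMeans(ce)
                ce - tm - gm + sm
              })
  S <- stats::cov(D)
  k <- nrow(S)
  # Box epsilon on the double-centred covariance
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  tr <- sum(diag(Sc))
  eps <- tr^2 / ((k - 1) * sum(Sc^2))
  min(1, max(eps, 1 / (k - 1)))
}

#' Bonferroni-adjusted pairwise post hoc comparisons
#'
#' Paired t-tests on subject-level condition means for the requested effect:
#' task marginals (6 pairs), gaze marginals (1 pair) or the 8 task x gaze
#' cells (28 pairs). Adjusted p is `min(1, m * p)` with m the number of
#' pairs. Intended to be run only when the corresponding ANOVA effect is
#' significant.
#'
#' @param table Study table ([aggregate_reps()]).
#' @param outcome Outcome name.
#' @param effect `"task"`, `"gaze"` or `"interaction"`.
#' @return Tibble `level1, level2, mean_diff, t, df, p, p_adj`.
#' @export
bonferroni_posthoc <- function(table, outcome,
                               effect = c("task", "gaze", "interaction")) {
  effect <- match.arg(effect)
  Y <- study_array(table, outcome)
  n <- dim(Y)[1]
  if (n < 3)
    stop_ls("landstab_stats_error", "need at least 3 paired observations")
  mat <- switch(effect,
                task = apply(Y, c(1, 2), mean),
                gaze = apply(Y, c(1, 3), mean),
                interaction = {
                  m <- matrix(Y, n, prod(dim(Y)[2:3]))
                  colnames(m) <- as.vector(outer(dimnames(Y)[[2]],
                                                 dimnames(Y)[[3]], paste,
                                                 sep = ":"))
                  m
                })
  levels <- colnames(mat)
  pairs <- utils::combn(levels, 2)
  m_comp <- ncol(pairs)
  rows <- lapply(seq_len(m_comp), function(q) {
    x <- mat[, pairs[1, q]]; y <- mat[, pairs[2, q]]
    pt <- paired_t(x, y)
    tibble(level1 = pairs[1, q], level2 = pairs[2, q],
           mean_diff = pt$diff, t = pt$t, df = pt$df, p = pt$p,
           p_adj = min(1, m_comp * pt$p))
  })
  dplyr::bind_rows(rows)
}

# Paired t with the degenerate-sample conventions: identical samples ->
# difference 0, p = 1; zero-variance non-zero difference -> p = 0.
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(diff = 0, t = NA_real_, df = n - 1, p = 1))
    return(list(diff = mean(d), t = NA_real_, df = n - 1, p = 0))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Simple-effects slices of the task x gaze interaction
#'
#' The Figure-style reading of interaction post hocs: pairwise task
#' comparisons within each gaze direction plus the gaze comparison within
#' each task, Bonferroni-adjusted over all slices jointly.
#'
#' @inheritParams bonferroni_posthoc
#' @return Tibble `slice, level1, level2, mean_diff, t, df, p, p_adj`.
#' @export
interaction_simple_effects <- function(table, outcome) {
  Y <- study_array(table, outcome)
  tasks <- dimnames(Y)[[2]]; gazes <- dimnames(Y)[[3]]
  rows <- list()
  for (gz in gazes) {
    prs <- utils::combn(tasks, 2)
    for (q in seq_len(ncol(prs))) {
      pt <- paired_t(Y[, prs[1, q], gz], Y[, prs[2, q], gz])
      rows[[length(rows) + 1]] <- tibble(slice = paste0("gaze=", gz),
                                         level1 = prs[1, q],
                                         level2 = prs[2, q],
                                         mean_diff = pt$diff, t = pt$t,
                                         df = pt$df, p = pt$p)
    }
  }
  for (tk in tasks) {
    pt <- paired_t(Y[, tk, gazes[1]], Y[, tk, gazes[2]])
    rows[[length(rows) + 1]] <- tibble(slice = paste0("task=", tk),
                                       level1 = gazes[1], level2 = gazes[2],
                                       mean_diff = pt$diff, t = pt$t,
                                       df = pt$df, p = pt$p)
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(1, nrow(out) * out$p)
  out
}

#' Kolmogorov-Smirnov normality screen (Lilliefors-corrected)
#'
#' One-sample KS statistic of the values against a normal distribution with
#' the sample mean and SD; because the parameters are estimated, the p-value
#' is Lilliefors-corrected by seeded Monte Carlo (default 10^4 draws of the
#' same sample size, each re-estimating its own parameters).
#'
#' @param values Numeric sample, at least 5 values, non-degenerate.
#' @param n_mc Monte-Carlo draws.
#' @param seed RNG seed for the Monte-Carlo null.
#' @return List `statistic`, `p`.
#' @export
ks_normality <- function(values, n_mc = 10000, seed = 1) {
  n <- length(values)
  if (n < 5)
    stop_ls("landstab_stats_error", "need at least 5 values")
  if (sd(values) == 0)
    stop_ls("landstab_degenerate", "zero-variance sample")
  d_obs <- ks_stat_normal(values)
  d_null <- withr_rng(seed, function()
    vapply(seq_len(n_mc), function(i) ks_stat_normal(rnorm(n)), numeric(1)))
  list(statistic = d_obs, p = (1 + sum(d_null >= d_obs)) / (n_mc + 1))
}

ks_stat_normal <- function(x) {
  n <- length(x)
  xs <- sort(x)
  Fx <- pnorm(xs, mean(x), sd(x))
  i <- seq_len(n)
  max(i / n - Fx, Fx - (i - 1) / n)
}

#' Marginal gaze-condition differences
#'
#' For each outcome in a study table, the marginal means under the two gaze
#' instructions (averaged over tasks and subjects) and their difference -
#' the quantity reported when a gaze main effect is significant.
#'
#' @param table Study table ([aggregate_reps()]).
#' @return Tibble `outcome, mean_down, mean_ahead, diff_ahead_minus_down,
#'   abs_diff`.
#' @export
gaze_marginal_differences <- function(table) {
  rows <- lapply(unique(table$outcome), function(oc) {
    Y <- study_array(table, oc)
    g <- apply(Y, 3, mean)
    tibble(outcome = oc, mean_down = g[["down"]], mean_ahead = g[["ahead"]],
           diff_ahead_minus_down = g[["ahead"]] - g[["down"]],
           abs_diff = abs(g[["ahead"]] - g[["down"]]))
  })
  dplyr::bind_rows(rows)
}
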