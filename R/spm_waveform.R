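# One-dimensional statistical parametric mapping over the 30-node integrated
# EMG patterns: the same fully within-subject task x gaze ANOVA is evaluated
# at every node, and family-wise inference across nodes uses the maximum-F
# statistic under within-subject permutation (non-parametric SPM). The
# interaction permutation residualises estimated main effects first and is
# approximate (restricted permutation).

#' Build a pattern stack for one muscle
#'
#' Collects the 30-node integrated, normalised activity patterns of one
#' muscle into a (subject x task x gaze x node) array of cell means over
#' repetitions. The design must be balanced (every subject has every
#' task x gaze cell).
#'
#' @param patterns Tidy tibble with columns `subject_id`, `task`, `gaze`,
#'   `repetition`, `muscle`, `node`, `value`.
#' @param muscle Which muscle to stack.
#' @param n_nodes Number of pattern nodes (30 for 20-ms windows over
#'   -300..+300 ms).
#' @return A `pattern_stack`: array with dimnames, attribute `muscle`.
#' @export
pattern_stack <- function(patterns, muscle, n_nodes = 30) {
  pat <- patterns[patterns$muscle == muscle, , drop = FALSE]
  if (!nrow(pat))
    stop_ls("landstab_stats_error", "no patterns for muscle '%s'", muscle)
  agg <- dplyr::summarise(
    dplyr::group_by(pat, .data$subject_id, .data$task, .data$gaze, .data$node),
    value = mean(.data$value), .groups = "drop")
  subs <- sort(unique(agg$subject_id))
  tasks <- intersect(landing_tasks(), unique(agg$task))
  gazes <- intersect(gaze_levels(), unique(agg$gaze))
  Y <- array(NA_real_, c(length(subs), length(tasks), length(gazes), n_nodes),
             dimnames = list(subs, tasks, gazes, NULL))
  Y[cbind(match(agg$subject_id, subs), match(agg$task, tasks),
          match(agg$gaze, gazes), agg$node)] <- agg$value
  if (anyNA(Y))
    stop_ls("landstab_imbalance",
            "pattern stack for %s is unbalanced or has missing nodes", muscle)
  structure(Y, muscle = muscle, class = c("pattern_stack", "array"))
}

#' Node-wise F-curves for the three within-subject effects
#'
#' Applies the scalar within-subject decomposition (see [rm_anova_2way()])
#' at every node of the stack, yielding one F-curve per effect.
#'
#' @param stack A [pattern_stack()] (subject x task x gaze x node array).
#' @return List per effect (`task`, `gaze`, `interaction`): `F` (one value
#'   per node), `df_num`, `df_den`.
#' @export
pointwise_f <- function(stack) {
  dms <- dim(stack)
  if (length(dms) != 4)
    stop_ls("landstab_stats_error", "stack must be a 4-d array")
  if (dms[1] < 3)
    stop_ls("landstab_stats_error", "need at least 3 subjects")
  fit <- rm_anova_engine(unclass(stack))
  lapply(fit$effects, function(e) list(F = e$F, df_num = e$df_num,
                                       df_den = e$df_den))
}

# --- permutation machinery -------------------------------------------------

# rows of the flattened (subject, task, gaze) design, matching
# rm_anova_engine's layout (subject fastest, then task, then gaze)
design_rows <- function(n, a, b) {
  list(ii = rep(seq_len(n), times = a * b),
       jj = rep(rep(seq_len(a), each = n), times = b),
       kk = rep(seq_len(b), each = n * a))
}

# Permuted row order for one draw. flips: n x a logical (gaze); task_perms:
# list over (subject, gaze) of task orderings; cell_perms: list over subject
# of cell orderings.
permute_rows_gaze <- function(n, a, b, flips) {
  # row index of (i, j, k): i + (j-1) n + (k-1) n a
  idx <- seq_len(n * a * b)
  d <- design_rows(n, a, b)
  swap <- flips[cbind(d$ii, d$jj)]
  other <- d$ii + (d$jj - 1L) * n + ((b + 1L - d$kk) - 1L) * n * a
  ifelse(swap, other, idx)
}

permute_rows_task <- function(n, a, b, perms) {
  # perms: array n x b x a giving, for subject i and gaze k, the source task
  # for each target task slot
  d <- design_rows(n, a, b)
  src_task <- perms[cbind(d$ii, d$kk, d$jj)]
  d$ii + (src_task - 1L) * n + (d$kk - 1L) * n * a
}

permute_rows_cells <- function(n, a, b, perms) {
  # perms: matrix n x (a*b); source cell for each target cell, per subject
  d <- design_rows(n, a, b)
  cell <- (d$kk - 1L) * a + d$jj
  src <- perms[cbind(d$ii, cell)]
  src_j <- (src - 1L) %% a + 1L
  src_k <- (src - 1L) %/% a + 1L
  d$ii + (src_j - 1L) * n + (src_k - 1L) * n * a
}

# M is flattened in engine layout (subject fastest, then task, then gaze),
# so restoring the 4-d dims is a plain reshape
max_f_for <- function(M, n, a, b, K, effect) {
  fit <- rm_anova_engine(array(M, c(n, a, b, K)))
  max(fit$effects[[effect]]$F)
}

# residualise group-level main effects (task, gaze), keeping interaction +
# subject + error structure; used by the approximate interaction permutation
residualise_main <- function(M, n, a, b) {
  d <- design_rows(n, a, b)
  m <- colMeans(M)
  T_ <- rowsum(M, d$jj) / (n * b)
  G <- rowsum(M, d$kk) / (n * a)
  M - T_[d$jj, , drop = FALSE] - G[d$kk, , drop = FALSE] +
    rep(m, each = nrow(M))
}

#' Permutation threshold for the max-F statistic
#'
#' Estimates the family-wise critical value F* for one effect by
#' within-subject permutation: gaze labels are flipped per (subject, task);
#' task labels are permuted per (subject, gaze); for the interaction the
#' estimated main effects are subtracted first and whole cells are permuted
#' within subject (approximate restricted permutation). For every draw the
#' maximum of the effect's F-curve over nodes is recorded; F* is the
#' (1 - alpha) quantile of that null sample, so any observed node above F*
#' is significant at family-wise level alpha.
#'
#' @param stack A [pattern_stack()].
#' @param effect `"task"`, `"gaze"` or `"interaction"`.
#' @param n_perm Number of Monte-Carlo permutations (>= 100).
#' @param seed RNG seed.
#' @param alpha Family-wise significance level.
#' @param exact Enumerate all permutations instead of sampling (gaze effect
#'   only; feasible when `2^(n_subjects * n_tasks)` is small).
#' @return List `f_star`, `null_max_f`, `n_perm`, `effect`, `alpha`.
#' @export
permutation_threshold <- function(stack, effect = c("task", "gaze",
                                                    "interaction"),
                                  n_perm = 1000, seed = 1, alpha = 0.05,
                                  exact = FALSE) {
  effect <- match.arg(effect)
  dms <- dim(stack)
  n <- dms[1]; a <- dms[2]; b <- dms[3]; K <- dms[4]
  if (alpha <= 0 || alpha > 1)
    stop_ls("landstab_invalid_config", "alpha must be in (0, 1]")
  n_distinct <- switch(effect,
                       gaze = 2^(n * a),
                       task = factorial(a)^(n * b),
                       interaction = factorial(a * b)^n)
  if (n_distinct < 1 / alpha)
    stop_ls("landstab_stats_error",
            paste0("only %g distinct permutations exist (< 1/alpha); ",
                   "use exact enumeration at a larger alpha"), n_distinct)
  M <- matrix(unclass(stack), nrow = n * a * b, ncol = K)
  if (effect == "interaction") M <- residualise_main(M, n, a, b)

  if (exact) {
    if (effect != "gaze")
      stop_ls("landstab_stats_error",
              "exact enumeration is implemented for the gaze effect only")
    n_bits <- n * a
    if (n_bits > 20)
      stop_ls("landstab_stats_error",
              "exact enumeration infeasible for %d flip bits", n_bits)
    combos <- 2^n_bits
    null_max <- vapply(seq_len(combos) - 1L, function(code) {
      flips <- matrix(bitwAnd(code %/% 2^(seq_len(n_bits) - 1L), 1L) == 1L,
                      n, a)
      idx <- permute_rows_gaze(n, a, b, flips)
      max_f_for(M[idx, , drop = FALSE], n, a, b, K, effect)
    }, numeric(1))
  } else {
    if (n_perm < 100)
      stop_ls("landstab_stats_error", "n_perm must be at least 100")
    null_max <- withr_rng(seed, function() {
      vapply(seq_len(n_perm), function(p) {
        idx <- switch(effect,
                      gaze = permute_rows_gaze(
                        n, a, b, matrix(runif(n * a) < 0.5, n, a)),
                      task = {
                        perms <- array(0L, c(n, b, a))
                        for (i in seq_len(n)) for (k in seq_len(b))
                          perms[i, k, ] <- sample.int(a)
                        permute_rows_task(n, a, b, perms)
                      },
                      interaction = {
                        perms <- t(vapply(seq_len(n),
                                          function(i) sample.int(a * b),
                                          integer(a * b)))
                        permute_rows_cells(n, a, b, perms)
                      })
        max_f_for(M[idx, , drop = FALSE], n, a, b, K, effect)
      }, numeric(1))
    })
  }
  sorted <- sort(null_max)
  f_star <- if (alpha >= 1) -Inf else
    sorted[ceiling((1 - alpha) * length(sorted))]
  list(f_star = f_star, null_max_f = null_max, n_perm = length(null_max),
       effect = effect, alpha = alpha)
}

#' Waveform SPM inference
#'
#' Runs [pointwise_f()] and [permutation_threshold()] for each requested
#' effect and extracts supra-threshold clusters: maximal runs of consecutive
#' nodes with F above F*. Each cluster's p-value is the proportion of the
#' permutation null whose max-F reaches the cluster's peak F.
#'
#' @param stack A [pattern_stack()].
#' @param effects Effects to test.
#' @param n_perm Permutations per effect.
#' @param seed Master seed (one derived seed per effect).
#' @param alpha Family-wise level.
#' @return List per effect: `F` (curve), `df_num`, `df_den`, `f_star`,
#'   `clusters` (tibble `node_start, node_end, max_F, p`), `alpha`,
#'   `n_perm`; attribute `muscle` carried over.
#' @export
spm_infer <- function(stack, effects = c("task", "gaze", "interaction"),
                      n_perm = 1000, seed = 1, alpha = 0.05) {
  curves <- pointwise_f(stack)
  out <- list()
  for (e in effects) {
    thr <- permutation_threshold(stack, e, n_perm = n_perm,
                                 seed = seed + match(e, c("task", "gaze",
                                                          "interaction")),
                                 alpha = alpha)
    Fv <- curves[[e]]$F
    supra <- if (alpha >= 1) rep(TRUE, length(Fv)) else Fv > thr$f_star
    cl <- cluster_runs(supra)
    clusters <- if (nrow(cl)) {
      cl$max_F <- vapply(seq_len(nrow(cl)), function(q)
        max(Fv[cl$node_start[q]:cl$node_end[q]]), numeric(1))
      cl$p <- vapply(cl$max_F, function(fm)
        (1 + sum(thr$null_max_f >= fm)) / (thr$n_perm + 1), numeric(1))
      cl
    } else {
      tibble(node_start = integer(), node_end = integer(),
             max_F = numeric(), p = numeric())
    }
    out[[e]] <- list(F = Fv, df_num = curves[[e]]$df_num,
                     df_den = curves[[e]]$df_den, f_star = thr$f_star,
                     clusters = clusters, alpha = alpha, n_perm = thr$n_perm)
  }
  attr(out, "muscle") <- attr(stack, "muscle")
  out
}

cluster_runs <- function(supra) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(node_start = as.integer(starts[r$values]),
         node_end = as.integer(ends[r$values]))
}

#' Plot SPM F-curves
#'
#' Base-graphics view of one effect's F-curve with the permutation threshold
#' and the contact boundary between nodes 15 and 16.
#'
#' @param spm A [spm_infer()] result.
#' @param effect Which effect to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_spm <- function(spm, effect = "task", ...) {
  res <- spm[[effect]]
  graphics::plot(seq_along(res$F), res$F, type = "l", xlab = "node",
                 ylab = "F", main = sprintf("%s effect (%s)", effect,
                                            attr(spm, "muscle") %||% ""), ...)
  graphics::abline(h = res$f_star, lty = 2, col = "darkgreen")
  graphics::abline(v = 15.5, lty = 3, col = "purple")
  invisible(spm)
}
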