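test_that("repetition aggregation averages cells and flags holes", {
  trials <- expand.grid(subject_id = c("S01", "S02", "S03"),
                        task = landing_tasks(), gaze = gaze_levels(),
                        repetition = 1:2, stringsAsFactors = FALSE)
  trials$outcome <- "y"
  trials$value <- 1
  trials$value[trials$subject_id == "S01" & trials$task == "DL" &
                 trials$gaze == "down"] <- c(0.10, 0.12)
  tab <- aggregate_reps(trials)
  expect_equal(tab$value[tab$subject_id == "S01" & tab$task == "DL" &
                           tab$gaze == "down"], 0.11)
  # three reps equal brute-force sum / 3
  t3 <- trials[trials$repetition == 1, ]
  t3 <- rbind(t3, transform(t3, repetition = 2), transform(t3, repetition = 3))
  set.seed(2)
  t3$value <- rnorm(nrow(t3))
  tab3 <- aggregate_reps(t3)
  one <- t3[t3$subject_id == "S02" & t3$task == "SF" & t3$gaze == "ahead", ]
  expect_equal(tab3$value[tab3$subject_id == "S02" & tab3$task == "SF" &
                            tab3$gaze == "ahead"],
               (one$value[1] + one$value[2] + one$value[3]) / 3)
  # a missing cell is an error naming the cell
  holes <- trials[!(trials$subject_id == "S02" & trials$task == "SB" &
                      trials$gaze == "ahead"), ]
  err <- expect_error(aggregate_reps(holes), class = "landstab_imbalance")
  expect_match(conditionMessage(err), "S02/SB/ahead")
})

test_that("within-subject ANOVA matches the general-linear-model reference", {
  for (seed in c(11, 12, 13, 14, 15)) {
    tab <- random_table(8, seed)
    got <- rm_anova_2way(tab, "y")
    expect_equal(stats::setNames(got$F, got$effect), oracle_aov(tab),
                 tolerance = 1e-10)
    expect_equal(stats::setNames(got$p, got$effect), oracle_aov_p(tab),
                 tolerance = 1e-10)
  }
  expect_equal(rm_anova_2way(random_table(18, 1), "y")$df_den, c(51, 17, 51))
})

test_that("degenerate and unbalanced inputs follow the stated conventions", {
  tab <- random_table(6, 3)
  tab$value <- 4.2
  got <- rm_anova_2way(tab, "y")
  expect_equal(got$F, c(0, 0, 0))
  expect_equal(got$p, c(1, 1, 1))
  expect_error(rm_anova_2way(tab[-5, ], "y"), class = "landstab_imbalance")
  expect_error(rm_anova_2way(random_table(2, 1), "y"),
               class = "landstab_stats_error")
})

test_that("sums of squares decompose the total exactly", {
  set.seed(21)
  for (i in 1:10) {
    Y <- array(rnorm(7 * 4 * 2, sd = runif(1, 0.5, 5)), c(7, 4, 2, 1))
    ss <- landstab:::rm_anova_engine(Y)$ss
    parts <- ss$subject + ss$task + ss$gaze + ss$interaction +
      ss$task_subject + ss$gaze_subject + ss$interaction_subject
    expect_lt(abs(ss$total - parts) / ss$total, 1e-9)
  }
})

test_that("Bonferroni post hocs use paired t with capped adjustment", {
  tab <- random_table(10, 31, task_shift = 0.8)
  ph <- bonferroni_posthoc(tab, "y", "task")
  expect_equal(nrow(ph), 6)
  expect_true(all(ph$p_adj >= ph$p - 1e-15))
  expect_true(all(ph$p_adj <= 1))
  expect_equal(ph$p_adj, pmin(1, 6 * ph$p))
  # textbook paired-t oracle on the task marginals
  Y <- landstab:::study_array(tab, "y")
  marg <- apply(Y, c(1, 2), mean)
  ref <- oracle_paired_t(marg[, "DL"], marg[, "SB"])
  row <- ph[ph$level1 == "DL" & ph$level2 == "SB", ]
  expect_equal(row$t, ref$t, tolerance = 1e-12)
  expect_equal(row$p, ref$p, tolerance = 1e-12)
  expect_equal(nrow(bonferroni_posthoc(tab, "y", "gaze")), 1)
  expect_equal(nrow(bonferroni_posthoc(tab, "y", "interaction")), 28)
  # identical paired samples: difference 0, p = 1
  tab0 <- tab
  tab0$value <- rep(c(1, 2, 3, 4, 5, 6, 7, 8), each = 10)[seq_len(nrow(tab0))]
  tab0$value <- 1
  ph0 <- bonferroni_posthoc(tab0, "y", "gaze")
  expect_equal(ph0$mean_diff, 0)
  expect_equal(ph0$p, 1)
  # simple-effects slices: 6 task pairs per gaze + 4 gaze contrasts
  se <- interaction_simple_effects(tab, "y")
  expect_equal(nrow(se), 16)
  expect_equal(se$p_adj, pmin(1, 16 * se$p))
})

test_that("KS statistic equals the brute-force sup over sample points", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(60, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    expect_equal(ks_normality(x, n_mc = 100, seed = 1)$statistic,
                 oracle_ks_stat(x), tolerance = 1e-14)
  }
  # cross-check against the independent Lilliefors implementation
  if (requireNamespace("nortest", quietly = TRUE)) {
    x <- rnorm(80)
    expect_equal(ks_normality(x, n_mc = 100, seed = 1)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(ks_normality(rep(1, 10)), class = "landstab_degenerate")
  expect_error(ks_normality(rnorm(4)), class = "landstab_stats_error")
})

test_that("normality screen keeps normal data and rejects exponential data", {
  set.seed(51)
  p_norm <- replicate(60, ks_normality(rnorm(200), n_mc = 800,
                                       seed = sample.int(1e6, 1))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(60, ks_normality(rexp(100), n_mc = 800,
                                      seed = sample.int(1e6, 1))$p)
  expect_gte(mean(p_exp < 0.05), 0.95)
})

test_that("a one-SD gaze shift is detected in most replicates at n = 18", {
  set.seed(71)
  hits <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    Y <- array(rnorm(18 * 4 * 2), c(18, 4, 2, 1))
    Y[, , 2, ] <- Y[, , 2, ] + 1 # gaze shift of one within-cell SD
    hits <- hits + (landstab:::rm_anova_engine(Y)$effects$gaze$p < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("gaze marginal differences summarise the study table", {
  tab <- random_table(6, 61, gaze_shift = 0.25)
  gd <- gaze_marginal_differences(tab)
  Y <- landstab:::study_array(tab, "y")
  expect_equal(gd$diff_ahead_minus_down,
               mean(Y[, , "ahead"]) - mean(Y[, , "down"]))
  expect_equal(gd$abs_diff, abs(gd$diff_ahead_minus_down))
})
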