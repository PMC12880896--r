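# Shared small fixtures. Everything is generated in code; the tiny dataset
# is built once per test session and reused read-only.

small_config <- function(seed = 42, ...) {
  sim_config(n_subjects = 2, reps_per_cell = 2, seed = seed, ...)
}

# random balanced study table for the scalar ANOVA layer
random_table <- function(n_subjects, seed, sd_noise = 1,
                         task_shift = 0, gaze_shift = 0) {
  set.seed(seed)
  tab <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                     task = landing_tasks(), gaze = gaze_levels(),
                     stringsAsFactors = FALSE)
  shift_t <- stats::setNames(c(0, 1, 2, 3) * task_shift, landing_tasks())
  tab$outcome <- "y"
  tab$value <- rnorm(nrow(tab), sd = sd_noise) + shift_t[tab$task] +
    ifelse(tab$gaze == "ahead", gaze_shift, 0)
  tab
}

# random balanced pattern tibble for one muscle
random_patterns <- function(n_subjects, seed, n_reps = 1,
                            muscle = "rectus_femoris", bump = NULL) {
  set.seed(seed)
  grid <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                      task = landing_tasks(), gaze = gaze_levels(),
                      repetition = seq_len(n_reps), node = 1:30,
                      stringsAsFactors = FALSE)
  grid$muscle <- muscle
  grid$value <- rnorm(nrow(grid))
  if (!is.null(bump)) {
    sel <- grid$node %in% bump$nodes & grid$task %in% bump$tasks
    grid$value[sel] <- grid$value[sel] + bump$size
  }
  grid
}

# one shared tiny dataset + pipeline run per session
tiny_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "landstab-tiny-run")
    cfg <- sim_config(n_subjects = 3, reps_per_cell = 2, seed = 42)
    rc <- run_config(out_dir = dir, sim = cfg, n_perm = 200,
                     n_mc_ks = 500, seed = 42, overwrite = TRUE)
    res <- run_all(rc)
    cache <<- list(dir = dir, config = rc, sim = cfg, res = res)
    cache
  }
})
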