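# Small configurations reused across tests. Amplitude 0 everywhere unless a
# test plants structure explicitly.

null_config <- function(n_units = 1, trials = 10, baseline = 20, seed = 1) {
  synth_config(
    n_units = n_units, n_datasets = 1, trials_per_condition = trials,
    baseline_hz = baseline, amplitudes = numeric(), seed = seed
  )
}

# coarse alignments keep the smaller tests fast
fast_alignments <- function(step = 20) default_alignments(step)

# trial-averaged tensor built directly from a planted ground truth with NO
# Poisson noise: the condition-mean rate evaluated on a reference schedule.
# This is the noiseless oracle for dPCA tests.
noiseless_tensor <- function(config, dataset_index = 1, step = 20,
                             rectify = FALSE) {
  gt <- build_ground_truth(config, dataset_index)
  al <- default_alignments(step)
  sched <- list(
    t_cue_on_ms = 900, t_go_ms = 2600, t_move_on_ms = 2850,
    t_reward_ms = 3455, t_end_ms = 4255
  )
  ev <- c(
    cue_onset = sched$t_cue_on_ms,
    movement_onset = sched$t_move_on_ms,
    reward = sched$t_reward_ms
  )
  grids <- purrr::map(al, ~ seq(.x$pre_ms, .x$post_ms, by = .x$step_ms))
  time_tbl <- purrr::map2_dfr(al, grids, function(a, g) {
    tibble::tibble(alignment = a$event, time_ms = g)
  })
  time_tbl$col <- seq_len(nrow(time_tbl))
  abs_t <- unlist(purrr::map2(al, grids, function(a, g) g + ev[[a$event]]))
  cond <- task_conditions()
  vals <- array(0, dim = c(config$n_units, nrow(cond), length(abs_t)))
  for (u in seq_len(config$n_units)) {
    for (ci in cond$condition_id) {
      vals[u, ci, ] <- planted_intensity(
        gt, config$baseline_hz, u, ci, sched, abs_t,
        rectify = rectify
      )
    }
  }
  structure(
    list(
      values = vals, mode = "trial_averaged", units = seq_len(config$n_units),
      conditions = cond, trials = NULL, time = time_tbl,
      kernel_sd_ms = 57, alignments = al, hemisphere = "left"
    ),
    class = "rate_tensor"
  )
}

# single-trial tensor of iid Gaussian "rates" around planted condition means
# (white measurement noise; fast stand-in for full spike simulation when a
# test only needs the linear-algebra stages)
gaussian_trial_tensor <- function(base_tensor, trials_per_condition = 6,
                                  noise_sd = 1, seed = 1) {
  d <- dim(base_tensor$values)
  n_tr <- d[2] * trials_per_condition
  cond <- base_tensor$conditions
  set.seed(seed)
  trials <- tibble::tibble(
    trial_id = seq_len(n_tr),
    condition_id = rep(cond$condition_id, each = trials_per_condition)
  ) |>
    dplyr::left_join(cond, by = "condition_id") |>
    dplyr::mutate(
      t_cue_on_ms = 900, t_go_ms = 2600, t_move_on_ms = 2850,
      t_reward_ms = 3455, t_end_ms = 4255
    )
  vals <- array(0, dim = c(d[1], n_tr, d[3]))
  for (i in seq_len(n_tr)) {
    ci <- trials$condition_id[i]
    vals[, i, ] <- base_tensor$values[, ci, ] +
      rnorm(d[1] * d[3], sd = noise_sd)
  }
  crm <- apply(vals, c(1, 2), mean)
  structure(
    list(
      values = vals, mode = "single_trial", units = base_tensor$units,
      conditions = cond, trials = trials, time = base_tensor$time,
      cue_reward_mean = crm,
      kernel_sd_ms = base_tensor$kernel_sd_ms,
      alignments = base_tensor$alignments, hemisphere = "left"
    ),
    class = "rate_tensor"
  )
}
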