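test_that("the factorial grid has exactly 20 distinct conditions", {
  cond <- task_conditions()
  expect_equal(nrow(cond), 20)
  expect_equal(nrow(dplyr::distinct(cond[, c("hand", "grip", "orientation")])), 20)
  expect_setequal(unique(cond$orientation), c(-50, -25, 0, 25, 50))
})

test_that("config validation rejects degenerate setups", {
  expect_error(synth_config(n_units = 0), "n_units")
  expect_error(synth_config(trials_per_condition = 4), "trials_per_condition")
  expect_error(synth_config(amplitudes = c(hand = -1)), ">= 0")
  expect_error(synth_config(amplitudes = c(wiggle = 1)), "Unknown")
})

test_that("ground truth covers all seven marginalization tags deterministically", {
  cfg <- synth_config(n_units = 4, seed = 3)
  gt1 <- build_ground_truth(cfg, 1)
  gt2 <- build_ground_truth(cfg, 1)
  expect_identical(gt1, gt2)
  expect_setequal(
    vapply(gt1, `[[`, character(1), "tag"),
    c(
      "condition_independent", "hand", "grip", "orientation",
      "hand:grip", "hand:orientation", "grip:orientation"
    )
  )
})

test_that("planted weights respect their marginalization tag", {
  cfg <- synth_config(n_units = 2, amplitudes = c(grip = 4), seed = 1)
  gt <- build_ground_truth(cfg, 1)
  grip_comp <- gt[[which(vapply(gt, `[[`, character(1), "tag") == "grip")]]
  cond <- task_conditions()
  # identical across the 2 x 5 hand-orientation cells within each grip
  for (g in c("power", "precision")) {
    expect_length(unique(grip_comp$weights[cond$grip == g]), 1)
  }
  # mirror interaction: value(left, theta) == value(right, -theta) exactly
  mirror <- gt[[which(vapply(gt, `[[`, character(1), "tag") == "hand:orientation")]]
  for (th in c(-50, -25, 0, 25, 50)) {
    wl <- mirror$weights[cond$hand == "left" & cond$orientation == th]
    wr <- mirror$weights[cond$hand == "right" & cond$orientation == -th]
    expect_equal(unique(wl), unique(wr))
  }
})

test_that("zero amplitudes give the constant baseline intensity", {
  cfg <- null_config(n_units = 2, baseline = 15)
  gt <- build_ground_truth(cfg, 1)
  sched <- sample_schedule(cfg, 1, 1)
  lam <- planted_intensity(gt, 15, 1, 7, sched, seq(0, 3000, by = 50))
  expect_true(all(lam == 15))
})

test_that("intensity is conserved (baseline + components) and scales linearly", {
  mk <- function(a) {
    synth_config(
      n_units = 3, amplitudes = c(hand = a, grip = 2),
      seed = 5
    )
  }
  cfg1 <- mk(2)
  cfg2 <- mk(4)
  gt1 <- build_ground_truth(cfg1, 1)
  gt2 <- build_ground_truth(cfg2, 1)
  sched <- sample_schedule(cfg1, 1, 3)
  tt <- seq(0, sched$t_end_ms, by = 25)
  manual <- rep(cfg1$baseline_hz, length(tt))
  for (cp in gt1) {
    manual <- manual + cp$amplitude * cp$loadings[2] * cp$weights[4] *
      popgrasp:::envelope_value(cp$shape, tt, sched)
  }
  expect_equal(
    planted_intensity(gt1, cfg1$baseline_hz, 2, 4, sched, tt, rectify = FALSE),
    manual
  )
  # doubling the hand amplitude doubles the left-right intensity difference
  d1 <- planted_intensity(gt1, 10, 1, 1, sched, tt, rectify = FALSE) -
    planted_intensity(gt1, 10, 1, 11, sched, tt, rectify = FALSE)
  d2 <- planted_intensity(gt2, 10, 1, 1, sched, tt, rectify = FALSE) -
    planted_intensity(gt2, 10, 1, 11, sched, tt, rectify = FALSE)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("event times are strictly increasing and epochs in range", {
  cfg <- null_config(n_units = 1, trials = 5, seed = 9)
  ds <- simulate_dataset(cfg, 1)
  tr <- ds$trials
  expect_true(all(tr$t_cue_on_ms >= 700 & tr$t_cue_on_ms <= 1100))
  expect_true(all(tr$t_go_ms - tr$t_cue_on_ms - 800 >= 700))
  expect_true(all(tr$t_go_ms - tr$t_cue_on_ms - 800 <= 1100))
  expect_true(all(tr$t_cue_on_ms < tr$t_go_ms))
  expect_true(all(tr$t_go_ms < tr$t_move_on_ms))
  expect_true(all(tr$t_move_on_ms < tr$t_reward_ms))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- synth_config(
    n_units = 2, trials_per_condition = 5,
    amplitudes = c(hand = 3), seed = 17
  )
  expect_identical(simulate_dataset(cfg, 1), simulate_dataset(cfg, 1))
})

test_that("null spiking matches the homogeneous Poisson rate oracle", {
  cfg <- null_config(n_units = 1, trials = 5, baseline = 20, seed = 2)
  ds <- simulate_dataset(cfg, 1)
  total_s <- sum(ds$trials$t_end_ms) / 1000
  se <- sqrt(20 / total_s)
  expect_lt(abs(nrow(ds$spikes) / total_s - 20), 3 * se)
})

test_that("the artifact component is confined to its dataset", {
  cfg <- synth_config(
    n_units = 6, n_datasets = 2, trials_per_condition = 10,
    baseline_hz = 20, amplitudes = numeric(),
    artifact = list(dataset = 1, amplitude = 10), seed = 4
  )
  gt1 <- build_ground_truth(cfg, 1)
  gt2 <- build_ground_truth(cfg, 2)
  expect_true(any(vapply(gt1, `[[`, logical(1), "artifact")))
  expect_false(any(vapply(gt2, `[[`, logical(1), "artifact")))
  # dataset 2's left-right rate difference in the cue window is within noise
  ds2 <- simulate_dataset(cfg, 2)
  cue_count <- ds2$spikes |>
    dplyr::left_join(ds2$trials, by = "trial_id") |>
    dplyr::filter(
      .data$spike_time_ms >= .data$t_cue_on_ms,
      .data$spike_time_ms < .data$t_go_ms
    ) |>
    dplyr::count(.data$hand)
  secs <- ds2$trials |>
    dplyr::group_by(.data$hand) |>
    dplyr::summarise(s = sum(.data$t_go_ms - .data$t_cue_on_ms) / 1000)
  rates <- cue_count$n / secs$s[match(cue_count$hand, secs$hand)] / cfg$n_units
  se <- sqrt(sum(20 / (cfg$n_units * secs$s)))
  expect_lt(abs(diff(rates)), 3 * se)
})

test_that("condition-averaged empirical rates recover planted profiles", {
  cfg <- synth_config(
    n_units = 3, n_datasets = 1, trials_per_condition = 20,
    baseline_hz = 30, amplitudes = c(hand = 25, orientation = 25),
    loading_sd = 1, seed = 8
  )
  ds <- simulate_dataset(cfg, 1)
  tens <- build_rate_tensor(ds, fast_alignments(), mode = "trial_averaged")
  gt <- ds$ground_truth
  ev_col <- c(
    cue_onset = "t_cue_on_ms", movement_onset = "t_move_on_ms",
    reward = "t_reward_ms"
  )
  n_time <- nrow(tens$time)
  n_tr <- nrow(ds$trials)
  planted_vals <- array(0, dim = c(3, n_tr, n_time))
  for (i in seq_len(n_tr)) {
    sched <- as.list(ds$trials[i, ])
    for (al in unique(tens$time$alignment)) {
      cols <- which(tens$time$alignment == al)
      tt <- tens$time$time_ms[cols] + sched[[ev_col[[al]]]]
      for (u in 1:3) {
        planted_vals[u, i, cols] <- planted_intensity(
          gt, 25, u, ds$trials$condition_id[i], sched, tt
        )
      }
    }
  }
  for (u in 1:3) {
    pm <- t(vapply(tens$conditions$condition_id, function(ci) {
      rows <- ds$trials$condition_id == ci
      colMeans(matrix(planted_vals[u, rows, ], sum(rows), n_time))
    }, numeric(n_time)))
    expect_gt(cor(as.vector(pm), as.vector(tens$values[u, , ])), 0.95)
  }
})

test_that("spike tables round-trip through delimited text", {
  cfg <- synth_config(
    n_units = 2, trials_per_condition = 5,
    amplitudes = c(grip = 3), seed = 12
  )
  ds <- simulate_dataset(cfg, 1)
  dir <- withr::local_tempdir()
  write_spike_dataset(ds, dir)
  back <- read_spike_dataset(dir)
  expect_equal(back$spikes, ds$spikes)
  expect_equal(back$trials, ds$trials, ignore_attr = TRUE)
  expect_equal(back$hemisphere, ds$hemisphere)
  expect_equal(
    purrr::map(back$ground_truth, "loadings"),
    purrr::map(ds$ground_truth, "loadings"),
    tolerance = 1e-12
  )
})
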