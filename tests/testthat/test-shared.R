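# two-dataset configuration with strong shared structure and an optional
# cue-confined hand artifact in dataset 1 only. The shared hand component is
# movement-locked so it is temporally disjoint from the cue-window artifact.
shared_cfg <- function(artifact_amp = 10, seed = 1, n_units = 14) {
  synth_config(
    n_units = n_units, n_datasets = 2, trials_per_condition = 6,
    baseline_hz = 20,
    amplitudes = c(condition_independent = 8, hand = 6, grip = 6),
    shapes = list(hand = "movement_locked"),
    artifact = if (artifact_amp > 0) list(dataset = 1, amplitude = artifact_amp),
    seed = seed
  )
}

shared_fits <- function(cfg, noise_sd = 0.5, n_comp = 6, seed = 1) {
  tens <- purrr::map(1:2, function(d) {
    base <- noiseless_tensor(cfg, dataset_index = d, step = 40)
    base$values <- base$values +
      array(
        with_seed(seed + d, rnorm(length(base$values), sd = noise_sd)),
        dim = dim(base$values)
      )
    base
  })
  pooled_tensor <- pool_datasets(tens)
  list(
    tensors = tens,
    pooled_tensor = pooled_tensor,
    pooled = fit_dpca(pooled_tensor, n_components = n_comp, lambda = 1e-7),
    per = purrr::map(tens, fit_dpca, n_components = n_comp, lambda = 1e-7)
  )
}

test_that("component correlation handles identity, sign and degeneracy", {
  set.seed(1)
  v <- rnorm(200)
  expect_equal(component_correlation(v, v), 1)
  expect_equal(abs(component_correlation(v, -v)), 1)
  z <- component_correlation(rep(1, 200), v)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(component_correlation(v, v[-1]), "length")
  # independent white-noise courses of C*T length are near-uncorrelated
  rs <- vapply(1:200, function(i) {
    set.seed(i)
    abs(component_correlation(rnorm(2000), rnorm(2000)))
  }, numeric(1))
  expect_gte(mean(rs < 0.1), 0.99)
})

test_that("identically planted structure is retained in both datasets", {
  cfg <- shared_cfg(artifact_amp = 0, seed = 2)
  f <- shared_fits(cfg, noise_sd = 0.3, seed = 5)
  sel <- select_shared(f$pooled, f$per, threshold = 0.6)
  # the dominant (high-variance) pooled components are all shared
  big <- f$pooled$components$component[f$pooled$components$var_share > 0.05]
  expect_true(all(big %in% sel$retained))
  # an impossible threshold discards everything
  sel_hi <- select_shared(f$pooled, f$per, threshold = 1 + 1e-9)
  expect_length(sel_hi$retained, 0)
  expect_setequal(
    sel_hi$discarded,
    seq_len(nrow(f$pooled$components))
  )
})

test_that("a single-dataset artifact is discarded with higher contribution there", {
  hits <- purrr::map_lgl(1:5, function(s) {
    cfg <- shared_cfg(artifact_amp = 20, seed = s, n_units = 24)
    f <- shared_fits(cfg, noise_sd = 0.3, n_comp = 8, seed = 10 + s)
    sel <- select_shared(f$pooled, f$per, threshold = 0.6)
    # find the pooled component most correlated with the planted artifact
    gt1 <- build_ground_truth(cfg, 1)
    art <- gt1[[which(vapply(gt1, `[[`, logical(1), "artifact"))]]
    sched <- list(
      t_cue_on_ms = 900, t_go_ms = 2600, t_move_on_ms = 2850,
      t_reward_ms = 3455
    )
    ev <- c(cue_onset = 900, movement_onset = 2850, reward = 3455)
    abs_t <- f$tensors[[1]]$time$time_ms + ev[f$tensors[[1]]$time$alignment]
    env <- popgrasp:::envelope_value(art$shape, abs_t, sched)
    art_ct <- as.vector(t(outer(art$weights, env)))
    rr <- abs(apply(f$pooled$timecourses, 1, cor, y = art_ct))
    art_comp <- which.max(rr)
    contrib <- dplyr::filter(sel$contributions, .data$component == art_comp)
    (art_comp %in% sel$discarded) &&
      contrib$mean_abs_weight[contrib$dataset == 1] >
        contrib$mean_abs_weight[contrib$dataset == 2]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("back-projection uses only the dataset's rows and bounds the error", {
  cfg <- shared_cfg(artifact_amp = 0, seed = 3)
  f <- shared_fits(cfg, noise_sd = 0.3, seed = 7)
  sel <- select_shared(f$pooled, f$per, threshold = 0.6)
  # retain-all reconstruction error equals the discarded variance share
  sel_all <- sel
  sel_all$retained <- seq_len(nrow(f$pooled$components))
  rec <- backproject(sel_all, f$tensors[[1]], 1)
  xm <- popgrasp:::tensor_to_matrix(f$tensors[[1]])
  xc <- xm - rowMeans(xm)
  expect_lt(sum((rec$values - xc)^2) / sum(xc^2), 0.25)
  # retain-none reconstruction is exactly zero (with a warning)
  sel_none <- sel
  sel_none$retained <- integer()
  expect_warning(rec0 <- backproject(sel_none, f$tensors[[1]], 1), "Empty")
  expect_true(all(rec0$values == 0))
})

test_that("artifact removal shrinks its window but preserves shared hand signal", {
  # the artifact is the dominant unshared component, as in the emulated
  # study, so the pooled decomposition separates it cleanly
  cfg <- shared_cfg(artifact_amp = 22, seed = 4, n_units = 40)
  f <- shared_fits(cfg, noise_sd = 0.15, n_comp = 10, seed = 9)
  sel <- select_shared(f$pooled, f$per, threshold = 0.6)
  tens1 <- f$tensors[[1]]
  xm <- popgrasp:::tensor_to_matrix(tens1)
  xc <- xm - rowMeans(xm)
  rec <- backproject(sel, tens1, 1)
  n_t <- nrow(tens1$time)
  hand_diff <- function(values) {
    popgrasp:::factor_difference(values, tens1$conditions, n_t, "hand")
  }
  d_raw <- hand_diff(xc)
  d_rec <- hand_diff(rec$values)
  # the artifact lives in the cue window; the shared hand component is
  # movement-locked, so the windows are disjoint
  art_win <- tens1$time$alignment == "cue_onset" &
    tens1$time$time_ms > 0 & tens1$time$time_ms < 800
  shrink <- 1 - sum(d_rec[, art_win]) / sum(d_raw[, art_win])
  expect_gt(shrink, 0.8)
  # the shared hand signal (movement alignment) is preserved within 10%
  keep_win <- tens1$time$alignment == "movement_onset"
  keep_ratio <- sum(d_rec[, keep_win]) / sum(d_raw[, keep_win])
  expect_gt(keep_ratio, 0.9)
})

test_that("selection is idempotent on clean shared structure", {
  cfg <- shared_cfg(artifact_amp = 12, seed = 6)
  f <- shared_fits(cfg, noise_sd = 0.3, seed = 11)
  sel <- select_shared(f$pooled, f$per, threshold = 0.6)
  recs <- purrr::map(1:2, function(d) backproject(sel, f$tensors[[d]], d))
  # rebuild tensors from the reconstructions and re-run the selection
  tens2 <- purrr::map(1:2, function(d) {
    t2 <- f$tensors[[d]]
    v <- recs[[d]]$values
    arr <- array(v, dim = c(nrow(v), nrow(t2$time), 20))
    t2$values <- aperm(arr, c(1, 3, 2))
    t2
  })
  pooled2 <- fit_dpca(pool_datasets(tens2),
    n_components = nrow(f$pooled$components), lambda = 1e-7
  )
  per2 <- purrr::map(tens2, fit_dpca,
    n_components = nrow(f$pooled$components), lambda = 1e-7
  )
  sel2 <- select_shared(pooled2, per2, threshold = 0.6)
  # every retained pooled component of round 2 matches a retained round-1
  # component (no oscillation: nothing new appears, nothing shared is lost)
  r2 <- pooled2$timecourses[sel2$retained, , drop = FALSE]
  r1 <- f$pooled$timecourses[sel$retained, , drop = FALSE]
  cc <- abs(cor(t(r2), t(r1)))
  expect_true(all(apply(cc, 1, max) > 0.8))
})

test_that("threshold re-tuning is calibrated on the baseline window", {
  cfg <- shared_cfg(artifact_amp = 0, seed = 7, n_units = 20)
  f <- shared_fits(cfg, noise_sd = 0.5, seed = 13)
  sel <- select_shared(f$pooled, f$per, threshold = 0.6)
  rec <- backproject(sel, f$tensors[[1]], 1)
  tt <- threshold_tuning(rec, factor = "hand", baseline_rate = 0.05)
  base_cols <- rec$time$alignment == "cue_onset" & rec$time$time_ms < 0
  base_frac <- mean(tt$tuned[, base_cols])
  expect_lt(abs(base_frac - 0.05), 0.03)
  # planted memory-sustained hand tuning exceeds baseline later on
  late <- rec$time$alignment == "movement_onset"
  expect_gt(mean(tt$tuned[, late]), 3 * base_frac)
  # zero reconstruction -> nothing tuned anywhere ... threshold at the
  # baseline quantile of an all-zero signal is 0, and 0 > 0 is false
  rec0 <- rec
  rec0$values[] <- 0
  tt0 <- threshold_tuning(rec0, factor = "hand", baseline_rate = 0.05)
  expect_equal(sum(tt0$tuned), 0)
  expect_error(
    threshold_tuning(rec, baseline = rep(FALSE, nrow(rec$time))),
    "baseline"
  )
})

test_that("no planted grip structure stays at baseline after back-projection", {
  cfg <- synth_config(
    n_units = 20, n_datasets = 2, trials_per_condition = 6,
    baseline_hz = 20,
    amplitudes = c(condition_independent = 8, hand = 6), # no grip term
    artifact = list(dataset = 1, amplitude = 12), seed = 8
  )
  f <- shared_fits(cfg, noise_sd = 0.5, seed = 15)
  sel <- select_shared(f$pooled, f$per, threshold = 0.6)
  rec <- backproject(sel, f$tensors[[1]], 1)
  tt <- threshold_tuning(rec, factor = "grip", baseline_rate = 0.05)
  base_cols <- rec$time$alignment == "cue_onset" & rec$time$time_ms < 0
  base_frac <- mean(tt$tuned[, base_cols])
  overall <- mean(tt$tuned[, !base_cols])
  expect_lt(abs(overall - base_frac), 0.02 + 0.02)
})
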