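test_that("pointwise t-statistic matches the pooled-variance closed form", {
  a <- cbind(c(1, 2, 3), c(1, 2, 3))
  b <- cbind(c(4, 5, 6), c(4, 5, 6))
  tt <- pointwise_tstat(a, b)
  expect_equal(tt, c(-3.674, -3.674), tolerance = 1e-3)
  # antisymmetry and the A == B case
  expect_equal(pointwise_tstat(b, a), -tt)
  expect_equal(pointwise_tstat(a, a), c(0, 0))
  # zero variance on both sides with equal means -> 0 by convention
  cons <- matrix(2, 3, 2)
  expect_equal(pointwise_tstat(cons, cons), c(0, 0))
  expect_error(pointwise_tstat(a[1, , drop = FALSE], b), "2 trials")
})

test_that("cluster extraction finds sign-homogeneous super-threshold runs", {
  df <- 10
  thr <- qt(0.975, df)
  expect_equal(nrow(extract_clusters(rep(0.5, 20), df)), 0)
  # one run of 4 samples at |t| = 3: a single cluster of mass 12
  tv <- c(0, 3, 3, 3, 3, 0)
  cl <- extract_clusters(tv, df)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$mass, 12)
  expect_equal(c(cl$start, cl$end), c(2, 5))
  # a sign flip splits the run
  cl2 <- extract_clusters(c(3, 3, -3, -3), df)
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$sign, c(1, -1))
  # an alignment boundary splits the run
  cl3 <- extract_clusters(c(3, 3, 3, 3), df, segments = c(1, 1, 2, 2))
  expect_equal(nrow(cl3), 2)
  expect_equal(cl3$mass, c(6, 6))
})

test_that("the permutation null has the configured size and degenerate limit", {
  set.seed(1)
  a <- matrix(rnorm(10 * 30), 10)
  b <- matrix(rnorm(10 * 30), 10)
  null <- permutation_null(a, b, n_perm = 200, seed = 4)
  expect_length(null, 200)
  expect_true(all(null >= 0))
  expect_identical(null, permutation_null(a, b, n_perm = 200, seed = 4))
  # identical constant trials: no variance anywhere -> all-zero null
  cons <- matrix(5, 6, 30)
  expect_equal(permutation_null(cons, cons, n_perm = 50, seed = 1), rep(0, 50))
})

test_that("the two-group test composes: planted step is found, A == B never is", {
  n_time <- 60
  step_cols <- 21:40
  gen <- function(delta, n = 10, seed) {
    set.seed(seed)
    m <- matrix(rnorm(n * n_time), n)
    m[, step_cols] <- m[, step_cols] + delta
    m
  }
  hits <- vapply(1:10, function(s) {
    a <- gen(2, seed = s)
    b <- gen(0, seed = 100 + s)
    res <- cbpt_test(a, b, n_perm = 400, seed = s)
    sig <- dplyr::filter(res$clusters, .data$significant)
    nrow(sig) > 0 && any(sig$start <= 40 & sig$end >= 21)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  a <- gen(0, seed = 77)
  res0 <- cbpt_test(a, a, n_perm = 400, seed = 3)
  expect_false(any(res0$clusters$significant))
})

test_that("preferred/non-preferred levels follow the cue-to-reward mean", {
  cfg <- null_config(n_units = 1, trials = 8, seed = 2)
  ds <- simulate_dataset(cfg, 1)
  tens <- build_rate_tensor(ds, fast_alignments(), mode = "single_trial")
  # inject known per-trial means: rate ordered by orientation, peak +25 deg
  prof <- c(`-50` = 1, `-25` = 4, `0` = 6, `25` = 9, `50` = 3)
  tens$cue_reward_mean[1, ] <- prof[as.character(tens$trials$orientation)]
  pl <- preferred_levels(tens, 1, "orientation")
  expect_equal(pl$preferred, 25)
  expect_equal(pl$non_preferred, -50)
  expect_false(pl$tie)
  # 2-level grip factor: preferred is the grip with the higher mean
  tens$cue_reward_mean[1, ] <- ifelse(tens$trials$grip == "precision", 7, 3)
  pg <- preferred_levels(tens, 1, "grip")
  expect_equal(pg$preferred, "precision")
  expect_equal(pg$non_preferred, "power")
  # a flat unit falls back to the documented tie rule and is flagged
  tens$cue_reward_mean[] <- 1
  tie <- preferred_levels(tens, 1, "orientation")
  expect_true(tie$tie)
  expect_equal(tie$preferred, -50)
  expect_equal(tie$non_preferred, -25)
})

test_that("factor tuning flags planted factors and only those", {
  cfg <- synth_config(
    n_units = 1, trials_per_condition = 10, baseline_hz = 25,
    amplitudes = c(grip = 12), loading_sd = 1, seed = 31
  )
  ds <- simulate_dataset(cfg, 1)
  tens <- build_rate_tensor(ds, fast_alignments(), mode = "single_trial")
  res <- cbpt_unit(tens, 1, n_perm = 500, seed = 9)
  sig <- dplyr::filter(res$clusters, .data$significant)
  expect_true("grip" %in% sig$factor)
  expect_true(task_related(res))
  # determinism of the full test
  res2 <- cbpt_unit(tens, 1, n_perm = 500, seed = 9)
  expect_equal(res$clusters, res2$clusters)
})

test_that("all three planted factors are detected in a strongly loading unit", {
  cfg <- synth_config(
    n_units = 8, trials_per_condition = 10, baseline_hz = 30,
    amplitudes = c(hand = 15, grip = 15, orientation = 18),
    loading_sd = 1, seed = 41
  )
  gt <- build_ground_truth(cfg, 1)
  tags <- vapply(gt, `[[`, character(1), "tag")
  strength <- do.call(pmin, purrr::map(
    gt[tags %in% c("hand", "grip", "orientation")],
    ~ abs(.x$loadings)
  ))
  u <- which.max(strength) # unit loading clearly on all three factors
  expect_gt(strength[u], 0.5)
  ds <- simulate_dataset(cfg, 1)
  tens <- build_rate_tensor(ds, fast_alignments(), mode = "single_trial")
  res <- cbpt_unit(tens, u, n_perm = 500, seed = 2)
  sig <- unique(dplyr::filter(res$clusters, .data$significant)$factor)
  expect_setequal(sig, c("hand", "grip", "orientation"))
})

test_that("tuning fractions cover the planted window and respect subsets", {
  cfg <- synth_config(
    n_units = 6, trials_per_condition = 10, baseline_hz = 25,
    amplitudes = c(hand = 15), loading_sd = 1, seed = 51
  )
  ds <- simulate_dataset(cfg, 1)
  tens <- build_rate_tensor(ds, fast_alignments(), mode = "single_trial")
  pop <- cbpt_population(tens, n_perm = 400, seed = 5)
  # units loading clearly on the planted hand component must be flagged
  strong <- abs(ds$ground_truth[[2]]$loadings) > 0.5
  expect_true(all(pop$units$task_related[strong]))
  frac <- tuning_fraction(pop, "hand")
  # the planted hand component is memory-sustained: high fraction late in
  # the cue alignment, low pre-cue
  pre <- dplyr::filter(frac, .data$alignment == "cue_onset", .data$time_ms < 0)
  late <- dplyr::filter(frac, .data$alignment == "movement_onset")
  expect_lt(mean(pre$fraction), 0.2)
  expect_gt(max(late$fraction), 0.5)
  g <- tuning_fraction(pop, "grip")
  expect_lt(mean(g$fraction), 0.1)
})

test_that("glance and tidy summarise population results", {
  cfg <- null_config(n_units = 2, trials = 5, seed = 13)
  ds <- simulate_dataset(cfg, 1)
  tens <- build_rate_tensor(ds, fast_alignments(), mode = "single_trial")
  pop <- cbpt_population(tens, n_perm = 100, seed = 1)
  gl <- glance(pop)
  expect_equal(gl$n_units, 2)
  td <- tidy(pop)
  expect_true(all(c("unit", "factor", "mass", "p_value", "significant") %in% names(td)))
})
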