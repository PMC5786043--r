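#' Stratified pseudo-trial hold-out split
#'
#' Holds out one random trial per unit and condition; the held-out trials
#' compose a test pseudo-trial per condition (units were not recorded
#' simultaneously, so single "population trials" must be assembled this
#' way). The remaining trials are averaged into the training set.
#'
#' @param tensor A single-trial `rate_tensor` with >= 2 trials per unit and
#'   condition.
#' @param seed RNG seed; the split is deterministic given it.
#' @param trial_map Optional units x trials integer matrix reassigning, per
#'   unit, which recorded trial plays the role of each trial row (used by
#'   [shuffle_null()] to shuffle trials between conditions while respecting
#'   per-condition trial counts). Default: identity.
#' @return List with `x_train`, `x_test` (units x conditions x time arrays),
#'   `x_train_mat`, `x_test_mat` (units x CT, time fastest within
#'   condition), and `held` (tibble `unit`, `condition_id`, `trial_id`).
#' @export
split_pseudotrials <- function(tensor, seed = NULL, trial_map = NULL) {
  stopifnot(inherits(tensor, "rate_tensor"), tensor$mode == "single_trial")
  d <- dim(tensor$values)
  n_units <- d[1]
  n_time <- d[3]
  cond <- tensor$conditions
  ci <- match(tensor$trials$condition_id, cond$condition_id)
  cond_rows <- purrr::map(seq_len(nrow(cond)), function(c_i) which(ci == c_i))
  short <- which(lengths(cond_rows) < 2)
  if (length(short)) {
    lab <- cond[short[1], ]
    abort(sprintf(
      "Condition %s/%s/%+d deg has fewer than 2 trials.",
      lab$hand, lab$grip, lab$orientation
    ))
  }
  picks <- with_seed(seed, {
    matrix(
      unlist(purrr::map(seq_len(nrow(cond)), function(c_i) {
        n <- length(cond_rows[[c_i]])
        sample.int(n, n_units, replace = TRUE)
      })),
      nrow = n_units
    )
  })
  x_train <- array(0, dim = c(n_units, nrow(cond), n_time))
  x_test <- array(0, dim = c(n_units, nrow(cond), n_time))
  held <- matrix(0L, n_units, nrow(cond))
  for (u in seq_len(n_units)) {
    rows_u <- if (is.null(trial_map)) seq_len(nrow(tensor$trials)) else trial_map[u, ]
    for (c_i in seq_len(nrow(cond))) {
      rr <- rows_u[cond_rows[[c_i]]]
      out_i <- picks[u, c_i]
      x_test[u, c_i, ] <- tensor$values[u, rr[out_i], ]
      m <- tensor$values[u, rr[-out_i], , drop = FALSE]
      dim(m) <- dim(m)[2:3]
      x_train[u, c_i, ] <- colMeans(m)
      held[u, c_i] <- rr[out_i]
    }
  }
  to_mat <- function(a) {
    m <- aperm(a, c(1, 3, 2))
    dim(m) <- c(n_units, n_time * nrow(cond))
    m
  }
  list(
    x_train = x_train, x_test = x_test,
    x_train_mat = to_mat(x_train), x_test_mat = to_mat(x_test),
    held = tibble::tibble(
      unit = rep(tensor$units, times = nrow(cond)),
      condition_id = rep(cond$condition_id, each = n_units),
      trial_id = as.vector(tensor$trials$trial_id[held])
    )
  )
}

factor_class_labels <- function(conditions, factor) {
  if (grepl(":", factor)) {
    parts <- strsplit(factor, ":", fixed = TRUE)[[1]]
    interaction(conditions[parts], drop = TRUE, lex.order = TRUE)
  } else {
    base::factor(conditions[[factor]])
  }
}

#' Nearest-class-mean classification along one component axis
#'
#' Projects a test pseudo-trial onto a component's decoder axis and, at
#' each time point, predicts the class whose training-mean projection is
#' nearest. Distance ties go to the lowest class index.
#'
#' @param train_means Classes x time matrix of training-set mean
#'   projections.
#' @param test_projection Numeric vector (time) of the test pseudo-trial's
#'   projection on the same axis.
#' @return Integer vector of predicted class indices per time point.
#' @export
classify_on_component <- function(train_means, test_projection) {
  d <- abs(sweep(train_means, 2, test_projection, "-"))
  max.col(t(-d), ties.method = "first")
}

decode_once <- function(tensor, factor, lambda, n_components, seed, trial_map = NULL) {
  sp <- split_pseudotrials(tensor, seed = seed, trial_map = trial_map)
  mu_units <- rowMeans(sp$x_train_mat)
  xtr <- sp$x_train_mat - mu_units
  xte <- sp$x_test_mat - mu_units
  marg <- marginalize_matrix(xtr, tensor)
  fit <- fit_dpca(
    marg,
    n_components = min(n_components, nrow(xtr)), lambda = lambda
  )
  krow <- which(fit$components$marginalization == factor)[1]
  if (is.na(krow)) {
    fit <- fit_dpca(marg, n_components = 1, lambda = lambda, tags = factor)
    krow <- 1L
  }
  axis <- fit$decoder[krow, , drop = FALSE]
  n_time <- tensor_ntime(tensor)
  n_cond <- nrow(tensor$conditions)
  ytr <- matrix(axis %*% xtr, n_time, n_cond) # T x C
  yte <- matrix(axis %*% xte, n_time, n_cond)
  cls <- factor_class_labels(tensor$conditions, factor)
  lev <- levels(cls)
  means <- t(vapply(lev, function(l) {
    rowMeans(ytr[, cls == l, drop = FALSE])
  }, numeric(n_time))) # L x T
  correct <- matrix(FALSE, n_cond, n_time)
  for (c_i in seq_len(n_cond)) {
    pred <- classify_on_component(means, yte[, c_i])
    correct[c_i, ] <- lev[pred] == as.character(cls[c_i])
  }
  colMeans(correct)
}

tensor_ntime <- function(tensor) nrow(tensor$time)

#' Decoding accuracy time-course along a factor's component axis
#'
#' Repeats, `n_iter` times: hold out one random trial per unit and
#' condition ([split_pseudotrials()]), fit dPCA on the training averages,
#' take the factor's top component as a linear classifier, and classify the
#' held-out pseudo-trials at each time point.
#'
#' @param tensor A single-trial `rate_tensor`.
#' @param factor Factor to decode (`"hand"`, `"grip"`, `"orientation"`, or
#'   a compound such as `"hand:orientation"`).
#' @param n_iter Monte-Carlo iterations (default 100).
#' @param lambda dPCA regularization.
#' @param n_components Components in each refit (default 30, capped at the
#'   unit count).
#' @param seed Master seed.
#' @return Matrix `n_iter` x time of held-out accuracies.
#' @export
decode_timecourse <- function(tensor, factor, n_iter = 100, lambda = 0,
                              n_components = 30, seed = 1) {
  t(vapply(seq_len(n_iter), function(i) {
    decode_once(tensor, factor, lambda, n_components, split_seed(seed, i))
  }, numeric(tensor_ntime(tensor))))
}

#' Shuffle-based chance distribution of decoding accuracy
#'
#' For each shuffle, every unit's trials are shuffled between conditions
#' (respecting the number of trials per condition) and the full
#' split / dPCA / classify pipeline is re-run once, giving the Monte-Carlo
#' distribution of accuracies expected by chance.
#'
#' @inheritParams decode_timecourse
#' @param n_shuffles Number of shuffles (default 100).
#' @return Matrix `n_shuffles` x time of null accuracies.
#' @export
shuffle_null <- function(tensor, factor, n_shuffles = 100, lambda = 0,
                         n_components = 30, seed = 1) {
  n_tr <- nrow(tensor$trials)
  n_units <- dim(tensor$values)[1]
  t(vapply(seq_len(n_shuffles), function(s) {
    tm <- with_seed(split_seed(seed, 7L, s), {
      t(vapply(seq_len(n_units), function(u) sample.int(n_tr, n_tr), integer(n_tr)))
    })
    decode_once(
      tensor, factor, lambda, n_components,
      seed = split_seed(seed, 8L, s), trial_map = tm
    )
  }, numeric(tensor_ntime(tensor))))
}

#' Significant decoding intervals
#'
#' Marks time samples where the real accuracy exceeds the chance level on
#' ALL iterations — i.e. the minimum real accuracy exceeds the maximum
#' shuffle-null accuracy — and keeps maximal runs (within one alignment)
#' spanning at least `min_duration_ms`.
#'
#' @param real Matrix iterations x time of real accuracies.
#' @param null Matrix shuffles x time of null accuracies.
#' @param time Time tibble (`alignment`, `time_ms`) matching the columns.
#' @param min_duration_ms Minimum contiguous duration (default 200 ms).
#' @return Tibble `start`, `end` (columns), `alignment`, `start_ms`,
#'   `end_ms`.
#' @export
significant_intervals <- function(real, null, time, min_duration_ms = 200) {
  stopifnot(ncol(real) == ncol(null), ncol(real) == nrow(time))
  exceed <- apply(real, 2, min) > apply(null, 2, max)
  seg <- as.integer(factor(time$alignment, levels = unique(time$alignment)))
  out <- purrr::map_dfr(unique(seg), function(s) {
    idx <- which(seg == s)
    r <- runs_true(exceed[idx])
    dplyr::mutate(r, start = idx[.data$start], end = idx[.data$end])
  })
  if (!nrow(out)) {
    return(tibble::tibble(
      start = integer(), end = integer(), alignment = character(),
      start_ms = numeric(), end_ms = numeric()
    ))
  }
  out <- dplyr::filter(
    out, time$time_ms[.data$end] - time$time_ms[.data$start] >= min_duration_ms
  )
  dplyr::mutate(
    out,
    alignment = time$alignment[.data$start],
    start_ms = time$time_ms[.data$start],
    end_ms = time$time_ms[.data$end]
  )
}

#' Full decoding run for one factor
#'
#' Combines [decode_timecourse()], [shuffle_null()] and
#' [significant_intervals()].
#'
#' @inheritParams decode_timecourse
#' @param n_shuffles Shuffles for the chance distribution.
#' @param min_duration_ms Minimum significant-interval duration.
#' @return A `decode_run` with `accuracy` (iterations x time), `null`
#'   (shuffles x time), `intervals`, `time`, `factor`, `chance`.
#' @export
decode_run <- function(tensor, factor, n_iter = 100, n_shuffles = 100,
                       lambda = 0, n_components = 30,
                       min_duration_ms = 200, seed = 1) {
  acc <- decode_timecourse(tensor, factor, n_iter, lambda, n_components, seed)
  null <- shuffle_null(tensor, factor, n_shuffles, lambda, n_components, seed)
  cls <- factor_class_labels(tensor$conditions, factor)
  structure(
    list(
      factor = factor, accuracy = acc, null = null,
      intervals = significant_intervals(acc, null, tensor$time, min_duration_ms),
      time = tensor$time, chance = 1 / nlevels(cls),
      n_iter = n_iter, n_shuffles = n_shuffles, seed = seed
    ),
    class = "decode_run"
  )
}

#' @export
print.decode_run <- function(x, ...) {
  cat("<decode_run>", x$factor, "-", x$n_iter, "iterations,",
    x$n_shuffles, "shuffles, chance", signif(x$chance, 3), "\n")
  cat("  mean accuracy", signif(mean(x$accuracy), 3), ";",
    nrow(x$intervals), "significant interval(s)\n")
  invisible(x)
}

#' @export
tidy.decode_run <- function(x, ...) {
  tibble::tibble(
    alignment = x$time$alignment,
    time_ms = x$time$time_ms,
    accuracy = colMeans(x$accuracy),
    accuracy_min = apply(x$accuracy, 2, min),
    null_mean = colMeans(x$null),
    null_max = apply(x$null, 2, max)
  )
}

#' @export
glance.decode_run <- function(x, ...) {
  tibble::tibble(
    factor = x$factor,
    mean_accuracy = mean(x$accuracy),
    null_mean_accuracy = mean(x$null),
    chance = x$chance,
    n_significant_intervals = nrow(x$intervals),
    n_iter = x$n_iter,
    n_shuffles = x$n_shuffles
  )
}
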