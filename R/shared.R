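#' Stack datasets into a pooled trial-averaged tensor
#'
#' Units of all datasets become rows over the shared 20-condition x time
#' column grid. All datasets must use identical alignment windows and the
#' complete condition grid.
#'
#' @param tensors List of trial-averaged `rate_tensor`s (one per dataset).
#' @return A pooled `rate_tensor` with a `unit_dataset` integer vector
#'   recording each unit's dataset of origin.
#' @export
pool_datasets <- function(tensors) {
  stopifnot(length(tensors) >= 2)
  tensors <- purrr::map(tensors, function(t) {
    if (t$mode == "single_trial") average_trials(t) else t
  })
  ref <- tensors[[1]]
  for (t in tensors[-1]) {
    if (!identical(dim(t$values)[2:3], dim(ref$values)[2:3]) ||
      !isTRUE(all.equal(t$time, ref$time)) ||
      !identical(t$conditions$condition_id, ref$conditions$condition_id)) {
      abort("All datasets must share identical condition grids and alignment windows.")
    }
  }
  vals <- do.call(abind_units, purrr::map(tensors, "values"))
  out <- ref
  out$values <- vals
  out$units <- seq_len(dim(vals)[1])
  out$unit_dataset <- rep(
    seq_along(tensors),
    vapply(tensors, function(t) dim(t$values)[1], integer(1))
  )
  out$hemisphere <- NULL
  out
}

abind_units <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Correlation between two component condition-time courses
#'
#' Pearson correlation of the concatenated condition x time vectors (length
#' C*T). A zero-variance vector has undefined correlation; it is returned as
#' 0 with attribute `degenerate = TRUE`.
#'
#' @param comp_a,comp_b Numeric vectors of equal length C*T.
#' @return Correlation in \[-1, 1\]. Component sign is arbitrary in dPCA, so
#'   comparisons should use `abs()`.
#' @export
component_correlation <- function(comp_a, comp_b) {
  if (length(comp_a) != length(comp_b)) abort("Condition-time courses differ in length.")
  if (sd(comp_a) == 0 || sd(comp_b) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cor(comp_a, comp_b)
}

#' Select pooled components shared by every dataset
#'
#' A pooled dPCA component is retained iff, in EVERY dataset, its
#' condition-time course has absolute correlation of at least `threshold`
#' with at least one component of the dPCA fitted to that dataset alone.
#' Everything else is discarded. Contribution scores (mean absolute decoder
#' weight per unit, per dataset) identify which dataset drives each
#' discarded component.
#'
#' @param pooled A `dpca_fit` on the pooled tensor ([pool_datasets()]).
#' @param per_dataset List (>= 2) of `dpca_fit`s, one per dataset, on the
#'   same condition grid and time axis.
#' @param threshold Correlation threshold (default 0.6).
#' @return A `shared_selection`: `retained`, `discarded` (component
#'   indices), `correlations` tibble (`component`, `dataset`, `best_abs_r`),
#'   `contributions` tibble, and the inputs.
#' @export
select_shared <- function(pooled, per_dataset, threshold = 0.6) {
  stopifnot(inherits(pooled, "dpca_fit"))
  if (length(per_dataset) < 2) abort("Need >= 2 per-dataset fits.")
  if (is.null(pooled$unit_dataset)) {
    abort("Pooled fit lacks `unit_dataset`; fit it on a pool_datasets() tensor.")
  }
  for (f in per_dataset) {
    if (ncol(f$timecourses) != ncol(pooled$timecourses)) {
      abort("Pooled and per-dataset condition grids / time axes mismatch.")
    }
  }
  k <- nrow(pooled$components)
  best <- purrr::imap_dfr(per_dataset, function(fit, d) {
    r <- abs(cor(t(pooled$timecourses), t(fit$timecourses)))
    r[is.na(r)] <- 0
    tibble::tibble(
      component = seq_len(k),
      dataset = d,
      best_abs_r = apply(r, 1, max)
    )
  })
  ok <- best |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(keep = all(.data$best_abs_r >= threshold))
  retained <- ok$component[ok$keep]
  discarded <- setdiff(seq_len(k), retained)
  contributions <- purrr::map_dfr(seq_len(k), function(kk) {
    w <- abs(pooled$decoder[kk, ])
    tibble::tibble(
      component = kk,
      dataset = sort(unique(pooled$unit_dataset)),
      mean_abs_weight = vapply(
        sort(unique(pooled$unit_dataset)),
        function(d) mean(w[pooled$unit_dataset == d]),
        numeric(1)
      )
    )
  })
  structure(
    list(
      retained = retained, discarded = discarded,
      correlations = best, contributions = contributions,
      pooled = pooled, per_dataset = per_dataset, threshold = threshold
    ),
    class = "shared_selection"
  )
}

#' @export
print.shared_selection <- function(x, ...) {
  cat("<shared_selection>", length(x$retained), "retained /",
    length(x$discarded), "discarded (|r| >=", x$threshold, "in every dataset)\n")
  invisible(x)
}

#' @export
tidy.shared_selection <- function(x, ...) {
  dplyr::mutate(
    x$correlations,
    retained = .data$component %in% x$retained
  )
}

#' @export
glance.shared_selection <- function(x, ...) {
  disc_share <- sum(x$pooled$components$var_share[x$discarded])
  tibble::tibble(
    n_components = nrow(x$pooled$components),
    n_retained = length(x$retained),
    n_discarded = length(x$discarded),
    discarded_var_share = disc_share,
    threshold = x$threshold
  )
}

#' Back-project retained components to one dataset's units
#'
#' Reconstructs the denoised per-unit signals of dataset `dataset_index`
#' using only that dataset's rows of the pooled encoder and decoder:
#' `X_hat = F_d[, retained] (D[retained, d] X_d)`. The projection and the
#' reconstruction both use only data recorded in that dataset, so the
#' procedure cannot fabricate structure that is not present there.
#'
#' @param selection A `shared_selection`.
#' @param tensor The dataset's own trial-averaged `rate_tensor`.
#' @param dataset_index Which dataset (index into the pooled stack).
#' @param gain_correction Restricting the pooled encoder/decoder pair to one
#'   dataset's rows scales each component down by roughly that dataset's
#'   variance share. With `gain_correction = TRUE` (default) the scores are
#'   corrected by `(D_d F_d)^-1`, making the reconstruction an oblique
#'   projection that preserves the amplitude of shared components while the
#'   decoder still suppresses unshared directions; `FALSE` gives the plain
#'   composition `F_d D_d X_d`.
#' @return A `reconstruction`: `values` (units x CT matrix, per-unit
#'   centered), plus condition/time metadata.
#' @export
backproject <- function(selection, tensor, dataset_index,
                        gain_correction = TRUE) {
  stopifnot(inherits(selection, "shared_selection"))
  pooled <- selection$pooled
  rows <- which(pooled$unit_dataset == dataset_index)
  if (!length(rows)) abort("No units for that dataset in the pooled fit.")
  if (tensor$mode == "single_trial") tensor <- average_trials(tensor)
  xm <- tensor_to_matrix(tensor)
  if (nrow(xm) != length(rows)) {
    abort("Tensor unit count does not match the pooled fit's dataset rows.")
  }
  xc <- xm - rowMeans(xm)
  keep <- selection$retained
  if (!length(keep)) {
    warn("Empty retained set: reconstruction is identically zero.")
    xhat <- matrix(0, nrow(xc), ncol(xc))
  } else {
    f <- pooled$encoder[rows, keep, drop = FALSE]
    d <- pooled$decoder[keep, rows, drop = FALSE]
    scores <- d %*% xc
    if (gain_correction) {
      g <- d %*% f
      scores <- tryCatch(solve(g, scores), error = function(e) {
        warn("Gain matrix is singular; falling back to the plain composition.")
        scores
      })
    }
    xhat <- f %*% scores
  }
  structure(
    list(
      values = xhat, units = tensor$units,
      conditions = tensor$conditions, time = tensor$time,
      n_time = nrow(tensor$time), dataset_index = dataset_index,
      retained = keep
    ),
    class = "reconstruction"
  )
}

# between-level difference of the condition-mean reconstructed signal,
# units x T. 2-level factors: mean(level1) - mean(level2) (signed unless
# `signed = FALSE`); orientation: range over the five orientation means
# (always non-negative).
factor_difference <- function(values, conditions, n_time, factor, signed = FALSE) {
  u <- nrow(values)
  arr <- values
  dim(arr) <- c(u, n_time, nrow(conditions))
  labs <- conditions[[factor]]
  lev <- sort(unique(labs))
  means <- purrr::map(lev, function(l) {
    m <- arr[, , labs == l, drop = FALSE]
    apply(m, c(1, 2), mean)
  })
  if (length(lev) == 2) {
    d <- means[[1]] - means[[2]]
    if (signed) d else abs(d)
  } else {
    mx <- Reduce(pmax, means)
    mn <- Reduce(pmin, means)
    mx - mn
  }
}

#' Threshold-based re-tuning of reconstructed signals
#'
#' Tests each unit's reconstructed signal for factor tuning with a simple
#' threshold on the between-level condition-mean difference, calibrated on
#' the pre-cue baseline window so that the baseline tuned-fraction equals
#' `baseline_rate` (matched to the baseline level of tuning of the
#' cluster-based test on the same data).
#'
#' Two calibrations are available. `"quantile"` (default): the empirical
#' `1 - baseline_rate` quantile of the pooled absolute baseline
#' differences. `"gaussian"` (2-level factors): a per-unit
#' prediction-interval threshold
#' `qt(1 - rate/2, n_b - 1) * sd * sqrt(1 + 1/n_b)` on the
#' baseline-centered signed difference — exactly calibrated under a
#' Gaussian, stationary baseline, but more sensitive than the pooled
#' quantile when the reconstruction noise is modulated by the task epochs
#' (which it is, mildly: fitted components capture noise preferentially
#' where their signal lives). Multi-level factors (orientation) always use
#' the quantile calibration of the across-level range.
#'
#' @param recon A `reconstruction` (or a trial-averaged `rate_tensor`).
#' @param factor Factor to test (default `"hand"`).
#' @param baseline_rate Target tuned-fraction in the baseline window.
#' @param baseline Logical vector over time columns marking the baseline
#'   window; default pre-cue samples (`cue_onset` alignment, time < 0).
#' @param method Calibration method, see Details.
#' @return List with `threshold` (scalar or per-unit vector), `tuned`
#'   (units x time logical matrix), `fraction` tibble (`alignment`,
#'   `time_ms`, `fraction`), `baseline_rate`, `method`.
#' @export
threshold_tuning <- function(recon, factor = "hand", baseline_rate = 0.05,
                             baseline = NULL,
                             method = c("quantile", "gaussian")) {
  method <- match.arg(method)
  if (inherits(recon, "rate_tensor")) {
    if (recon$mode == "single_trial") recon <- average_trials(recon)
    recon <- structure(
      list(
        values = tensor_to_matrix(recon) - rowMeans(tensor_to_matrix(recon)),
        units = recon$units, conditions = recon$conditions,
        time = recon$time, n_time = nrow(recon$time)
      ),
      class = "reconstruction"
    )
  }
  stopifnot(inherits(recon, "reconstruction"))
  base <- baseline %||%
    (recon$time$alignment == "cue_onset" & recon$time$time_ms < 0)
  if (!any(base)) abort("Empty baseline window.")
  n_levels <- length(unique(recon$conditions[[factor]]))
  if (method == "gaussian" && n_levels == 2) {
    d <- factor_difference(
      recon$values, recon$conditions, recon$n_time, factor,
      signed = TRUE
    )
    nb <- sum(base)
    if (nb < 3) abort("Gaussian calibration needs >= 3 baseline samples.")
    mu <- rowMeans(d[, base, drop = FALSE])
    dc <- d - mu
    sdu <- apply(dc[, base, drop = FALSE], 1, sd)
    thr <- qt(1 - baseline_rate / 2, nb - 1) * sdu * sqrt(1 + 1 / nb)
    tuned <- abs(dc) > thr
  } else {
    d <- factor_difference(recon$values, recon$conditions, recon$n_time, factor)
    thr <- quantile(d[, base], 1 - baseline_rate, names = FALSE)
    tuned <- d > thr
  }
  structure(
    list(
      threshold = thr, tuned = tuned,
      fraction = dplyr::mutate(
        recon$time[, c("alignment", "time_ms")],
        fraction = colMeans(tuned)
      ),
      factor = factor, baseline_rate = baseline_rate, method = method
    ),
    class = "threshold_tuning"
  )
}
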