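dpca_tags <- function() c(marg_tags(), "hand:grip:orientation")

# averaging projectors on the 20-condition axis. Each marginalization tag
# maps to a 20 x 20 projector; the eight projectors sum to the identity, so
# the decomposition conserves the centered data exactly and the terms are
# mutually orthogonal for the balanced 2 x 2 x 5 grid.
marg_projectors <- function() {
  cond <- task_conditions()
  keep_only <- function(keep_cols) {
    # average over the factors NOT in keep_cols (cell means of keep_cols)
    if (!length(keep_cols)) {
      grp <- rep(1L, nrow(cond))
    } else {
      grp <- as.integer(interaction(cond[keep_cols], drop = TRUE))
    }
    m <- outer(grp, grp, "==") * 1
    m / rowSums(m)
  }
  a_all <- keep_only(character()) # grand mean over conditions
  a_h <- keep_only("hand")
  a_g <- keep_only("grip")
  a_o <- keep_only("orientation")
  a_hg <- keep_only(c("hand", "grip"))
  a_ho <- keep_only(c("hand", "orientation"))
  a_go <- keep_only(c("grip", "orientation"))
  p <- list(
    condition_independent = a_all,
    hand = a_h - a_all,
    grip = a_g - a_all,
    orientation = a_o - a_all,
    `hand:grip` = a_hg - a_h - a_g + a_all,
    `hand:orientation` = a_ho - a_h - a_o + a_all,
    `grip:orientation` = a_go - a_g - a_o + a_all
  )
  p$`hand:grip:orientation` <- diag(nrow(cond)) - Reduce(`+`, p)
  p
}

# units x (C*T) matrix with column index (c-1)*T + t from a trial-averaged
# tensor (time fastest within condition: "the entire time-course of all
# conditions" concatenated)
tensor_to_matrix <- function(tensor) {
  v <- aperm(tensor$values, c(1, 3, 2)) # units x T x C
  dim(v) <- c(dim(v)[1], dim(v)[2] * dim(v)[3])
  v
}

apply_projector <- function(xmat, p, n_time) {
  n_units <- nrow(xmat)
  n_cond <- ncol(p)
  arr <- xmat
  dim(arr) <- c(n_units * n_time, n_cond)
  out <- arr %*% t(p)
  dim(out) <- c(n_units, n_time * n_cond)
  out
}

#' Marginalization decomposition of a trial-averaged population tensor
#'
#' Splits the per-unit-centered data matrix `X` (units x condition-time)
#' into additive marginalizations: the condition-independent (time) term,
#' the three main factor terms, the three pairwise interactions, and the
#' three-way interaction. Each term varies only with its own factors (plus
#' time), the terms sum to the centered `X` exactly, and for the balanced
#' 2 x 2 x 5 design they are mutually orthogonal.
#'
#' @param tensor A trial-averaged `rate_tensor` over the complete
#'   20-condition grid, or a single-trial tensor (averaged first).
#' @return A `marginalization_set`: list with `X` (centered units x CT
#'   matrix), `terms` (named list of matrices of the same shape),
#'   `unit_means`, `conditions`, `time`, `n_time`.
#' @export
marginalize <- function(tensor) {
  stopifnot(inherits(tensor, "rate_tensor"))
  if (tensor$mode == "single_trial") tensor <- average_trials(tensor)
  if (nrow(tensor$conditions) != 20) {
    abort("Marginalization needs the complete 2 x 2 x 5 condition grid.")
  }
  n_time <- nrow(tensor$time)
  xmat <- tensor_to_matrix(tensor)
  unit_means <- rowMeans(xmat)
  xc <- xmat - unit_means
  projs <- marg_projectors()
  terms <- purrr::map(projs, function(p) apply_projector(xc, p, n_time))
  structure(
    list(
      X = xc, terms = terms, unit_means = unit_means,
      conditions = tensor$conditions, time = tensor$time,
      n_time = n_time, units = tensor$units,
      unit_dataset = tensor$unit_dataset %||% NULL
    ),
    class = "marginalization_set"
  )
}

#' @export
print.marginalization_set <- function(x, ...) {
  v <- vapply(x$terms, function(m) sum(m^2), numeric(1))
  cat("<marginalization_set>", nrow(x$X), "units x", ncol(x$X), "condition-time\n")
  print(round(v / sum(x$X^2), 4))
  invisible(x)
}

#' Fit demixed PCA
#'
#' For every marginalization `phi`, minimizes
#' `||X_phi - F_phi D_phi X||^2 + lambda ||F_phi D_phi||^2` over
#' rank-constrained encoder/decoder pairs: the full-rank ridge solution
#' `A_phi = X_phi X' (X X' + mu I)^-1` with `mu = lambda * ||X||^2`
#' (so the dimensionless `lambda` is comparable across datasets), followed
#' by rank truncation of `A_phi X` by singular value decomposition. The
#' encoder `F_phi` has orthonormal columns and `D_phi = F_phi' A_phi`.
#' Components from all marginalizations are pooled and the global top
#' `n_components` by explained signal variance are kept.
#'
#' @param x A trial-averaged `rate_tensor` or a [marginalize()] result.
#' @param n_components Total components to keep (default 30, as extracted
#'   per area in the emulated study).
#' @param lambda Regularization (>= 0); the study's cross-validated values
#'   were 5.1e-7 and 2.3e-7 for the two areas.
#' @param per_marg_components Components fitted per marginalization before
#'   pooling (default `n_components`).
#' @param tags Marginalizations to fit (default all eight).
#' @return A `dpca_fit` with `encoder` (units x K), `decoder` (K x units),
#'   `timecourses` (K x CT), and a `components` tibble (`component`,
#'   `marginalization`, `var`, `var_share`).
#' @export
fit_dpca <- function(x, n_components = 30, lambda = 0,
                     per_marg_components = NULL, tags = NULL) {
  marg <- if (inherits(x, "marginalization_set")) x else marginalize(x)
  if (lambda < 0) abort("`lambda` must be >= 0.")
  xc <- marg$X
  n_units <- nrow(xc)
  if (n_components > n_units) {
    abort("`n_components` cannot exceed the number of units.")
  }
  tags <- tags %||% names(marg$terms)
  bad <- setdiff(tags, names(marg$terms))
  if (length(bad)) abort(paste0("Unknown marginalization(s): ", toString(bad)))
  q <- min(per_marg_components %||% n_components, n_units, ncol(xc))
  total_var <- sum(xc^2)
  mu <- lambda * total_var
  reg <- tcrossprod(xc)
  diag(reg) <- diag(reg) + mu
  rinv <- tryCatch(solve(reg), error = function(e) {
    ev <- eigen(reg, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  })
  fits <- purrr::map(tags, function(tag) {
    a <- (marg$terms[[tag]] %*% t(xc)) %*% rinv
    z <- a %*% xc
    qq <- min(q, nrow(z), ncol(z))
    sv <- svd(z, nu = qq, nv = 0)
    f <- sv$u
    d <- crossprod(f, a)
    y <- d %*% xc
    list(
      tag = tag, encoder = f, decoder = d, timecourses = y,
      var = rowSums(y^2)
    )
  })
  pool <- purrr::map_dfr(fits, function(ft) {
    tibble::tibble(
      marginalization = ft$tag,
      rank_within = seq_along(ft$var),
      var = ft$var
    )
  })
  pool <- dplyr::arrange(pool, dplyr::desc(.data$var))
  keep <- head(pool, n_components)
  enc <- matrix(0, n_units, nrow(keep))
  dec <- matrix(0, nrow(keep), n_units)
  tc <- matrix(0, nrow(keep), ncol(xc))
  for (i in seq_len(nrow(keep))) {
    ft <- fits[[match(keep$marginalization[i], tags)]]
    enc[, i] <- ft$encoder[, keep$rank_within[i]]
    dec[i, ] <- ft$decoder[keep$rank_within[i], ]
    tc[i, ] <- ft$timecourses[keep$rank_within[i], ]
  }
  comps <- dplyr::mutate(
    keep,
    component = dplyr::row_number(), .before = 1
  )
  comps$var_share <- comps$var / total_var
  structure(
    list(
      encoder = enc, decoder = dec, timecourses = tc,
      components = comps, lambda = lambda, mu = mu,
      total_var = total_var, unit_means = marg$unit_means,
      conditions = marg$conditions, time = marg$time,
      n_time = marg$n_time, units = marg$units,
      unit_dataset = marg$unit_dataset, tags = tags
    ),
    class = "dpca_fit"
  )
}

#' @export
print.dpca_fit <- function(x, ...) {
  cat("<dpca_fit>", nrow(x$encoder), "units,", nrow(x$components),
    "components, lambda =", format(x$lambda), "\n")
  print(head(x$components, 10))
  invisible(x)
}

#' @export
tidy.dpca_fit <- function(x, ...) x$components

#' @export
glance.dpca_fit <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$encoder),
    n_components = nrow(x$components),
    lambda = x$lambda,
    total_var = x$total_var,
    var_share_captured = sum(x$components$var_share)
  )
}

#' Component time-courses in long form
#'
#' @param fit A `dpca_fit`.
#' @param components Component indices (default all).
#' @return Tibble `component`, `marginalization`, condition labels,
#'   `alignment`, `time_ms`, `score`.
#' @export
component_timecourses <- function(fit, components = NULL) {
  components <- components %||% fit$components$component
  n_t <- fit$n_time
  purrr::map_dfr(components, function(k) {
    y <- fit$timecourses[k, ]
    tibble::tibble(
      component = k,
      marginalization = fit$components$marginalization[k],
      condition_id = rep(fit$conditions$condition_id, each = n_t),
      alignment = rep(fit$time$alignment, times = nrow(fit$conditions)),
      time_ms = rep(fit$time$time_ms, times = nrow(fit$conditions)),
      score = y
    ) |>
      dplyr::left_join(
        fit$conditions, by = "condition_id"
      )
  })
}

#' Variance bookkeeping for a dPCA fit
#'
#' Cumulative variance of the joint reconstruction from the top-k dPCA
#' components, the ordinary-PCA cumulative curve at the same ranks (the
#' dPCA curve can never exceed it), and the split of total signal variance
#' across marginalizations.
#'
#' @param fit A `dpca_fit`.
#' @param x The data it was fitted to (tensor or `marginalization_set`).
#' @return A list with `cumulative` (tibble `rank`, `dpca`, `pca`) and
#'   `marginalization_shares` (tibble).
#' @export
variance_summary <- function(fit, x) {
  marg <- if (inherits(x, "marginalization_set")) x else marginalize(x)
  xc <- marg$X
  tot <- sum(xc^2)
  k <- nrow(fit$components)
  y <- fit$timecourses
  b <- crossprod(fit$encoder, xc) # K x CT
  cross <- cumsum(rowSums(b * y))
  gram <- crossprod(fit$encoder)
  yy <- tcrossprod(y)
  m <- gram * yy
  quad <- numeric(k)
  acc <- 0
  for (i in seq_len(k)) {
    acc <- acc + m[i, i] + if (i > 1) 2 * sum(m[seq_len(i - 1), i]) else 0
    quad[i] <- acc
  }
  dpca_cum <- (2 * cross - quad) / tot
  sv <- svd(xc, nu = 0, nv = 0)$d^2
  pca_cum <- cumsum(sv)[seq_len(k)] / tot
  shares <- tibble::tibble(
    marginalization = names(marg$terms),
    var_share = vapply(marg$terms, function(m) sum(m^2), numeric(1)) / tot
  )
  list(
    cumulative = tibble::tibble(rank = seq_len(k), dpca = dpca_cum, pca = pca_cum),
    marginalization_shares = shares
  )
}

#' How each component's variance splits across marginalizations
#'
#' Decomposes every component time-course with the same marginalization
#' algebra and reports the share of its variance in each term — the
#' demixing-quality diagnostic (a well-demixed component has ~all of its
#' variance in its own marginalization).
#'
#' @param fit A `dpca_fit`.
#' @return Tibble `component`, `marginalization` (of the fit), one column
#'   per marginalization tag with the variance share of the time-course.
#' @export
component_marginalization_shares <- function(fit) {
  y <- fit$timecourses
  yc <- y - rowMeans(y)
  projs <- marg_projectors()
  shares <- vapply(projs, function(p) {
    yp <- apply_projector(yc, p, fit$n_time)
    rowSums(yp^2)
  }, numeric(nrow(y)))
  if (nrow(y) == 1L) shares <- matrix(shares, nrow = 1, dimnames = list(NULL, names(projs)))
  tot <- rowSums(yc^2)
  out <- tibble::as_tibble(shares / ifelse(tot == 0, 1, tot))
  dplyr::bind_cols(
    fit$components[, c("component", "marginalization")],
    out
  )
}

#' Cross-validate the dPCA regularization strength
#'
#' Holds out one random trial per unit and condition, averages the rest into
#' a training set, fits dPCA at each candidate `lambda`, and measures the
#' reconstruction error of the held-out marginalized averages. One `lambda`
#' is chosen per dataset (area), minimizing the summed error over folds.
#'
#' @param tensor A single-trial `rate_tensor` with >= 2 trials per unit and
#'   condition.
#' @param lambdas Candidate grid (non-negative, length >= 2).
#' @param n_folds Number of random hold-out folds (default 10).
#' @param n_components,tags Passed to [fit_dpca()].
#' @param seed RNG seed.
#' @return List with `lambda` (the minimizer) and `errors` (tibble
#'   `lambda`, `error`).
#' @export
cross_validate_lambda <- function(tensor, lambdas = 10^seq(-8, -3, by = 1),
                                  n_folds = 10, n_components = 30,
                                  tags = NULL, seed = 1) {
  if (length(lambdas) < 2 || any(lambdas < 0)) {
    abort("`lambdas` must be a grid of >= 2 non-negative values.")
  }
  errs <- matrix(0, n_folds, length(lambdas))
  for (fold in seq_len(n_folds)) {
    sp <- split_pseudotrials(tensor, seed = split_seed(seed, fold))
    train_means <- rowMeans(sp$x_train_mat)
    xtr <- sp$x_train_mat - train_means
    xte <- sp$x_test_mat - train_means
    marg_tr <- marginalize_matrix(xtr, tensor)
    marg_te <- marginalize_matrix(xte, tensor)
    for (li in seq_along(lambdas)) {
      fit <- fit_dpca(
        marg_tr,
        n_components = min(n_components, nrow(xtr)),
        lambda = lambdas[li], tags = tags
      )
      tags_fit <- unique(fit$components$marginalization)
      err <- 0
      for (tg in tags_fit) {
        rows <- fit$components$marginalization == tg
        fd <- fit$encoder[, rows, drop = FALSE] %*%
          fit$decoder[rows, , drop = FALSE]
        err <- err + sum((marg_te$terms[[tg]] - fd %*% xte)^2)
      }
      errs[fold, li] <- err
    }
  }
  total <- colSums(errs)
  list(
    lambda = lambdas[which.min(total)],
    errors = tibble::tibble(lambda = lambdas, error = total)
  )
}

# marginalization_set from an already-centered units x CT matrix, reusing a
# tensor's condition/time metadata
marginalize_matrix <- function(xc, tensor_like) {
  n_time <- nrow(tensor_like$time)
  projs <- marg_projectors()
  structure(
    list(
      X = xc,
      terms = purrr::map(projs, function(p) apply_projector(xc, p, n_time)),
      unit_means = rep(0, nrow(xc)),
      conditions = if (inherits(tensor_like, "rate_tensor")) tensor_like$conditions else tensor_like$conditions,
      time = tensor_like$time, n_time = n_time,
      units = tensor_like$units, unit_dataset = NULL
    ),
    class = "marginalization_set"
  )
}
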