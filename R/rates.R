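#' Event alignment specification
#'
#' Describes one analysis alignment: the trial event to align to, the window
#' around it, and the sampling step. The three canonical alignments of the
#' delayed-grasping analysis are produced by [default_alignments()].
#'
#' @param event One of `"cue_onset"`, `"movement_onset"`, `"reward"`.
#' @param pre_ms,post_ms Window bounds relative to the event (pre < post).
#' @param step_ms Sampling step in ms (> 0).
#' @return An `alignment_spec` list.
#' @export
alignment_spec <- function(event = c("cue_onset", "movement_onset", "reward"),
                           pre_ms, post_ms, step_ms = 10) {
  event <- match.arg(event)
  if (pre_ms >= post_ms) abort("`pre_ms` must be < `post_ms`.")
  if (step_ms <= 0) abort("`step_ms` must be > 0.")
  structure(
    list(event = event, pre_ms = pre_ms, post_ms = post_ms, step_ms = step_ms),
    class = "alignment_spec"
  )
}

#' @rdname alignment_spec
#' @details Default windows: cue \[-300, +1100\] ms (covering fixation end,
#'   cue and early memory), movement \[-500, +500\] ms, reward
#'   \[-300, +500\] ms, all at 10 ms steps. The emulated study does not print
#'   its analysis windows, so these are configurable defaults.
#' @export
default_alignments <- function(step_ms = 10) {
  list(
    alignment_spec("cue_onset", -300, 1100, step_ms),
    alignment_spec("movement_onset", -500, 500, step_ms),
    alignment_spec("reward", -300, 500, step_ms)
  )
}

alignment_event_col <- function(event) {
  switch(event,
    cue_onset = "t_cue_on_ms",
    movement_onset = "t_move_on_ms",
    reward = "t_reward_ms"
  )
}

alignment_grid <- function(a) seq(a$pre_ms, a$post_ms, by = a$step_ms)

# truncation half-width and renormalization for the Gaussian kernel
kernel_halfwidth <- function(sd_ms) ceiling(4 * sd_ms)
kernel_renorm <- function() 1 - 2 * pnorm(-4)

#' Gaussian-kernel firing-rate estimate for one spike train
#'
#' Computes `rate(t) = sum_spikes k(t - t_spike)` where `k` is a Gaussian
#' density (default SD 57 ms) truncated at +/- 4 SD and renormalized, scaled
#' to Hz. An empty spike vector gives an identically-zero rate. The kernel
#' integrates to 1, so the integral of the rate over a window that fully
#' contains the kernel support equals the spike count.
#'
#' @param spike_times_ms Spike times (ms), sorted ascending.
#' @param times_ms Times (ms) at which to evaluate the rate, on the same
#'   clock as the spikes.
#' @param kernel_sd_ms Kernel standard deviation in ms.
#' @return Firing rate in Hz at `times_ms`.
#' @export
#' @examples
#' smooth_unit_rate(0, 0) # ~ 1 / (57 ms * sqrt(2*pi)) = 6.997 Hz
smooth_unit_rate <- function(spike_times_ms, times_ms, kernel_sd_ms = 57) {
  if (is.unsorted(spike_times_ms)) abort("`spike_times_ms` must be sorted ascending.")
  out <- numeric(length(times_ms))
  if (!length(spike_times_ms)) return(out)
  hw <- kernel_halfwidth(kernel_sd_ms)
  for (i in seq_along(times_ms)) {
    d <- times_ms[i] - spike_times_ms
    d <- d[abs(d) <= hw]
    if (length(d)) {
      out[i] <- sum(dnorm(d, sd = kernel_sd_ms)) * 1000 / kernel_renorm()
    }
  }
  out
}

# kernel matrix mapping 1 ms spike bins (centers at ext_start + b - 0.5) to
# the alignment grid; values in Hz per spike. Cached: the same alignment
# windows recur for every unit of a population.
.kernel_cache <- new.env(parent = emptyenv())
kernel_matrix <- function(grid, ext_start, n_bins, kernel_sd_ms) {
  key <- paste(ext_start, n_bins, kernel_sd_ms, grid[1],
    grid[length(grid)], length(grid),
    sep = "|"
  )
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  centers <- ext_start + seq_len(n_bins) - 0.5
  d <- outer(centers, grid, "-")
  k <- dnorm(d, sd = kernel_sd_ms) * 1000 / kernel_renorm()
  k[abs(d) > kernel_halfwidth(kernel_sd_ms)] <- 0
  .kernel_cache[[key]] <- k
  k
}

#' Drop units not stably recorded in every condition
#'
#' Keeps only units with at least `min_trials` recorded trials in each of the
#' 20 conditions, the stability inclusion criterion of the emulated
#' recordings. A unit's recorded trials are taken from
#' `dataset$unit_trials` (tibble `unit_id`, `trial_id`) when present,
#' otherwise every unit is assumed recorded on every trial.
#'
#' @param dataset A `spike_dataset`.
#' @param min_trials Minimum trials per condition (default 5).
#' @return The filtered `spike_dataset` (units renumbered are NOT; original
#'   `unit_ids` are kept in `unit_ids`).
#' @export
exclude_unstable <- function(dataset, min_trials = 5) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!nrow(dataset$trials) || !dataset$n_units) {
    dataset$unit_ids <- intersect(dataset$unit_ids, integer())
    return(dataset)
  }
  ut <- dataset$unit_trials %||% tidyr::expand_grid(
    unit_id = dataset$unit_ids, trial_id = dataset$trials$trial_id
  )
  counts <- ut |>
    dplyr::left_join(
      dataset$trials[, c("trial_id", "condition_id")],
      by = "trial_id"
    ) |>
    dplyr::count(.data$unit_id, .data$condition_id)
  n_cond <- length(unique(dataset$trials$condition_id))
  keep <- counts |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      ok = dplyr::n() == n_cond && all(.data$n >= min_trials)
    ) |>
    dplyr::filter(.data$ok) |>
    dplyr::pull(.data$unit_id)
  drop <- setdiff(dataset$unit_ids, keep)
  dataset$unit_ids <- intersect(dataset$unit_ids, keep)
  dataset$spikes <- dplyr::filter(dataset$spikes, !(.data$unit_id %in% drop))
  if (!is.null(dataset$unit_trials)) {
    dataset$unit_trials <- dplyr::filter(
      dataset$unit_trials, !(.data$unit_id %in% drop)
    )
  }
  dataset
}

#' Build a smoothed firing-rate tensor in one or more alignments
#'
#' Converts a spike dataset into a rate tensor: unit x condition x time
#' (trial-averaged mode) or unit x trial x time (single-trial mode). Rates
#' are Gaussian-smoothed ([smooth_unit_rate()]); each alignment is computed
#' independently on its own time grid and the grids are concatenated along
#' the time axis with alignment boundaries recorded in the time metadata
#' (clusters and reconstructions never silently bridge them). Smoothing uses
#' spikes from the window extended by 4 kernel SDs so there is no boundary
#' bias.
#'
#' @param dataset A `spike_dataset`.
#' @param alignments List of [alignment_spec()]s; default the three canonical
#'   alignments.
#' @param mode `"trial_averaged"` (average within each condition) or
#'   `"single_trial"`.
#' @param kernel_sd_ms Gaussian kernel SD in ms (default 57).
#' @param units Units to include (default all of `dataset$unit_ids`).
#' @param trials Optional trial ids to restrict to (e.g. a contra-lateral
#'   subset); conditions must remain non-empty.
#' @return A `rate_tensor`: list with `values` (3-d array), `mode`,
#'   `units`, `conditions` (tibble), `trials` (single-trial mode),
#'   `time` (tibble `alignment`, `time_ms`, `col`), `kernel_sd_ms`.
#' @export
build_rate_tensor <- function(dataset,
                              alignments = default_alignments(),
                              mode = c("trial_averaged", "single_trial"),
                              kernel_sd_ms = 57,
                              units = NULL,
                              trials = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  mode <- match.arg(mode)
  units <- units %||% dataset$unit_ids
  tr_meta <- dataset$trials
  if (!is.null(trials)) tr_meta <- dplyr::filter(tr_meta, .data$trial_id %in% trials)
  if (!nrow(tr_meta)) abort("No trials selected.")
  cond <- dplyr::arrange(
    dplyr::distinct(
      tr_meta[, c("condition_id", "hand", "grip", "orientation")]
    ),
    .data$condition_id
  )
  full_cond <- task_conditions()
  missing_cond <- setdiff(full_cond$condition_id, cond$condition_id)
  if (length(missing_cond)) {
    lab <- full_cond[full_cond$condition_id %in% missing_cond, ]
    abort(paste0(
      "Condition(s) with zero trials: ",
      paste(sprintf(
        "%s/%s/%+d deg", lab$hand, lab$grip, lab$orientation
      ), collapse = ", ")
    ))
  }
  needed <- c("t_cue_on_ms", "t_move_on_ms", "t_reward_ms")
  if (any(!needed %in% names(tr_meta)) || anyNA(tr_meta[needed])) {
    abort("Every trial needs cue-onset, movement-onset and reward event times.")
  }

  grids <- purrr::map(alignments, alignment_grid)
  n_time <- sum(lengths(grids))
  time_tbl <- purrr::map2_dfr(alignments, grids, function(a, g) {
    tibble::tibble(alignment = a$event, time_ms = g)
  })
  time_tbl$col <- seq_len(n_time)

  n_tr <- nrow(tr_meta)
  vals <- array(
    0,
    dim = c(length(units), n_tr, n_time),
    dimnames = list(unit = units, trial = tr_meta$trial_id, time = NULL)
  )
  hw <- kernel_halfwidth(kernel_sd_ms)
  sp <- dataset$spikes[dataset$spikes$unit_id %in% units &
    dataset$spikes$trial_id %in% tr_meta$trial_id, ]
  trial_row <- match(sp$trial_id, tr_meta$trial_id)
  unit_row <- match(sp$unit_id, units)

  col0 <- 0L
  for (ai in seq_along(alignments)) {
    a <- alignments[[ai]]
    g <- grids[[ai]]
    ev <- tr_meta[[alignment_event_col(a$event)]]
    rel <- sp$spike_time_ms - ev[trial_row]
    ext_start <- floor(a$pre_ms) - hw
    ext_end <- ceiling(a$post_ms) + hw
    n_bins <- ext_end - ext_start
    keep <- rel > ext_start & rel < ext_end
    if (any(keep)) {
      K <- kernel_matrix(g, ext_start, n_bins, kernel_sd_ms)
      bin <- floor(rel[keep] - ext_start) + 1L
      grp <- (unit_row[keep] - 1L) * n_tr + trial_row[keep]
      contrib <- rowsum(K[bin, , drop = FALSE], group = grp)
      gid <- as.integer(rownames(contrib))
      u_of <- (gid - 1L) %/% n_tr + 1L
      t_of <- (gid - 1L) %% n_tr + 1L
      for (j in seq_along(g)) {
        vals[cbind(u_of, t_of, col0 + j)] <- contrib[, j]
      }
    }
    col0 <- col0 + length(g)
  }

  if (mode == "single_trial") {
    # per-(unit, trial) mean rate from cue onset to reward onset, in Hz;
    # the selection statistic for preferred/non-preferred levels
    dur <- tr_meta$t_reward_ms - tr_meta$t_cue_on_ms
    inwin <- sp$spike_time_ms >= tr_meta$t_cue_on_ms[trial_row] &
      sp$spike_time_ms < tr_meta$t_reward_ms[trial_row]
    crm <- matrix(0, length(units), n_tr)
    if (any(inwin)) {
      cnt <- table(factor(
        (unit_row[inwin] - 1L) * n_tr + trial_row[inwin],
        levels = seq_len(length(units) * n_tr)
      ))
      crm <- matrix(as.numeric(cnt), length(units), n_tr, byrow = TRUE)
    }
    crm <- sweep(crm, 2, dur / 1000, "/")
    out <- list(
      values = vals, mode = mode, units = units,
      conditions = cond, trials = tr_meta, time = time_tbl,
      cue_reward_mean = crm,
      kernel_sd_ms = kernel_sd_ms, alignments = alignments,
      hemisphere = dataset$hemisphere
    )
  } else {
    ci <- match(tr_meta$condition_id, cond$condition_id)
    avg <- array(0, dim = c(length(units), nrow(cond), n_time))
    for (c_i in seq_len(nrow(cond))) {
      rows <- which(ci == c_i)
      avg[, c_i, ] <- if (length(rows) == 1L) {
        vals[, rows, ]
      } else {
        apply(vals[, rows, , drop = FALSE], c(1, 3), mean)
      }
    }
    dimnames(avg) <- list(unit = units, condition = cond$condition_id, time = NULL)
    out <- list(
      values = avg, mode = mode, units = units,
      conditions = cond, trials = NULL, time = time_tbl,
      kernel_sd_ms = kernel_sd_ms, alignments = alignments,
      hemisphere = dataset$hemisphere
    )
  }
  structure(out, class = "rate_tensor")
}

#' Average a single-trial rate tensor within conditions
#'
#' Averaging commutes with the (linear) smoothing, so this equals the
#' `trial_averaged` output of [build_rate_tensor()] exactly.
#'
#' @param tensor A single-trial `rate_tensor`.
#' @return A trial-averaged `rate_tensor`.
#' @export
average_trials <- function(tensor) {
  stopifnot(inherits(tensor, "rate_tensor"), tensor$mode == "single_trial")
  cond <- tensor$conditions
  ci <- match(tensor$trials$condition_id, cond$condition_id)
  avg <- array(0, dim = c(length(tensor$units), nrow(cond), nrow(tensor$time)))
  for (c_i in seq_len(nrow(cond))) {
    rows <- which(ci == c_i)
    avg[, c_i, ] <- if (length(rows) == 1L) {
      tensor$values[, rows, ]
    } else {
      apply(tensor$values[, rows, , drop = FALSE], c(1, 3), mean)
    }
  }
  dimnames(avg) <- list(unit = tensor$units, condition = cond$condition_id, time = NULL)
  tensor$values <- avg
  tensor$mode <- "trial_averaged"
  tensor$trials <- NULL
  tensor
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<rate_tensor>", x$mode, "\n")
  cat(sprintf(
    "  %d units x %d %s x %d time samples (%s)\n",
    d[1], d[2], if (x$mode == "single_trial") "trials" else "conditions", d[3],
    paste(unique(x$time$alignment), collapse = " | ")
  ))
  invisible(x)
}

#' Tidy a rate tensor into a long tibble
#'
#' @param x A `rate_tensor`.
#' @param ... Unused.
#' @return A tibble with one row per unit x (condition|trial) x time sample.
#' @export
tidy.rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  key <- if (x$mode == "single_trial") x$trials$trial_id else x$conditions$condition_id
  out <- tibble::tibble(
    unit = rep(x$units, times = d[2] * d[3]),
    key = rep(rep(key, each = d[1]), times = d[3]),
    alignment = rep(x$time$alignment, each = d[1] * d[2]),
    time_ms = rep(x$time$time_ms, each = d[1] * d[2]),
    rate_hz = as.vector(x$values)
  )
  names(out)[2] <- if (x$mode == "single_trial") "trial_id" else "condition_id"
  if (x$mode == "trial_averaged") {
    out <- dplyr::left_join(out, x$conditions, by = "condition_id")
  } else {
    out <- dplyr::left_join(
      out, x$trials[, c("trial_id", "condition_id", "hand", "grip", "orientation")],
      by = "trial_id"
    )
  }
  out
}
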