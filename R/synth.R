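#' The 20-condition factorial task grid
#'
#' The delayed-grasping design crosses hand (left/right), grip type
#' (power/precision) and handle orientation (-50, -25, 0, +25, +50 degrees),
#' giving 20 distinct conditions. Every trial maps to exactly one row.
#'
#' @return A tibble with columns `condition_id`, `hand`, `grip`,
#'   `orientation` (degrees).
#' @export
#' @examples
#' task_conditions()
task_conditions <- function() {
  grid <- tidyr::expand_grid(
    hand = c("left", "right"),
    grip = c("power", "precision"),
    orientation = c(-50, -25, 0, 25, 50)
  )
  dplyr::mutate(grid, condition_id = dplyr::row_number(), .before = 1)
}

marg_tags <- function() {
  c(
    "condition_independent", "hand", "grip", "orientation",
    "hand:grip", "hand:orientation", "grip:orientation"
  )
}

default_shapes <- function() {
  list(
    condition_independent = "movement_locked",
    hand = "memory_sustained",
    grip = "memory_sustained",
    orientation = "cue_sustained",
    `hand:grip` = "movement_locked",
    `hand:orientation` = "memory_sustained",
    `grip:orientation` = "movement_locked"
  )
}

#' Configuration for the synthetic population generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: the
#' 2 x 2 x 5 factorial grid, epoch durations (fixation 700-1100 ms, cue
#' 800 ms, memory 700-1100 ms, hold 300 ms), reaction and movement times
#' around per-dataset medians, and the planted factorial rate components.
#'
#' @param n_units Units per synthetic dataset.
#' @param n_datasets Number of datasets (use >= 2 to exercise the
#'   shared-component selection; each dataset emulates one animal).
#' @param trials_per_condition Trials per condition (>= 5, matching the
#'   stability inclusion criterion of the emulated recordings).
#' @param baseline_hz Baseline firing rate in Hz.
#' @param amplitudes Named non-negative vector of component amplitudes (Hz per
#'   unit-loading SD) for the seven marginalization tags
#'   `condition_independent`, `hand`, `grip`, `orientation`, `hand:grip`,
#'   `hand:orientation`, `grip:orientation`. Missing names default to 0.
#' @param shapes Named list overriding the per-tag temporal envelope; see
#'   Details. Defaults favour cue-sustained orientation coding,
#'   memory-sustained hand/grip coding and movement-locked
#'   condition-independent activity.
#' @param orientation_profile Either `"linear"` or a numeric vector of length
#'   5 giving the orientation tuning profile over (-50, -25, 0, 25, 50)
#'   degrees; it is centered before use. The mirror (hand x orientation)
#'   interaction uses the odd part of this profile so the planted component
#'   satisfies `value(left, theta) == value(right, -theta)` exactly.
#' @param artifact Optional `list(dataset =, amplitude =, shape =)` planting a
#'   transient hand component confined to the cue/memory window into ONE
#'   dataset only (emulating a dataset-specific premature-movement artifact).
#' @param reaction_median_ms,movement_median_ms Per-dataset medians (recycled)
#'   for reaction and movement time; defaults match the emulated behaviour
#'   (~230/265 ms reaction, ~305/325 ms movement).
#' @param hemispheres Recording hemisphere per dataset (recycled); defines
#'   contra-/ipsi-lateral trial splits downstream.
#' @param loading_sd Standard deviation of the Gaussian per-unit loadings.
#' @param seed Master seed; all randomness derives from it via [split_seed()].
#'
#' @details Available envelope shapes: `"cue_phasic"` (Gaussian bump 250 ms
#'   after cue onset, SD 120 ms), `"cue_sustained"` (rises at cue onset,
#'   sustained to reward), `"memory_sustained"` (rises in late cue, sustained
#'   to reward), `"movement_locked"` (Gaussian bump 150 ms after movement
#'   onset, SD 150 ms), `"artifact_cue_transient"` (cue-locked bump truncated
#'   to the cue/memory window).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_units = 60,
                         n_datasets = 2,
                         trials_per_condition = 10,
                         baseline_hz = 10,
                         amplitudes = c(
                           condition_independent = 8, hand = 5, grip = 5,
                           orientation = 5, `hand:grip` = 2,
                           `hand:orientation` = 2, `grip:orientation` = 2
                         ),
                         shapes = NULL,
                         orientation_profile = "linear",
                         artifact = NULL,
                         reaction_median_ms = c(230, 265),
                         movement_median_ms = c(305, 325),
                         hemispheres = c("left", "right"),
                         loading_sd = 1,
                         seed = 1) {
  if (n_units < 1) abort("`n_units` must be at least 1.")
  if (n_datasets < 1) abort("`n_datasets` must be at least 1.")
  if (trials_per_condition < 5) {
    abort("`trials_per_condition` must be >= 5 (stability inclusion criterion).")
  }
  if (baseline_hz < 0) abort("`baseline_hz` must be non-negative.")
  amp <- stats::setNames(rep(0, length(marg_tags())), marg_tags())
  if (length(amplitudes)) {
    bad <- setdiff(names(amplitudes), marg_tags())
    if (length(bad)) abort(paste0("Unknown amplitude tag(s): ", toString(bad)))
    if (any(amplitudes < 0)) abort("Component amplitudes must be >= 0.")
    amp[names(amplitudes)] <- amplitudes
  }
  shp <- modifyList(default_shapes(), shapes %||% list())
  if (!is.null(artifact)) {
    stopifnot(is.list(artifact), !is.null(artifact$dataset), !is.null(artifact$amplitude))
    if (artifact$amplitude < 0) abort("Artifact amplitude must be >= 0.")
    artifact$shape <- artifact$shape %||% "artifact_cue_transient"
  }
  structure(
    list(
      n_units = as.integer(n_units),
      n_datasets = as.integer(n_datasets),
      trials_per_condition = as.integer(trials_per_condition),
      baseline_hz = baseline_hz,
      amplitudes = amp,
      shapes = shp,
      orientation_profile = orientation_profile,
      artifact = artifact,
      reaction_median_ms = rep_len(reaction_median_ms, n_datasets),
      movement_median_ms = rep_len(movement_median_ms, n_datasets),
      hemispheres = rep_len(hemispheres, n_datasets),
      loading_sd = loading_sd,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf(
    "  %d dataset(s) x %d units, %d trials/condition, baseline %.1f Hz\n",
    x$n_datasets, x$n_units, x$trials_per_condition, x$baseline_hz
  ))
  on <- x$amplitudes[x$amplitudes > 0]
  cat(
    "  planted:",
    if (length(on)) paste(names(on), signif(on, 3), collapse = ", ") else "none", "\n"
  )
  if (!is.null(x$artifact)) {
    cat(sprintf(
      "  artifact: hand transient (amp %.1f Hz) in dataset %d\n",
      x$artifact$amplitude, x$artifact$dataset
    ))
  }
  invisible(x)
}

orientation_weights <- function(profile) {
  p <- if (identical(profile, "linear")) c(-1, -0.5, 0, 0.5, 1) else as.numeric(profile)
  stopifnot(length(p) == 5)
  p - mean(p)
}

# odd part of the orientation profile over (-50..50); guarantees zero marginal
# means for the mirror interaction and exact mirror symmetry
mirror_weights <- function(profile) {
  p <- if (identical(profile, "linear")) c(-1, -0.5, 0, 0.5, 1) else as.numeric(profile)
  (p - rev(p)) / 2
}

condition_weights <- function(tag, orientation_profile = "linear") {
  cond <- task_conditions()
  hs <- ifelse(cond$hand == "left", 1, -1)
  gs <- ifelse(cond$grip == "power", 1, -1)
  oi <- match(cond$orientation, c(-50, -25, 0, 25, 50))
  ow <- orientation_weights(orientation_profile)
  mw <- mirror_weights(orientation_profile)
  switch(tag,
    condition_independent = rep(1, nrow(cond)),
    hand = hs,
    grip = gs,
    orientation = ow[oi],
    `hand:grip` = hs * gs,
    `hand:orientation` = hs * mw[oi],
    `grip:orientation` = gs * mw[oi],
    abort(paste0("Unknown marginalization tag: ", tag))
  )
}

#' Build the planted ground-truth components for one dataset
#'
#' Returns one component per marginalization tag (plus the optional artifact
#' component) with the configured amplitude, a per-unit Gaussian loading
#' vector, the per-condition weight vector and the temporal envelope shape.
#' Deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @param dataset_index Which dataset (1-based).
#' @return A list of components of class `ground_truth`; each component has
#'   fields `tag`, `amplitude`, `shape`, `loadings`, `weights`, `artifact`.
#' @export
build_ground_truth <- function(config, dataset_index = 1) {
  stopifnot(inherits(config, "synth_config"))
  if (dataset_index < 1 || dataset_index > config$n_datasets) {
    abort("`dataset_index` must be in 1..n_datasets.")
  }
  comps <- purrr::imap(as.list(config$amplitudes), function(a, tag) {
    k <- match(tag, marg_tags())
    loadings <- with_seed(
      split_seed(config$seed, dataset_index, 1000L, k),
      rnorm(config$n_units, sd = config$loading_sd)
    )
    list(
      tag = tag, amplitude = a, shape = config$shapes[[tag]],
      loadings = loadings,
      weights = condition_weights(tag, config$orientation_profile),
      artifact = FALSE
    )
  })
  comps <- unname(comps)
  if (!is.null(config$artifact) && config$artifact$dataset == dataset_index) {
    loadings <- with_seed(
      split_seed(config$seed, dataset_index, 2000L),
      rnorm(config$n_units, sd = config$loading_sd)
    )
    comps <- c(comps, list(list(
      tag = "hand", amplitude = config$artifact$amplitude,
      shape = config$artifact$shape, loadings = loadings,
      weights = condition_weights("hand"), artifact = TRUE
    )))
  }
  structure(comps, class = "ground_truth")
}

# temporal envelope in [0, 1] on the absolute trial clock
envelope_value <- function(shape, t, sched) {
  cue <- sched$t_cue_on_ms
  go <- sched$t_go_ms
  mov <- sched$t_move_on_ms
  rew <- sched$t_reward_ms
  switch(shape,
    cue_phasic = exp(-0.5 * ((t - (cue + 250)) / 120)^2),
    cue_sustained = stats::plogis((t - (cue + 150)) / 60) *
      stats::plogis(((rew + 100) - t) / 150),
    memory_sustained = stats::plogis((t - (cue + 500)) / 80) *
      stats::plogis((rew - t) / 120),
    movement_locked = exp(-0.5 * ((t - (mov + 150)) / 150)^2),
    artifact_cue_transient = exp(-0.5 * ((t - (cue + 300)) / 130)^2) *
      as.numeric(t >= cue & t <= go),
    abort(paste0("Unknown envelope shape: ", shape))
  )
}

# per-trial epoch schedule; all event times integer ms, strictly increasing
sample_schedule <- function(config, dataset_index, trial) {
  with_seed(split_seed(config$seed, dataset_index, 3000L, trial), {
    fixation <- round(runif(1, 700, 1100))
    memory <- round(runif(1, 700, 1100))
    reaction <- max(150, round(rnorm(1, config$reaction_median_ms[dataset_index], 15)))
    movement <- max(200, round(rnorm(1, config$movement_median_ms[dataset_index], 20)))
    cue_on <- fixation
    go <- cue_on + 800 + memory
    move_on <- go + reaction
    reward <- move_on + movement + 300
    list(
      t_cue_on_ms = cue_on, t_go_ms = go, t_move_on_ms = move_on,
      t_reward_ms = reward, t_end_ms = reward + 800
    )
  })
}

#' Planted intensity function (simulation oracle)
#'
#' Evaluates the exact inhomogeneous-Poisson intensity used by
#' [simulate_dataset()] for one unit on one trial: baseline plus the loaded
#' sum of planted components, optionally rectified at zero. Before
#' rectification the intensity is exactly the sum of the baseline and all
#' component contributions (conservation), so tests can use this as the
#' ground-truth rate oracle.
#'
#' @param ground_truth A [build_ground_truth()] result.
#' @param baseline_hz Baseline rate in Hz.
#' @param unit Unit index.
#' @param condition_id Condition id (row of [task_conditions()]).
#' @param sched A schedule list with `t_cue_on_ms`, `t_go_ms`,
#'   `t_move_on_ms`, `t_reward_ms`.
#' @param t Times (ms, absolute trial clock) at which to evaluate.
#' @param rectify Rectify at 0 (the generator always does)?
#' @return Intensity in Hz at `t`.
#' @export
planted_intensity <- function(ground_truth, baseline_hz, unit, condition_id,
                              sched, t, rectify = TRUE) {
  lam <- rep(baseline_hz, length(t))
  for (comp in ground_truth) {
    if (comp$amplitude == 0) next
    lam <- lam + comp$amplitude * comp$loadings[unit] *
      comp$weights[condition_id] * envelope_value(comp$shape, t, sched)
  }
  if (rectify) pmax(lam, 0) else lam
}

#' Simulate one synthetic spiking dataset
#'
#' Generates inhomogeneous-Poisson spike trains for every unit and trial.
#' The intensity is the rectified sum of the baseline and the planted
#' components evaluated on each trial's epoch schedule, discretised at 1 ms;
#' spike times sit at bin centers (k + 0.5 ms). Each (dataset, unit, trial)
#' triple has its own RNG stream derived from the master seed, so results are
#' reproducible independent of iteration order. The optional artifact
#' component is included only when `dataset_index` matches the artifact spec.
#'
#' @param config A [synth_config()].
#' @param dataset_index Which dataset to generate (1-based).
#' @return A `spike_dataset`: list with `spikes` (tibble `unit_id`,
#'   `trial_id`, `spike_time_ms`), `trials` (tibble with condition labels and
#'   event times), `ground_truth`, `hemisphere`, `config`, `dataset_index`.
#' @export
#' @examples
#' ds <- simulate_dataset(synth_config(n_units = 2, trials_per_condition = 5))
#' head(ds$spikes)
simulate_dataset <- function(config, dataset_index = 1) {
  stopifnot(inherits(config, "synth_config"))
  if (dataset_index < 1 || dataset_index > config$n_datasets) {
    abort("`dataset_index` must be in 1..n_datasets.")
  }
  cond <- task_conditions()
  gt <- build_ground_truth(config, dataset_index)
  n_trials <- nrow(cond) * config$trials_per_condition
  cond_seq <- rep(cond$condition_id, config$trials_per_condition)
  # pseudorandom presentation order
  cond_seq <- with_seed(
    split_seed(config$seed, dataset_index, 4000L),
    sample(cond_seq)
  )
  scheds <- purrr::map(seq_len(n_trials), function(tr) {
    sample_schedule(config, dataset_index, tr)
  })
  trials <- dplyr::bind_cols(
    tibble::tibble(trial_id = seq_len(n_trials)),
    cond[cond_seq, c("condition_id", "hand", "grip", "orientation")],
    dplyr::bind_rows(purrr::map(scheds, tibble::as_tibble))
  )

  active <- purrr::keep(gt, ~ .x$amplitude > 0)
  out_unit <- vector("list", n_trials)
  out_time <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    sch <- scheds[[tr]]
    nb <- sch$t_end_ms
    centers <- seq_len(nb) - 0.5
    cid <- cond_seq[tr]
    if (length(active)) {
      E <- vapply(active, function(cp) {
        envelope_value(cp$shape, centers, sch)
      }, numeric(nb)) # nb x n_comp
      L <- vapply(active, function(cp) {
        cp$amplitude * cp$weights[cid] * cp$loadings
      }, numeric(config$n_units)) # n_units x n_comp
      if (config$n_units == 1L) L <- matrix(L, nrow = 1)
      lam <- config$baseline_hz + tcrossprod(L, E) # n_units x nb, Hz
      lam[lam < 0] <- 0
    } else {
      lam <- NULL
    }
    su <- vector("list", config$n_units)
    st <- vector("list", config$n_units)
    for (u in seq_len(config$n_units)) {
      counts <- with_seed(
        split_seed(config$seed, dataset_index, u, tr, 7L),
        if (is.null(lam)) {
          rpois(nb, config$baseline_hz / 1000)
        } else {
          rpois(nb, lam[u, ] / 1000)
        }
      )
      nz <- counts > 0L
      if (any(nz)) {
        tms <- rep(centers[nz], counts[nz])
        su[[u]] <- rep(u, length(tms))
        st[[u]] <- tms
      }
    }
    out_unit[[tr]] <- unlist(su)
    out_time[[tr]] <- unlist(st)
  }
  lens <- lengths(out_time)
  spikes <- tibble::tibble(
    unit_id = as.integer(unlist(out_unit) %||% integer()),
    trial_id = rep(seq_len(n_trials), lens),
    spike_time_ms = as.numeric(unlist(out_time) %||% numeric())
  )
  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$trial_id, .data$spike_time_ms)
  structure(
    list(
      spikes = spikes, trials = trials,
      n_units = config$n_units, unit_ids = seq_len(config$n_units),
      unit_trials = NULL,
      ground_truth = gt,
      hemisphere = config$hemispheres[dataset_index],
      config = config, dataset_index = dataset_index
    ),
    class = "spike_dataset"
  )
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset>\n")
  cat(sprintf(
    "  %d units, %d trials (%d conditions), %d spikes, hemisphere: %s\n",
    x$n_units, nrow(x$trials), length(unique(x$trials$condition_id)),
    nrow(x$spikes), x$hemisphere
  ))
  invisible(x)
}

#' Write / read a spike dataset as delimited text
#'
#' `write_spike_dataset()` writes `spikes.csv` (`unit_id`, `trial_id`,
#' `spike_time_ms` on the absolute trial clock), `trials.csv` (condition
#' labels with `orientation_deg` and event times) and
#' `ground_truth.json` into `dir`. `read_spike_dataset()` reads them back.
#'
#' @param dataset A `spike_dataset`.
#' @param dir Directory to write to (created if missing).
#' @return `write_spike_dataset()` returns the file paths invisibly;
#'   `read_spike_dataset()` returns a `spike_dataset`.
#' @export
write_spike_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spike_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "spikes.csv")
  tr <- file.path(dir, "trials.csv")
  gt <- file.path(dir, "ground_truth.json")
  utils::write.csv(dataset$spikes, sp, row.names = FALSE)
  trials <- dplyr::rename(dataset$trials, orientation_deg = "orientation")
  utils::write.csv(trials, tr, row.names = FALSE)
  jsonlite::write_json(
    list(
      hemisphere = dataset$hemisphere,
      dataset_index = dataset$dataset_index,
      n_units = dataset$n_units,
      components = purrr::map(dataset$ground_truth, function(cp) {
        cp[c("tag", "amplitude", "shape", "loadings", "weights", "artifact")]
      })
    ),
    gt,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(spikes = sp, trials = tr, ground_truth = gt))
}

#' @rdname write_spike_dataset
#' @export
read_spike_dataset <- function(dir) {
  spikes <- tibble::as_tibble(utils::read.csv(file.path(dir, "spikes.csv")))
  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  trials <- dplyr::rename(trials, orientation = "orientation_deg")
  meta_path <- file.path(dir, "ground_truth.json")
  gt <- NULL
  hemisphere <- "left"
  dsi <- 1L
  n_units <- max(spikes$unit_id, 0L)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
    hemisphere <- meta$hemisphere
    dsi <- meta$dataset_index
    n_units <- meta$n_units
    if (!is.null(meta$components)) {
      gt <- structure(
        purrr::map(meta$components, function(cp) {
          list(
            tag = cp$tag, amplitude = cp$amplitude, shape = cp$shape,
            loadings = as.numeric(unlist(cp$loadings)),
            weights = as.numeric(unlist(cp$weights)),
            artifact = isTRUE(cp$artifact)
          )
        }),
        class = "ground_truth"
      )
    }
  }
  structure(
    list(
      spikes = spikes, trials = trials,
      n_units = as.integer(n_units), unit_ids = seq_len(n_units),
      unit_trials = NULL, ground_truth = gt,
      hemisphere = hemisphere, config = NULL, dataset_index = dsi
    ),
    class = "spike_dataset"
  )
}
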