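#' Default end-to-end pipeline configuration
#'
#' A modest-scale configuration exercising every stage: two synthetic
#' datasets, rate estimation, per-unit tuning tests, per-dataset and pooled
#' dPCA, shared-component selection with back-projection, and hand decoding.
#'
#' @return A nested list; see the fields for the tunable parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    synth = list(
      n_units = 30, n_datasets = 2, trials_per_condition = 10,
      baseline_hz = 10,
      amplitudes = list(
        condition_independent = 8, hand = 5, grip = 5, orientation = 5,
        `hand:orientation` = 2
      ),
      artifact = NULL
    ),
    rates = list(step_ms = 10, kernel_sd_ms = 57),
    cbpt = list(
      run = TRUE, n_perm = 1000, alpha = 0.05, cluster_p = 0.05,
      max_units = 10, laterality = FALSE
    ),
    dpca = list(n_components = 15, lambda = 1e-6),
    shared = list(threshold = 0.6, baseline_rate = 0.05),
    decode = list(factors = "hand", n_iter = 25, n_shuffles = 25)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_rec(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  merge_rec(default_pipeline_config(), user)
}

write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates synth -> rates -> cbpt -> dpca -> shared -> decode from one
#' configuration, writing delimited-text tables and a JSON run manifest to
#' `out_dir`. All stage seeds derive from the single master seed. A stage
#' failure aborts with the stage name and cause.
#'
#' @param config A config list ([default_pipeline_config()],
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return The run manifest (list, invisibly written to `manifest.json`):
#'   config hash, per-stage seeds and wall-clock, output files and their
#'   content hash.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("popgrasp_run_"),
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- config$seed
  files <- character()
  timings <- list()
  results <- list()

  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }

  datasets <- stage("synth", {
    sc <- config$synth
    cfg <- synth_config(
      n_units = sc$n_units, n_datasets = sc$n_datasets,
      trials_per_condition = sc$trials_per_condition,
      baseline_hz = sc$baseline_hz,
      amplitudes = unlist(sc$amplitudes) %||% numeric(),
      artifact = sc$artifact,
      seed = split_seed(master, 1L)
    )
    purrr::map(seq_len(cfg$n_datasets), function(d) {
      ds <- simulate_dataset(cfg, d)
      files <<- c(files, write_spike_dataset(
        ds, file.path(out_dir, paste0("dataset_", d))
      ))
      ds
    })
  })

  tensors <- stage("rates", {
    al <- default_alignments(config$rates$step_ms)
    purrr::map(datasets, function(ds) {
      ds <- exclude_unstable(ds)
      list(
        avg = build_rate_tensor(ds, al,
          mode = "trial_averaged",
          kernel_sd_ms = config$rates$kernel_sd_ms
        ),
        single = build_rate_tensor(ds, al,
          mode = "single_trial",
          kernel_sd_ms = config$rates$kernel_sd_ms
        )
      )
    })
  })

  if (isTRUE(config$cbpt$run)) {
    results$cbpt <- stage("cbpt", {
      purrr::imap(tensors, function(tn, d) {
        units <- head(tn$single$units, config$cbpt$max_units %||% Inf)
        pop <- cbpt_population(
          tn$single,
          alpha = config$cbpt$alpha, cluster_p = config$cbpt$cluster_p,
          n_perm = config$cbpt$n_perm, seed = split_seed(master, 2L, d),
          units = units
        )
        files <<- c(
          files,
          write_table(
            tidy(pop), out_dir, paste0("cbpt_clusters_dataset_", d, ".csv")
          )
        )
        frac <- purrr::map_dfr(
          c("hand", "grip", "orientation"),
          function(f) dplyr::mutate(tuning_fraction(pop, f), factor = f)
        )
        files <<- c(files, write_table(
          frac, out_dir, paste0("cbpt_tuning_fraction_dataset_", d, ".csv")
        ))
        pop
      })
    })
  }

  fits <- stage("dpca", {
    lam <- config$dpca$lambda
    per <- purrr::imap(tensors, function(tn, d) {
      if (identical(lam, "cv")) {
        cv <- cross_validate_lambda(
          tn$single,
          lambdas = unlist(config$dpca$cv_lambdas) %||% 10^seq(-8, -3),
          seed = split_seed(master, 3L, d),
          n_components = config$dpca$n_components
        )
        lam_d <- cv$lambda
      } else {
        lam_d <- lam
      }
      fit_dpca(tn$avg, n_components = config$dpca$n_components, lambda = lam_d)
    })
    pooled_tensor <- pool_datasets(purrr::map(tensors, "avg"))
    pooled <- fit_dpca(
      pooled_tensor,
      n_components = config$dpca$n_components,
      lambda = if (identical(lam, "cv")) {
        per[[1]]$lambda
      } else {
        lam
      }
    )
    vs <- variance_summary(pooled, pooled_tensor)
    files <- c(
      files,
      write_table(vs$cumulative, out_dir, "dpca_cumulative_variance.csv"),
      write_table(
        vs$marginalization_shares, out_dir, "dpca_marginalization_shares.csv"
      ),
      write_table(tidy(pooled), out_dir, "dpca_pooled_components.csv")
    )
    list(per = per, pooled = pooled, pooled_tensor = pooled_tensor)
  })

  results$shared <- stage("shared", {
    sel <- select_shared(fits$pooled, fits$per, config$shared$threshold)
    files <- c(
      files,
      write_table(tidy(sel), out_dir, "shared_selection.csv"),
      write_table(sel$contributions, out_dir, "shared_contributions.csv")
    )
    retuned <- purrr::imap(tensors, function(tn, d) {
      rec <- backproject(sel, tn$avg, d)
      tt <- threshold_tuning(
        rec,
        factor = "hand",
        baseline_rate = config$shared$baseline_rate
      )
      files <<- c(files, write_table(
        tt$fraction, out_dir, paste0("shared_hand_tuning_dataset_", d, ".csv")
      ))
      tt
    })
    list(selection = sel, retuned = retuned)
  })

  results$decode <- stage("decode", {
    purrr::map(config$decode$factors, function(f) {
      dr <- decode_run(
        tensors[[1]]$single, f,
        n_iter = config$decode$n_iter,
        n_shuffles = config$decode$n_shuffles,
        lambda = if (identical(config$dpca$lambda, "cv")) {
          fits$per[[1]]$lambda
        } else {
          config$dpca$lambda
        },
        n_components = config$dpca$n_components,
        seed = split_seed(master, 4L, match(f, config$decode$factors))
      )
      files <<- c(
        files,
        write_table(tidy(dr), out_dir, paste0("decode_accuracy_", gsub(":", "_", f), ".csv")),
        write_table(dr$intervals, out_dir, paste0("decode_intervals_", gsub(":", "_", f), ".csv"))
      )
      dr
    })
  })

  files <- unname(files)
  file_hashes <- vapply(
    sort(files),
    function(f) rlang::hash(readBin(f, "raw", file.info(f)$size)),
    character(1)
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("popgrasp")),
    config = config,
    config_hash = rlang::hash(config),
    master_seed = master,
    stage_seconds = timings,
    files = sort(files),
    output_hash = rlang::hash(unname(file_hashes))
  )
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "stage_seconds")],
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest$results <- results
  invisible(manifest)
}
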