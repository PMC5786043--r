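align_facet <- function() {
  ggplot2::facet_grid(
    cols = ggplot2::vars(.data$alignment),
    scales = "free_x", space = "free_x"
  )
}

#' Plot tuned-fraction time-courses
#'
#' @param fractions A tibble as returned by [tuning_fraction()], optionally
#'   with extra grouping columns (e.g. `factor`, `subset`).
#' @param colour Optional column name to colour by.
#' @return A ggplot.
#' @export
plot_tuning_fraction <- function(fractions, colour = NULL) {
  p <- ggplot2::ggplot(
    fractions,
    ggplot2::aes(.data$time_ms, 100 * .data$fraction)
  ) +
    align_facet() +
    ggplot2::labs(x = "time (ms)", y = "% units tuned") +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p + ggplot2::geom_line()
  }
}

#' @export
autoplot.rate_tensor <- function(object, units = NULL, ...) {
  dat <- tidy(object)
  units <- units %||% head(unique(dat$unit), 4)
  dat <- dplyr::filter(dat, .data$unit %in% units)
  if (object$mode == "single_trial") {
    dat <- dat |>
      dplyr::group_by(
        .data$unit, .data$condition_id, .data$hand, .data$grip,
        .data$orientation, .data$alignment, .data$time_ms
      ) |>
      dplyr::summarise(rate_hz = mean(.data$rate_hz), .groups = "drop")
  }
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$time_ms, .data$rate_hz,
      colour = base::factor(.data$orientation),
      linetype = paste(.data$hand, .data$grip)
    )
  ) +
    ggplot2::geom_line() +
    align_facet() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$unit),
      cols = ggplot2::vars(.data$alignment),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(
      x = "time (ms)", y = "rate (Hz)",
      colour = "orientation", linetype = "hand / grip"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dpca_fit <- function(object, components = NULL, ...) {
  components <- components %||% head(object$components$component, 6)
  dat <- component_timecourses(object, components)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$time_ms, .data$score,
      colour = base::factor(.data$orientation),
      linetype = paste(.data$hand, .data$grip)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(
        paste0("#", .data$component, " ", .data$marginalization)
      ),
      cols = ggplot2::vars(.data$alignment),
      scales = "free", space = "free_x"
    ) +
    ggplot2::labs(
      x = "time (ms)", y = "component score",
      colour = "orientation", linetype = "hand / grip"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decode_run <- function(object, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time_ms)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 100 * .data$null_mean, ymax = 100 * .data$null_max),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 100 * object$chance, linetype = 2) +
    align_facet() +
    ggplot2::labs(
      x = "time (ms)", y = "% correct",
      title = paste("decoding:", object$factor)
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$intervals)) {
    p <- p + ggplot2::geom_segment(
      data = object$intervals,
      ggplot2::aes(
        x = .data$start_ms, xend = .data$end_ms,
        y = 100, yend = 100
      ),
      linewidth = 2
    )
  }
  p
}

#' @export
autoplot.shared_selection <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(base::factor(.data$dataset), base::factor(.data$component),
      fill = .data$best_abs_r
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$retained, "", "x")), size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    ggplot2::labs(
      x = "dataset", y = "pooled component", fill = "best |r|",
      title = "shared-component selection (x = discarded)"
    ) +
    ggplot2::theme_minimal()
}
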