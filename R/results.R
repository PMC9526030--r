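#' @export
print.completion_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<completion_summary> %.0f Hz, %g m territories, EWL %s: %.3f %% (SE %.3f, n = %d)\n",
    x$config$freq, x$config$diameter,
    if (x$config$ewl$enabled) "on" else "off",
    s$mean_pct, s$se, s$n))
  invisible(x)
}

#' Tidy a completion summary
#'
#' @param x A `completion_summary` from [run_scenario()].
#' @param ... Unused.
#' @return The per-iteration, per-day end-of-day completion percentages as
#'   a tibble (`iteration`, `day`, `pct`).
#' @method tidy completion_summary
#' @export
tidy.completion_summary <- function(x, ...) x$daily

#' One-row summary of a completion scenario
#'
#' @param x A `completion_summary` from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble: `freq`, `diameter`, `ewl`, `n`, `mean_pct`,
#'   `se` — the shape of a completion-percentage results table row.
#' @method glance completion_summary
#' @export
glance.completion_summary <- function(x, ...) {
  tibble::tibble(
    freq = x$config$freq,
    diameter = x$config$diameter,
    ewl = x$config$ewl$enabled,
    n = x$summary$n,
    mean_pct = x$summary$mean_pct,
    se = x$summary$se
  )
}

#' Plot the mean completion curve
#'
#' @param object A `completion_summary` from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot of the per-step mean completion percentage.
#' @method autoplot completion_summary
#' @export
autoplot.completion_summary <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$step, y = .data$mean_pct)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(
      x = "time step (min after sunrise)",
      y = "interior birds finished (%)",
      title = sprintf("Completion curve, %.0f Hz, %g m territories, EWL %s",
                      object$config$freq, object$config$diameter,
                      if (object$config$ewl$enabled) "on" else "off")) +
    ggplot2::theme_minimal()
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> '%s': %d freq x %d radius cells, %d iterations\n",
              x$label, dplyr::n_distinct(x$grid$freq),
              dplyr::n_distinct(x$grid$radius), x$iterations))
  invisible(x)
}

#' Tidy a two-bird sweep result
#'
#' @param x A `sweep_result` from [run_pairwise_sweep()].
#' @param ... Unused.
#' @return A tibble with `freq`, `radius`, `contact_pct`.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) x$grid

#' Contact-percentage heatmap for a sweep
#'
#' @param object A `sweep_result` from [run_pairwise_sweep()].
#' @param ... Unused.
#' @return A ggplot heatmap of contact percentage over frequency and
#'   territory radius.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$radius, y = .data$freq / 1000,
                               fill = .data$contact_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "territory radius (m)", y = "frequency (kHz)",
                  fill = "contact %", title = object$label) +
    ggplot2::theme_minimal()
}

#' @export
print.sweep_diff <- function(x, ...) {
  cat(sprintf("<sweep_diff> '%s': %d cells, mean diff %.2f\n",
              x$label, nrow(x$grid), mean(x$grid$diff_pct)))
  invisible(x)
}

#' Tidy a sweep difference grid
#'
#' @param x A `sweep_diff` from [diff_grid()].
#' @param ... Unused.
#' @return A tibble with `freq`, `radius`, `diff_pct`.
#' @method tidy sweep_diff
#' @export
tidy.sweep_diff <- function(x, ...) x$grid

#' Difference heatmap between two sweeps
#'
#' @param object A `sweep_diff` from [diff_grid()].
#' @param ... Unused.
#' @return A ggplot diverging heatmap of the cell-wise contact-percentage
#'   difference.
#' @method autoplot sweep_diff
#' @export
autoplot.sweep_diff <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$radius, y = .data$freq / 1000,
                               fill = .data$diff_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#3b4cc0", mid = "white",
                                  high = "#b40426", midpoint = 0) +
    ggplot2::labs(x = "territory radius (m)", y = "frequency (kHz)",
                  fill = "difference (%)", title = object$label) +
    ggplot2::theme_minimal()
}
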