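#' Plot loop-array observables along a trajectory
#'
#' Time courses of loop coverage, mean loop size (sites), mean LEFs per loop
#' and branched fraction, faceted on a free y scale -- the standard check
#' that a run has reached its steady state.
#'
#' @param object A `lef_trajectory`.
#' @param stats Optional precomputed [trajectory_loop_stats()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lef_trajectory <- function(object, stats = NULL, ...) {
  if (is.null(stats)) stats <- trajectory_loop_stats(object)
  long <- tidyr::pivot_longer(
    dplyr::select(stats, "time", "coverage", "mean_loop_size",
                  "mean_lefs_per_loop", "branched_fraction"),
    -"time", names_to = "observable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(
      x = "time", y = NULL,
      title = sprintf("Loop array dynamics (lambda/d = %.3g)",
                      object$params$lambda_over_d)
    ) +
    ggplot2::theme_minimal()
}

#' Draw a loop array
#'
#' Arc-free diagram of a reconstructed loop array: each loop is a horizontal
#' segment spanning its genomic extent, raised by its nesting level, with
#' line width showing the supporting-stack size. Gaps between top-level
#' loops appear along the baseline.
#'
#' @param object A `loop_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loop_table <- function(object, ...) {
  df <- tibble::as_tibble(tidy(object))
  df$level <- ifelse(df$top_level, 1, 2)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$level,
                   yend = .data$level, linewidth = .data$n_lefs,
                   colour = .data$branched)
    ) +
    ggplot2::scale_linewidth_continuous(range = c(0.5, 3)) +
    ggplot2::scale_y_continuous(breaks = c(1, 2),
                                labels = c("top-level", "nested"),
                                limits = c(0.5, 2.5)) +
    ggplot2::labs(x = "lattice site", y = NULL, linewidth = "LEFs in stack",
                  colour = "branched",
                  title = sprintf("Loop array at t = %g", attr(object, "time"))) +
    ggplot2::theme_minimal()
}

#' Plot estimated loop death and division rates against the scaling laws
#'
#' Log-scale rates versus loop size in units of `d`, with the
#' unit-prefactor theory curves `(1/tau)(x e^{-x})` and
#' `(1/tau) x^3 (d/lambda)` overlaid for shape comparison (the laws predict
#' scaling, not absolute constants).
#'
#' @param object A tibble from [estimate_event_rates()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loop_rates <- function(object, ...) {
  p <- attr(object, "params")
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$rate),
                      .data$rate > 0)
  xx <- seq(max(min(df$x) / 2, 0.05), max(df$x) * 1.2, length.out = 200)
  theo <- dplyr::bind_rows(
    tibble::tibble(x = xx, kind = "death",
                   rate = rate_loop_death(xx * p$d, p$d, p$tau)),
    tibble::tibble(x = xx, kind = "division",
                   rate = rate_loop_division(xx * p$d, p$d, p$tau, p$lambda))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$rate)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(.data$rate - .data$se, 1e-12),
                   ymax = .data$rate + .data$se)
    ) +
    ggplot2::geom_line(data = theo, linetype = 2, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "loop size / d", y = "events per loop per unit time",
                  title = "Loop death and division rates") +
    ggplot2::theme_minimal()
}

#' Plot a phase-diagram sweep
#'
#' Coverage, branched fraction and mean LEFs per loop as functions of
#' `lambda/d` on a log axis, with the rough sparse/dense regime boundaries
#' at 0.5 and 20 marked. Runs from grids varying different microscopic
#' parameters should collapse onto single curves.
#'
#' @param sweep A tibble from [sweep_phase_diagram()].
#' @param colour_by Optional column name used to colour points (e.g.
#'   `"N"` to check curve collapse across parameterisations).
#' @return A ggplot.
#' @export
plot_phase_diagram <- function(sweep, colour_by = NULL) {
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, "lambda_over_d",
                  dplyr::all_of(c(colour_by, "coverage", "branched_fraction",
                                  "mean_lefs_per_loop"))),
    dplyr::all_of(c("coverage", "branched_fraction", "mean_lefs_per_loop")),
    names_to = "observable", values_to = "value"
  )
  aes <- if (is.null(colour_by)) {
    ggplot2::aes(.data$lambda_over_d, .data$value)
  } else {
    ggplot2::aes(.data$lambda_over_d, .data$value,
                 colour = factor(.data[[colour_by]]))
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(0.5, 20), linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "lambda / d", y = NULL, colour = colour_by,
                  title = "Loop-array phase diagram") +
    ggplot2::theme_minimal()
}

#' @export
tidy.lef_trajectory <- function(x, ...) trajectory_loop_stats(x, ...)

#' @export
glance.lef_trajectory <- function(x, ...) {
  final <- loop_stats(extract_loops(x$final_state), ...)
  dplyr::bind_cols(
    tibble::tibble(
      L = x$params$L, N = x$params$N, v = x$params$v, tau = x$params$tau,
      lambda_over_d = x$params$lambda_over_d,
      t_final = attr(x$final_state, "time"),
      n_snapshots = length(unique(x$snapshots$time))
    ),
    final
  )
}
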