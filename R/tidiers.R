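#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run
#'
#' Long-format time series of a run: one row per recorded sample and
#' signal.
#'
#' @param x A `stngpe_sim` object.
#' @param signals Which series columns to keep. Default all.
#' @param ... Unused.
#' @return Tibble with columns `t` (ms), `signal`, `value`.
#' @export
tidy.stngpe_sim <- function(x, signals = c("lfp", "x", "R", "gate", "S", "A"),
                            ...) {
  se <- dplyr::select(x$series, "t", dplyr::all_of(signals))
  tidyr::pivot_longer(se, -"t", names_to = "signal", values_to = "value")
}

#' One-row summary of a simulation run
#'
#' @param x A `stngpe_sim` object.
#' @param ... Unused.
#' @return The post-transient summary tibble (see [summarize_run()]).
#' @export
glance.stngpe_sim <- function(x, ...) x$summary

#' Per-run summaries of a protocol
#'
#' @param x A `stngpe_protocol` object.
#' @param ... Unused.
#' @return Tibble of per-ramp-run summaries.
#' @export
tidy.stngpe_protocol <- function(x, ...) x$runs

#' Averaged protocol summary
#'
#' @param x A `stngpe_protocol` object.
#' @param ... Unused.
#' @return One-row tibble of protocol means and sds.
#' @export
glance.stngpe_protocol <- function(x, ...) x$summary

#' Tidy burst statistics
#'
#' @param x A `burst_stats` object.
#' @param ... Unused.
#' @return The histogram tibble (`bin_lo`, `bin_hi`, `count`).
#' @export
tidy.burst_stats <- function(x, ...) x$histogram

#' One-row burst-statistics summary
#'
#' @param x A `burst_stats` object.
#' @param ... Unused.
#' @return Tibble with `n`, `mean`, `median`, `frac_short`, `cutoff_s`.
#' @export
glance.burst_stats <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, median = x$median,
                 frac_short = x$frac_short, cutoff_s = x$cutoff_s)
}

#' Plot a simulation run
#'
#' Stacked time courses of the order parameter, raw and filtered LFP, the
#' stimulation-gate trace and the modulation signal.
#'
#' @param object A `stngpe_sim` object.
#' @param signals Series columns to show. Default `c("R", "lfp", "x",
#'   "gate", "S")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stngpe_sim <- function(object,
                                signals = c("R", "lfp", "x", "gate", "S"),
                                ...) {
  d <- tidy(object, signals = signals)
  d$signal <- factor(d$signal, levels = signals)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t / 1000, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$config$t_stim_on / 1000,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot burst-length distribution
#'
#' @param object A `burst_stats` object.
#' @param ... Unused.
#' @return A ggplot histogram of burst lengths with mean and median marked.
#' @export
autoplot.burst_stats <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = if (nrow(h)) h$bin_hi[1] - h$bin_lo[1] else 1,
                      fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "burst length (s)", y = "count") +
    ggplot2::theme_minimal()
  if (object$n > 0) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = object$median, linetype = "dotted")
  }
  p
}

#' Plot a sweep result
#'
#' Averaged order parameter (and optionally other summaries) against a
#' swept parameter, grouped by a second one.
#'
#' @param sweep Tibble from [sweep_protocol()].
#' @param x Name of the swept column mapped to the x axis. Default "K".
#' @param y Summary column to plot. Default "R_mean".
#' @param group Optional column mapped to colour (e.g. "GW").
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, x = "K", y = "R_mean", group = NULL) {
  aes <- ggplot2::aes(x = .data[[x]], y = .data[[y]])
  p <- ggplot2::ggplot(dplyr::filter(sweep, .data$feasible), aes)
  if (!is.null(group)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(
      colour = factor(.data[[group]]))) +
      ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[group]]))) +
      ggplot2::labs(colour = group)
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p + ggplot2::theme_minimal()
}
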