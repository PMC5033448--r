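#' Tidy a balanced two-way ANOVA
#'
#' @param x A `vv_anova` from [two_way_anova()].
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `ss`, `df`, `ms`,
#'   `statistic`, `p.value`.
#' @method tidy vv_anova
#' @export
tidy.vv_anova <- function(x, ...) {
  x$table
}

#' One-row summary of a balanced two-way ANOVA
#'
#' @param x A `vv_anova`.
#' @param ... Unused.
#' @return A tibble with `nobs`, `n_per_cell`, `df.residual`, `ms.residual`,
#'   and `r.squared` (fraction of total SS explained by the model terms).
#' @method glance vv_anova
#' @export
glance.vv_anova <- function(x, ...) {
  ss <- x$table$ss
  tibble::tibble(
    nobs = x$nobs,
    n_per_cell = x$n_per_cell,
    df.residual = x$df_res,
    ms.residual = x$ms_res,
    r.squared = sum(ss[1:3]) / sum(ss)
  )
}

#' Tidy a pipeline report
#'
#' @param x A `vv_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The pairwise-comparison tibble (or, when the ANOVA stage was
#'   skipped, the long percent-change table).
#' @method tidy vv_report
#' @export
tidy.vv_report <- function(x, ...) {
  x$pairwise %||% x$long_table
}

#' Plot the channels of a recording
#'
#' Faceted time traces of the stimulation current and the three physiological
#' channels, with the stimulation window shaded when a stimulus is given.
#'
#' @param object A `physio_recording`.
#' @param stim Optional [stimulus_spec()] used to shade the stimulation
#'   window.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot physio_recording
#' @export
autoplot.physio_recording <- function(object, stim = NULL, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "value") |>
    dplyr::mutate(channel = factor(.data$channel, levels = recording_columns()[-1]))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 60, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL,
                  title = recording_meta(object)$animal_id) +
    ggplot2::theme_minimal()
  if (!is.null(stim)) {
    p <- p + ggplot2::annotate("rect", xmin = stim$onset / 60,
                               xmax = (stim$onset + stim$duration) / 60,
                               ymin = -Inf, ymax = Inf, alpha = 0.12,
                               fill = "red")
  }
  p
}

#' Plot percent changes by window and group
#'
#' Boxplots of the per-animal percent change from baseline for one channel
#' across the analysis windows, colored by group.
#'
#' @param long_table Output of [build_long_table()].
#' @param channel Channel to plot, default `"cbf_pu"`.
#' @return A ggplot.
#' @export
plot_percent_change <- function(long_table, channel = "cbf_pu") {
  dat <- dplyr::filter(long_table, .data$channel == !!channel) |>
    dplyr::mutate(window = factor(.data$window, levels = unique(.data$window)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$window, y = .data$pct_change,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "% change from baseline", fill = "Group",
                  title = channel) +
    ggplot2::theme_minimal()
}

#' Plot drop-event delays by group
#'
#' @param events Stacked drop events with `group` and `delay_s` columns (e.g.
#'   the `events` element of a [run_pipeline()] report).
#' @return A ggplot.
#' @export
plot_drop_delays <- function(events) {
  ggplot2::ggplot(events, ggplot2::aes(x = .data$group, y = .data$delay_s)) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "CBF drop delay (s)") +
    ggplot2::theme_minimal()
}
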