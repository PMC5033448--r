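#' Run the full analysis pipeline on a simulated or loaded cohort
#'
#' Orchestrates every stage end-to-end: simulate (or accept) the cohort,
#' segment each recording into the analysis windows, compute percent-change
#' summaries, detect sustained CBF drops, score stimulus-locked oscillations,
#' apply the responder inclusion rule (stimulated groups only), assemble the
#' long table, and — when at least two groups survive — run the two-way
#' group x window ANOVA with Sidak-adjusted pairwise comparisons per channel.
#' Deterministic given the configuration's master seed.
#'
#' @param config A [run_config()] (or a path to a YAML config).
#' @param recordings Optional list of `physio_recording`s to analyze instead
#'   of simulating (e.g. from [read_recording()]).
#' @return An object of class `vv_report`: a list with `summaries`, `events`,
#'   `inclusion`, `long_table`, `delay_summary`, `anova` (per channel),
#'   `pairwise` (per channel), and `provenance`. If `output_dir` is set, all
#'   tables are also persisted as CSV.
#' @examples
#' cfg <- run_config(cohort = cohort_spec(n_per_group = 3, master_seed = 5),
#'                   params = list(sgvs = preset_params("sgvs")))
#' \donttest{rep <- run_pipeline(cfg)}
#' @export
run_pipeline <- function(config, recordings = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  det <- config$detector
  windows <- config$windows
  baseline_win <- windows[1, ]
  stim_win <- windows[windows$window == "Stimulation", ]
  if (nrow(stim_win) != 1) {
    abort("Pipeline stage [segment]: windows must contain exactly one \"Stimulation\" window.")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage [%s]: %s", name, conditionMessage(e)))
    })
  }

  recs <- recordings %||% stage("simulate", {
    simulate_cohort(config$cohort, spec = config$stimulus,
                    params = config$params)
  })

  per_animal <- stage("summarize", {
    purrr::map(recs, function(rec) {
      s <- percent_change(summarize_sections(rec, windows))
      list(rec = rec, summaries = s, meta = recording_meta(rec))
    })
  })
  summaries <- purrr::map_dfr(per_animal, "summaries")

  events <- stage("detect", {
    purrr::map_dfr(per_animal, function(x) {
      ev <- detect_sustained_drop(
        x$rec, channel = "cbf_pu", stim_window = stim_win,
        base = baseline_stats(x$rec, baseline_win),
        k_sd = det$k_sd, min_duration = det$min_duration,
        smoothing_halfwidth = det$smoothing_halfwidth
      )
      if (nrow(ev) > 0) {
        dplyr::mutate(ev, animal = x$meta$animal_id, group = x$meta$group,
                      .before = 1)
      } else ev
    })
  })

  inclusion <- stage("include", {
    purrr::map_dfr(per_animal, function(x) {
      osc <- if (x$meta$group == "sham") c(map_mmHg = 0, hr_bpm = 0) else
        c(map_mmHg = oscillation_score(x$rec, "map_mmHg", config$stimulus,
                                       baseline_win),
          hr_bpm = oscillation_score(x$rec, "hr_bpm", config$stimulus,
                                     baseline_win))
      res <- apply_inclusion_rule(
        x$summaries, osc, group = x$meta$group,
        decrease_threshold = det$decrease_threshold,
        oscillation_threshold = det$oscillation_threshold
      )
      dplyr::mutate(res, animal = x$meta$animal_id, group = x$meta$group,
                    osc_map = osc[["map_mmHg"]], osc_hr = osc[["hr_bpm"]],
                    .before = 1)
    })
  })
  for (i in which(!inclusion$included)) {
    inform(sprintf("Excluded %s (%s): %s", inclusion$animal[i],
                   inclusion$group[i], inclusion$reason[i]))
  }

  long_table <- stage("long_table", build_long_table(summaries, inclusion))

  delay_summary <- if (nrow(events) >= 2) cohort_delay_summary(events) else NULL

  groups_left <- unique(long_table$group)
  stats_res <- list(anova = NULL, pairwise = NULL)
  if (length(groups_left) >= 2) {
    stats_res <- stage("statistics", {
      counts <- long_table |>
        dplyr::filter(.data$channel == "cbf_pu",
                      .data$window == "Stimulation") |>
        dplyr::count(.data$group)
      if (length(unique(counts$n)) != 1) {
        excluded <- inclusion$animal[!inclusion$included]
        abort(paste0(
          "cohort is unbalanced after exclusions (",
          paste(sprintf("%s: %d", counts$group, counts$n), collapse = ", "),
          "); excluded animals: ",
          if (length(excluded)) paste(excluded, collapse = ", ") else "none",
          ". Equalize group sizes (e.g. subsample) before the ANOVA."))
      }
      fits <- purrr::map(
        stats::setNames(physio_channels(), physio_channels()),
        function(ch) two_way_anova(dplyr::filter(long_table,
                                                 .data$channel == ch)))
      pw <- purrr::imap_dfr(fits, function(fit, ch) {
        dplyr::mutate(
          pairwise_group_comparisons(
            dplyr::filter(long_table, .data$channel == ch)),
          channel = ch, .before = 1)
      })
      list(anova = fits, pairwise = pw)
    })
  } else {
    inform("Fewer than two groups after exclusions; skipping the ANOVA stage.")
  }
  anova <- stats_res$anova
  pairwise <- stats_res$pairwise

  provenance <- list(
    # hash covers the scientific configuration, not where it is written
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    master_seed = config$cohort$master_seed,
    n_animals = length(recs),
    package_version = as.character(utils::packageVersion("vvsim"))
  )

  report <- structure(
    list(summaries = summaries, events = events, inclusion = inclusion,
         long_table = long_table, delay_summary = delay_summary,
         anova = anova, pairwise = pairwise, provenance = provenance),
    class = "vv_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Persist a pipeline report as CSV tables
#'
#' @param report A `vv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "vv_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$summaries, file.path(dir, "summaries.csv"))
  readr::write_csv(report$events, file.path(dir, "events.csv"))
  readr::write_csv(report$inclusion, file.path(dir, "inclusion.csv"))
  readr::write_csv(report$long_table, file.path(dir, "long_table.csv"))
  if (!is.null(report$delay_summary)) {
    readr::write_csv(report$delay_summary, file.path(dir, "delay_summary.csv"))
  }
  if (!is.null(report$anova)) {
    anova_tbl <- purrr::imap_dfr(report$anova, function(fit, ch) {
      dplyr::mutate(tidy(fit), channel = ch, .before = 1)
    })
    readr::write_csv(anova_tbl, file.path(dir, "anova.csv"))
    readr::write_csv(report$pairwise, file.path(dir, "pairwise.csv"))
  }
  writeLines(sprintf("%s: %s", names(report$provenance),
                     unlist(report$provenance)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' @export
print.vv_report <- function(x, ...) {
  cat("<vv_report>\n")
  cat(sprintf("  %d animals, %d included, %d CBF drop events\n",
              nrow(x$inclusion), sum(x$inclusion$included), nrow(x$events)))
  if (!is.null(x$delay_summary)) {
    cat(sprintf("  CBF drop delay: %.1f +/- %.1f s (n = %d)\n",
                x$delay_summary$mean_delay_s, x$delay_summary$sd_delay_s,
                x$delay_summary$n_events))
  }
  if (!is.null(x$pairwise)) {
    sig <- dplyr::filter(x$pairwise, .data$significant)
    cat(sprintf("  %d significant Sidak-adjusted pairwise comparisons\n",
                nrow(sig)))
  }
  invisible(x)
}
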