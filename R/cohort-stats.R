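#' Responder inclusion rule
#'
#' An animal shows a vasovagal-like response — and is included — if MAP or HR
#' decreases during stimulation, or if MAP or HR shows a stimulus-locked
#' oscillation. It is excluded only when *both* channels fail the decrease
#' criterion *and* both fail the oscillation criterion. Sham controls are
#' included by definition (`group = "sham"`): the rule screens stimulated
#' animals for a response, and a control is not expected to respond.
#'
#' @param summaries Percent-change summaries of one animal (output of
#'   [percent_change()]), containing the Stimulation window rows for
#'   `map_mmHg` and `hr_bpm`.
#' @param osc_scores Named numeric with [oscillation_score()]s for
#'   `map_mmHg` and `hr_bpm` (ignored for sham).
#' @param group Group label of the animal.
#' @param decrease_threshold Stimulation-window percent change below which a
#'   channel counts as decreased (default -2, i.e. a drop of more than 2%).
#' @param oscillation_threshold Oscillation score above which a channel
#'   counts as stimulus-locked (default 20, roughly the 99.99th percentile of
#'   the score's null distribution).
#' @param stim_window_name Name of the stimulation window in `summaries`.
#' @return One-row tibble: `included` (logical) and `reason` (which clause
#'   decided).
#' @export
apply_inclusion_rule <- function(summaries, osc_scores, group = "sgvs",
                                 decrease_threshold = -2,
                                 oscillation_threshold = 20,
                                 stim_window_name = "Stimulation") {
  if (group == "sham") {
    return(tibble::tibble(included = TRUE, reason = "sham control"))
  }
  stim <- summaries[summaries$window == stim_window_name, ]
  need <- c("map_mmHg", "hr_bpm")
  if (!all(need %in% stim$channel) || !"pct_change" %in% names(stim)) {
    abort("`summaries` must contain Stimulation-window pct_change for map_mmHg and hr_bpm.")
  }
  if (!all(need %in% names(osc_scores))) {
    abort("`osc_scores` must be named with map_mmHg and hr_bpm entries.")
  }
  pct <- stats::setNames(stim$pct_change, stim$channel)[need]
  dec <- pct < decrease_threshold
  osc <- osc_scores[need] >= oscillation_threshold
  clauses <- c(
    if (dec[["map_mmHg"]]) "MAP decrease",
    if (dec[["hr_bpm"]]) "HR decrease",
    if (osc[["map_mmHg"]]) "MAP oscillation",
    if (osc[["hr_bpm"]]) "HR oscillation"
  )
  if (length(clauses) > 0) {
    tibble::tibble(included = TRUE, reason = paste(clauses, collapse = " + "))
  } else {
    tibble::tibble(included = FALSE,
                   reason = "no decrease in MAP or HR and no stimulus-locked oscillation")
  }
}

#' Assemble the long percent-change table for group statistics
#'
#' Stacks the per-animal percent-change summaries of the included animals into
#' one row per animal x non-baseline window x channel.
#'
#' @param summaries Combined [percent_change()] summaries with `animal` and
#'   `group` columns (one block per animal, all standard windows present).
#' @param inclusion Tibble with columns `animal` and `included`; excluded
#'   animals contribute no rows. Omit to include everyone.
#' @param baseline Name of the baseline window to drop (its percent change is
#'   identically 0).
#' @return A tibble with columns `animal`, `group`, `window`, `channel`,
#'   `pct_change`.
#' @export
build_long_table <- function(summaries, inclusion = NULL,
                             baseline = "Baseline") {
  tbl <- summaries
  if (!is.null(inclusion)) {
    keep <- inclusion$animal[inclusion$included]
    tbl <- dplyr::filter(tbl, .data$animal %in% keep)
  }
  tbl <- tbl |>
    dplyr::filter(.data$window != baseline) |>
    dplyr::select("animal", "group", "window", "channel", "pct_change")
  counts <- dplyr::count(tbl, .data$animal, .data$channel)
  n_win <- length(unique(tbl$window))
  if (nrow(counts) > 0 && any(counts$n != n_win)) {
    bad <- unique(counts$animal[counts$n != n_win])
    abort(sprintf("Animal(s) %s are missing windows; every included animal needs all %d non-baseline windows.",
                  paste(bad, collapse = ", "), n_win))
  }
  tbl
}

#' Balanced two-way analysis of variance
#'
#' Fits the two-factor crossed design (by default group x window) to one
#' channel's percent changes using the closed-form balanced decomposition:
#' factor and interaction sums of squares are computed from cell and marginal
#' means, F statistics as factor mean square over residual mean square, and p
#' values from the upper tail of the F distribution. The design must be
#' balanced (equal observations per cell) and have at least one residual
#' degree of freedom.
#'
#' @param data Long tibble, e.g. one channel of [build_long_table()].
#' @param response Name of the response column, default `"pct_change"`.
#' @param factor_a,factor_b Names of the two factor columns, defaults
#'   `"group"` and `"window"`.
#' @return An object of class `vv_anova`; see [tidy.vv_anova()] and
#'   [pairwise_group_comparisons()].
#' @examples
#' recs <- simulate_cohort(cohort_spec(n_per_group = 4, master_seed = 11),
#'                         params = list(sgvs = preset_params("sgvs")))
#' long <- purrr::map_dfr(recs, ~ percent_change(summarize_sections(.x))) |>
#'   build_long_table()
#' fit <- two_way_anova(dplyr::filter(long, channel == "cbf_pu"))
#' tidy(fit)
#' @export
two_way_anova <- function(data, response = "pct_change",
                          factor_a = "group", factor_b = "window") {
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) abort(sprintf("Column \"%s\" not found.", col))
  }
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  a <- nlevels(A)
  b <- nlevels(B)
  if (a < 2 || b < 2) {
    abort(sprintf("Both factors need >= 2 levels (got %d x %d).", a, b))
  }
  counts <- table(A, B)
  if (any(counts == 0)) abort("Every factor-A x factor-B cell needs >= 1 observation.")
  if (length(unique(as.vector(counts))) != 1) {
    abort(paste0("Unbalanced design: cell counts differ (",
                 paste(range(counts), collapse = "-"),
                 "). The closed-form decomposition requires equal per-cell n; ",
                 "use equal group sizes (e.g. subsample the larger groups)."))
  }
  n <- counts[1, 1]
  if (n < 2) {
    abort("Only one observation per cell: no residual degrees of freedom.")
  }
  grand <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- b * n * sum((mA - grand)^2)
  ss_b <- a * n * sum((mB - grand)^2)
  ss_ab <- n * sum((mAB - outer(mA, rep(1, b)) -
                      outer(rep(1, a), mB) + grand)^2)
  ss_res <- sum((y - mAB[cbind(A, B)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (n - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_res)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  structure(
    list(
      table = tibble::tibble(
        term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b),
                 "Residuals"),
        ss = ss, df = df, ms = ms, statistic = f, p.value = p
      ),
      cell_means = mAB, n_per_cell = n,
      factor_a = factor_a, factor_b = factor_b,
      levels_a = levels(A), levels_b = levels(B),
      ms_res = ms[4], df_res = df[4],
      nobs = length(y)
    ),
    class = "vv_anova"
  )
}

#' @export
print.vv_anova <- function(x, ...) {
  cat(sprintf("Balanced two-way ANOVA: %s x %s, n = %d per cell\n",
              x$factor_a, x$factor_b, x$n_per_cell))
  print(x$table)
  invisible(x)
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1: the family-wise error rate under
#' independence of the `m` comparisons.
#'
#' @param raw_p Numeric vector of raw p values in `[0, 1]`.
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p values, same length as `raw_p`.
#' @examples
#' sidak_adjust(0.01, 5)
#' @export
sidak_adjust <- function(raw_p, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) abort("`m` must be >= 1.")
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE)) {
    abort("`raw_p` must lie in [0, 1].")
  }
  # -expm1(m*log1p(-p)) is 1-(1-p)^m without the cancellation that would
  # otherwise let the adjusted value dip below the raw p at m = 1
  adj <- -expm1(m * log1p(-raw_p))
  adj[raw_p == 1] <- 1
  pmax(raw_p, pmin(1, adj))
}

#' Pairwise group comparisons within each window
#'
#' For every window and every pair of groups, compares the group means with a
#' two-sample t statistic that pools the residual mean square of the balanced
#' two-way ANOVA as its variance estimate, on the ANOVA's residual degrees of
#' freedom. Raw p values are Sidak-adjusted over the whole family (windows x
#' group pairs) and classified at the 0.05 (significant) and 0.1 (tendency)
#' levels.
#'
#' @inheritParams two_way_anova
#' @param alpha,alpha_tendency Classification levels, defaults 0.05 and 0.1
#'   (applied to the adjusted p values).
#' @return A tibble with one row per window x group pair: `window`,
#'   `contrast`, `estimate` (difference of means, first minus second),
#'   `p_raw`, `p_sidak`, `significant`, `tendency`.
#' @export
pairwise_group_comparisons <- function(data, response = "pct_change",
                                       factor_a = "group",
                                       factor_b = "window",
                                       alpha = 0.05, alpha_tendency = 0.1) {
  fit <- two_way_anova(data, response, factor_a, factor_b)
  ga <- fit$levels_a
  pairs <- utils::combn(ga, 2, simplify = FALSE)
  m <- length(pairs) * length(fit$levels_b)
  se <- sqrt(fit$ms_res * 2 / fit$n_per_cell)
  out <- purrr::map_dfr(fit$levels_b, function(w) {
    purrr::map_dfr(pairs, function(pr) {
      diff <- fit$cell_means[pr[1], w] - fit$cell_means[pr[2], w]
      tstat <- diff / se
      tibble::tibble(
        window = w,
        contrast = paste(pr[1], "vs", pr[2]),
        estimate = diff,
        p_raw = 2 * pt(-abs(tstat), fit$df_res)
      )
    })
  })
  out |>
    dplyr::mutate(
      p_sidak = sidak_adjust(.data$p_raw, m),
      significant = .data$p_sidak < alpha,
      tendency = .data$p_sidak < alpha_tendency
    )
}
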