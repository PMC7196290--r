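#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator over a cohort, with log-log (Greenwood) confidence
#' intervals and the conventional median (first time the survival curve drops
#' to 0.5 or below).
#'
#' @param records Tibble with columns `time` (> 0, days) and `event`
#'   (1 = observed, 0 = censored).
#' @param conf_level Confidence level for the pointwise CI.
#' @return A `ctc_km` object wrapping the [survival::survfit] fit; `tidy()`
#'   gives the step function and `glance()` the median with CI (reported in
#'   months, 30.44 days each, alongside days).
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  assert_cols(records, c("time", "event"), "survival records")
  if (nrow(records) == 0) abort("no survival records")
  if (any(records$time <= 0)) abort("survival times must be positive")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0/1")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = records, conf.type = "log-log", conf.int = conf_level
  )
  structure(list(fit = fit, records = records, conf_level = conf_level),
            class = "ctc_km")
}

#' @export
print.ctc_km <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ctc_km> %d subjects, %d events; median %s days (%s months)\n",
              g$n, g$n_events,
              ifelse(is.na(g$median_days), "not reached", format(g$median_days)),
              ifelse(is.na(g$median_months), "-", format(round(g$median_months, 1)))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ctc_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, surv = s$surv,
    conf_low = s$lower, conf_high = s$upper
  )
}

#' @exportS3Method generics::glance
glance.ctc_km <- function(x, ...) {
  tb <- summary(x$fit)$table
  # median = first time the survival curve reaches 0.5 or below
  steps <- tidy(x)
  at_half <- steps$time[steps$surv <= 0.5]
  med <- if (length(at_half) > 0) min(at_half) else NA_real_
  tibble(
    n = unname(tb["records"]), n_events = unname(tb["events"]),
    median_days = med,
    median_months = med / 30.44,
    conf_low_days = unname(tb["0.95LCL"]),
    conf_high_days = unname(tb["0.95UCL"])
  )
}

#' Log-rank test between two survival groups
#'
#' Standard (unweighted) log-rank test with one degree of freedom; the
#' statistic is invariant to which group is called which.
#'
#' @param records Tibble with `time`, `event` and a grouping column.
#' @param group Name of the grouping column (two levels).
#' @return One-row tibble: `statistic` (chi-square), `df`, `p_value`, and the
#'   per-group observed/expected event counts as a nested list column.
#' @export
logrank_test <- function(records, group = "group") {
  assert_cols(records, c("time", "event", group), "survival records")
  g <- factor(records[[group]])
  if (nlevels(g) != 2) abort("log-rank comparison needs exactly 2 groups")
  if (sum(records$event) == 0) abort("no events in either group")
  dat <- tibble(time = records$time, event = records$event, g = g)
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  p <- stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE)
  tibble(
    statistic = unname(fit$chisq), df = 1, p_value = p,
    observed = list(setNames(fit$obs, levels(g))),
    expected = list(setNames(fit$exp, levels(g)))
  )
}

#' Split a cohort at a baseline-count cutoff
#'
#' CTC-High is defined strictly: baseline count greater than the cutoff;
#' counts equal to the cutoff stay Low.
#'
#' @param records Tibble with a `baseline_count_75` column.
#' @param cutoff Cutoff in CTCs per 7.5 mL.
#' @return `records` with an added `ctc_group` factor (High/Low); group sizes
#'   and percentages are attached as the `group_sizes` attribute.
#' @export
dichotomize <- function(records, cutoff) {
  assert_cols(records, "baseline_count_75", "survival records")
  if (!is.finite(cutoff)) abort("`cutoff` must be finite")
  out <- records %>%
    mutate(ctc_group = factor(if_else(.data$baseline_count_75 > cutoff,
                                      "High", "Low"),
                              levels = c("High", "Low")))
  sizes <- table(out$ctc_group)
  attr(out, "group_sizes") <- tibble(
    ctc_group = names(sizes), n = as.integer(sizes),
    pct = 100 * as.integer(sizes) / nrow(out)
  )
  out
}

#' Search for the baseline-count cutoff minimizing the log-rank p-value
#'
#' Every distinct baseline count is tried as a cutoff (High = count strictly
#' above it); cutoffs that leave either group under `min_group_frac` of the
#' cohort are skipped, and the cutoff with the smallest log-rank p-value is
#' returned together with the whole grid. Because the cutoff is chosen to
#' minimize p, the winning p-value is exploratory (optimistically biased) and
#' is flagged as such; it must not be read as a confirmatory test.
#'
#' @param records Tibble with `time`, `event`, `baseline_count_75`.
#' @param min_group_frac Smallest admissible group, as a fraction of n.
#' @return A `ctc_cutoff_search` object; `glance()` gives the best row,
#'   `tidy()` the full grid.
#' @export
optimal_cutoff_search <- function(records, min_group_frac = 0.1) {
  assert_cols(records, c("time", "event", "baseline_count_75"),
              "survival records")
  counts <- sort(unique(records$baseline_count_75))
  if (length(counts) < 2) abort("need >= 2 distinct baseline counts to split on")
  n <- nrow(records)
  min_n <- ceiling(min_group_frac * n)
  grid <- purrr::map_dfr(counts, function(cutoff) {
    high <- records$baseline_count_75 > cutoff
    n_high <- sum(high)
    n_low <- n - n_high
    if (n_high < min_n || n_low < min_n) return(NULL)
    dat <- records %>% mutate(g = if_else(high, "High", "Low"))
    if (sum(dat$event) == 0) return(NULL)
    lr <- logrank_test(dat, "g")
    tibble(cutoff = cutoff, p_value = lr$p_value,
           statistic = lr$statistic, n_high = n_high, n_low = n_low)
  })
  if (is.null(grid) || nrow(grid) == 0) {
    abort("no admissible cutoff (every split violates the group-size guard)")
  }
  best <- grid[which.min(grid$p_value), ]
  structure(list(
    best_cutoff = best$cutoff, best_p = best$p_value,
    n_high = best$n_high, n_low = best$n_low, grid = grid,
    min_group_frac = min_group_frac, n = n
  ), class = "ctc_cutoff_search")
}

#' @export
print.ctc_cutoff_search <- function(x, ...) {
  cat(sprintf(
    "<ctc_cutoff_search> best cutoff %s CTCs/7.5 mL: log-rank p = %.4g (exploratory: minimal-p selection)\n  High n = %d (%.1f%%), Low n = %d (%.1f%%); grid of %d admissible cutoffs\n",
    format(x$best_cutoff), x$best_p,
    x$n_high, 100 * x$n_high / x$n, x$n_low, 100 * x$n_low / x$n,
    nrow(x$grid)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ctc_cutoff_search <- function(x, ...) x$grid

#' @exportS3Method generics::glance
glance.ctc_cutoff_search <- function(x, ...) {
  tibble(best_cutoff = x$best_cutoff, best_p = x$best_p,
         n_high = x$n_high, n_low = x$n_low, n = x$n,
         pct_high = 100 * x$n_high / x$n,
         exploratory = TRUE)
}
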