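#' Normalize a CTC count to the 7.5 mL reporting basis
#'
#' Counts from draws of any blood volume are reported per 7.5 mL, the
#' conventional basis for CTC enumeration; a 3 mL draw is scaled by 2.5,
#' which is why half-integer counts such as 57.5 appear in reports.
#'
#' @param raw_count Non-negative cell count(s) observed in the draw.
#' @param volume_mL Blood volume(s) of the draw in mL.
#' @return `raw_count * 7.5 / volume_mL`, vectorized.
#' @examples
#' normalize_count(23, 3)   # 57.5 per 7.5 mL
#' @export
normalize_count <- function(raw_count, volume_mL) {
  if (any(volume_mL <= 0)) abort("`volume_mL` must be positive")
  if (any(raw_count < 0)) abort("`raw_count` must be non-negative")
  raw_count * 7.5 / volume_mL
}

#' Per-draw CTC change ratio relative to baseline
#'
#' For each patient, the change ratio at draw i is
#' `100 * (CTC_i - CTC_0) / CTC_0` percent, where CTC_0 is the day-0
#' baseline count. The statistic is invariant to the volume basis, so raw
#' and per-7.5 mL counts give the same value. Patients with a zero baseline
#' have an undefined ratio and are excluded with a warning rather than
#' smoothed with a pseudo-count.
#'
#' @param counts Tibble with columns `patient_id`, `day`, `raw_count`,
#'   `volume_mL`; each patient must include a day-0 baseline draw.
#' @return Tibble `patient_id`, `day`, `count_75`, `delta_ctc` (percent).
#' @export
ctc_change_ratio <- function(counts) {
  assert_cols(counts, c("patient_id", "day", "raw_count", "volume_mL"),
              "CTC count tibble")
  dup <- counts %>% dplyr::count(.data$patient_id, .data$day) %>% filter(n > 1)
  if (nrow(dup) > 0) abort("duplicate (patient, day) draws in the count table")
  no_baseline <- counts %>%
    group_by(.data$patient_id) %>%
    summarise(has0 = any(.data$day == 0), .groups = "drop") %>%
    filter(!.data$has0)
  if (nrow(no_baseline) > 0) {
    abort(sprintf("patient(s) missing a day-0 baseline draw: %s",
                  paste(no_baseline$patient_id, collapse = ", ")))
  }
  out <- counts %>%
    mutate(count_75 = normalize_count(.data$raw_count, .data$volume_mL)) %>%
    group_by(.data$patient_id) %>%
    mutate(.baseline = .data$count_75[.data$day == 0]) %>%
    ungroup()
  zero_base <- unique(out$patient_id[out$.baseline == 0])
  if (length(zero_base) > 0) {
    warn(sprintf("zero baseline count; change ratio undefined, patient(s) dropped: %s",
                 paste(zero_base, collapse = ", ")))
    out <- filter(out, !.data$patient_id %in% zero_base)
  }
  out %>%
    arrange(.data$patient_id, .data$day) %>%
    mutate(delta_ctc = 100 * (.data$count_75 - .data$.baseline) / .data$.baseline) %>%
    select("patient_id", "day", "count_75", "delta_ctc")
}

#' Pair CTC draws with the nearest radiographic assessment
#'
#' Each draw is matched to the patient's nearest-in-time RECIST assessment
#' within `max_gap_days`; at an exact tie the earlier scan wins. Draws with
#' no assessment inside the window get `NA` and are excluded from group
#' comparisons downstream.
#'
#' @param deltas Output of [ctc_change_ratio()].
#' @param assessments Tibble `patient_id`, `day`, `category` with categories
#'   from the RECIST 1.1 set (CR, PR, SD, PD).
#' @param max_gap_days Widest draw-to-scan gap still considered a match.
#'   Scans are typically acquired every two or three 3-week cycles, so the
#'   default 45 days spans half a scan interval.
#' @return `deltas` with an added `matched_response` column.
#' @export
pair_delta_with_response <- function(deltas, assessments, max_gap_days = 45) {
  assert_cols(deltas, c("patient_id", "day", "delta_ctc"), "delta-CTC tibble")
  assert_cols(assessments, c("patient_id", "day", "category"), "assessment tibble")
  bad <- setdiff(unique(assessments$category), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0) {
    abort(sprintf("assessment categories outside RECIST 1.1 set: %s",
                  paste(bad, collapse = ", ")))
  }
  match_one <- function(pid, day) {
    cand <- assessments[assessments$patient_id == pid, ]
    if (nrow(cand) == 0) return(NA_character_)
    gap <- abs(cand$day - day)
    ok <- gap <= max_gap_days
    if (!any(ok)) return(NA_character_)
    cand <- cand[ok, ]
    gap <- gap[ok]
    # nearest scan; ties broken toward the earlier scan day
    cand <- cand[order(gap, cand$day), ]
    cand$category[1]
  }
  deltas %>%
    mutate(matched_response = purrr::map2_chr(.data$patient_id, .data$day, match_one))
}

#' Compare CTC change rates between response groups
#'
#' Two-sample Student's t-test (pooled variance by default, matching the
#' classical two-tailed test; Welch available via `var_equal = FALSE`) of the
#' per-draw change ratios between two RECIST response groups, typically PD
#' versus PR.
#'
#' @param paired Output of [pair_delta_with_response()]; only follow-up draws
#'   (`day > 0`) in the two groups enter the test.
#' @param groups Length-2 character vector of response categories to compare.
#' @param var_equal Use the pooled-variance statistic (default) or Welch.
#' @return One-row tibble: group means and sizes, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_response_groups <- function(paired, groups = c("PD", "PR"),
                                    var_equal = TRUE) {
  assert_cols(paired, c("day", "delta_ctc", "matched_response"),
              "paired delta-CTC tibble")
  if (length(groups) != 2) abort("`groups` must name exactly two categories")
  dat <- paired %>%
    filter(.data$day > 0, .data$matched_response %in% groups)
  n_by <- table(factor(dat$matched_response, levels = groups))
  if (any(n_by < 2)) {
    abort(sprintf("each group needs >= 2 observations (got %s)",
                  paste(sprintf("%s: %d", names(n_by), n_by), collapse = ", ")))
  }
  a <- dat$delta_ctc[dat$matched_response == groups[1]]
  b <- dat$delta_ctc[dat$matched_response == groups[2]]
  fit <- t.test(a, b, var.equal = var_equal)
  tibble(
    group_a = groups[1], group_b = groups[2],
    mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b),
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value
  )
}
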