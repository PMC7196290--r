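#' Tissue-versus-CTC mutation concordance
#'
#' A sample is concordant when its CTC call equals the matched tissue call at
#' every assayed locus; the rate is the percentage of concordant samples.
#' Per-locus agreement rates are reported alongside for transparency.
#'
#' @param calls Long tibble with columns `sample_id`, `patient_id`, `stage`,
#'   `locus`, `tissue_call`, `ctc_call`; calls are `"+"` or `"-"`.
#' @return A `ctc_concordance` object; `glance()` gives the one-row summary,
#'   `tidy()` the per-sample calls.
#' @examples
#' glance(concordance_rate(egfr_call_fixture()))
#' @export
concordance_rate <- function(calls) {
  assert_cols(calls, c("sample_id", "locus", "tissue_call", "ctc_call"),
              "mutation call table")
  if (nrow(calls) == 0) abort("empty mutation call table")
  if (anyNA(calls$tissue_call) || anyNA(calls$ctc_call)) {
    abort("missing tissue or CTC call")
  }
  bad <- setdiff(unique(c(calls$tissue_call, calls$ctc_call)), c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("calls must be '+' or '-'; found: %s", paste(bad, collapse = ", ")))
  }
  per_sample <- calls %>%
    group_by(.data$sample_id) %>%
    summarise(concordant = all(.data$tissue_call == .data$ctc_call),
              .groups = "drop")
  per_locus <- calls %>%
    group_by(.data$locus) %>%
    summarise(rate = 100 * mean(.data$tissue_call == .data$ctc_call),
              n = n(), .groups = "drop")
  structure(list(
    n_samples = nrow(per_sample),
    n_concordant = sum(per_sample$concordant),
    rate = 100 * mean(per_sample$concordant),
    per_sample = per_sample, per_locus = per_locus
  ), class = "ctc_concordance")
}

#' @export
print.ctc_concordance <- function(x, ...) {
  cat(sprintf("<ctc_concordance> %d/%d samples concordant (%.4g%%)\n",
              x$n_concordant, x$n_samples, x$rate))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ctc_concordance <- function(x, ...) x$per_sample

#' @exportS3Method generics::glance
glance.ctc_concordance <- function(x, ...) {
  tibble(n_samples = x$n_samples, n_concordant = x$n_concordant, rate = x$rate)
}

#' Detect mutations emerging between longitudinal samples
#'
#' For each patient with samples at more than one treatment stage, flags loci
#' that were negative in both tissue and CTC at an earlier stage and positive
#' in either modality at a later one -- the pattern of an acquired resistance
#' mutation such as EGFR T790M appearing at relapse.
#'
#' @param calls Long mutation call tibble (see [concordance_rate()]).
#' @param stage_levels Temporal ordering of the stage labels; defaults to
#'   before-treatment then at-relapse.
#' @return Tibble `patient_id`, `locus`, `from_stage`, `to_stage`, `modality`
#'   (`"tissue"`, `"CTC"` or `"both"`); zero rows when nothing emerges.
#' @export
detect_emergent <- function(calls, stage_levels = c("BT", "AR")) {
  assert_cols(calls, c("patient_id", "stage", "locus", "tissue_call", "ctc_call"),
              "mutation call table")
  calls <- calls %>%
    mutate(.stage_rank = match(.data$stage, stage_levels))
  if (anyNA(calls$.stage_rank)) {
    abort(sprintf("stage label(s) outside `stage_levels`: %s",
                  paste(setdiff(unique(calls$stage), stage_levels), collapse = ", ")))
  }
  calls %>%
    group_by(.data$patient_id, .data$locus) %>%
    filter(dplyr::n_distinct(.data$.stage_rank) >= 2) %>%
    arrange(.data$.stage_rank, .by_group = TRUE) %>%
    summarise(
      from_stage = first(.data$stage),
      to_stage = dplyr::last(.data$stage),
      was_negative = first(.data$tissue_call) == "-" & first(.data$ctc_call) == "-",
      tissue_gain = dplyr::last(.data$tissue_call) == "+",
      ctc_gain = dplyr::last(.data$ctc_call) == "+",
      .groups = "drop"
    ) %>%
    filter(.data$was_negative, .data$tissue_gain | .data$ctc_gain) %>%
    mutate(modality = dplyr::case_when(
      .data$tissue_gain & .data$ctc_gain ~ "both",
      .data$tissue_gain ~ "tissue",
      TRUE ~ "CTC"
    )) %>%
    select("patient_id", "locus", "from_stage", "to_stage", "modality")
}

#' Bundled EGFR mutation call table (15 samples, 13 NSCLC patients)
#'
#' Paired tissue/CTC EGFR mutation calls from a published prospective NSCLC
#' cohort: 15 samples from 13 patients, each assayed for an activating
#' mutation (L858R or exon-19 deletion) and the T790M resistance mutation in
#' both tumor tissue and CTCs. Two patients (LP2, LP49) contribute
#' before-treatment (BT) and at-relapse (AR) pairs in which T790M emerges at
#' relapse in both modalities; every sample is tissue/CTC concordant.
#'
#' @return Long tibble with columns `sample_id`, `patient_id`, `stage`,
#'   `locus`, `tissue_call`, `ctc_call`.
#' @examples
#' detect_emergent(egfr_call_fixture())
#' @export
egfr_call_fixture <- function() {
  path <- system.file("extdata", "egfr_mutation_calls.csv", package = "ctcdx",
                      mustWork = TRUE)
  read_mutation_calls(path)
}
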