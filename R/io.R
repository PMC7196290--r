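#' Read a gene x cell Ct matrix (and optional quality sidecar) from CSV
#'
#' The wide format has gene ids in the first column and one column per cell;
#' the 999 sentinel is parsed as the undetected marker, not a Ct value. An
#' optional quality file of identical shape supplies per-entry quality
#' scores; without one, every entry gets quality 1.
#'
#' @param path CSV of Ct values.
#' @param quality_path Optional CSV of quality scores, same shape.
#' @return Long tibble `cell_id`, `gene`, `ct`, `quality` ready for
#'   [apply_quality_filter()].
#' @export
read_ct_matrix <- function(path, quality_path = NULL) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  names(wide)[1] <- "gene"
  if (anyDuplicated(wide$gene)) abort("duplicate gene ids in Ct matrix")
  if (anyDuplicated(names(wide)[-1])) abort("duplicate cell ids in Ct matrix")
  if (!all(vapply(wide[-1], is.numeric, logical(1)))) {
    abort("non-numeric Ct entries")
  }
  ct <- wide %>%
    tidyr::pivot_longer(-"gene", names_to = "cell_id", values_to = "ct") %>%
    select("cell_id", "gene", "ct")
  if (!is.null(quality_path)) {
    qwide <- readr::read_csv(quality_path, show_col_types = FALSE)
    names(qwide)[1] <- "gene"
    if (!identical(dim(qwide), dim(wide)) ||
        !identical(sort(qwide$gene), sort(wide$gene)) ||
        !identical(sort(names(qwide)), sort(names(wide)))) {
      abort(sprintf("quality file shape (%d x %d) does not match Ct matrix (%d x %d)",
                    nrow(qwide), ncol(qwide) - 1, nrow(wide), ncol(wide) - 1))
    }
    q <- qwide %>%
      tidyr::pivot_longer(-"gene", names_to = "cell_id", values_to = "quality")
    ct <- left_join(ct, q, by = c("cell_id", "gene"))
  } else {
    ct <- ct %>% mutate(quality = 1)
  }
  ct
}

#' Write a long Ct tibble back to the wide gene x cell CSV format
#'
#' @param ct Long tibble `cell_id`, `gene`, `ct` (and optionally `quality`).
#' @param path Destination for the Ct values.
#' @param quality_path Optional destination for the quality sidecar.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(ct, path, quality_path = NULL) {
  assert_cols(ct, c("cell_id", "gene", "ct"), "Ct tibble")
  wide <- ct %>%
    select("gene", "cell_id", "ct") %>%
    tidyr::pivot_wider(names_from = "cell_id", values_from = "ct")
  readr::write_csv(wide, path)
  if (!is.null(quality_path)) {
    assert_cols(ct, "quality", "Ct tibble (for the quality sidecar)")
    qwide <- ct %>%
      select("gene", "cell_id", "quality") %>%
      tidyr::pivot_wider(names_from = "cell_id", values_from = "quality")
    readr::write_csv(qwide, quality_path)
  }
  invisible(path)
}

read_checked <- function(path, required, what) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, required, what)
  x
}

#' Readers for the tabular pipeline inputs
#'
#' Thin validated CSV readers: CTC draw counts (`patient_id`, `day`,
#' `raw_count`, `volume_mL`), RECIST assessments (`patient_id`, `day`,
#' `category`), survival records (`patient_id`, `time`, `event`,
#' `baseline_count_75`), and long-format mutation calls (`sample_id`,
#' `patient_id`, `stage`, `locus`, `tissue_call`, `ctc_call`).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_ctc_counts <- function(path) {
  read_checked(path, c("patient_id", "day", "raw_count", "volume_mL"),
               "CTC count CSV")
}

#' @rdname readers
#' @export
read_response_assessments <- function(path) {
  read_checked(path, c("patient_id", "day", "category"), "assessment CSV")
}

#' @rdname readers
#' @export
read_survival_records <- function(path) {
  read_checked(path, c("patient_id", "time", "event", "baseline_count_75"),
               "survival CSV")
}

#' @rdname readers
#' @export
read_mutation_calls <- function(path) {
  read_checked(path, c("sample_id", "patient_id", "stage", "locus",
                       "tissue_call", "ctc_call"),
               "mutation call CSV")
}

#' Run the full pipeline end-to-end on a synthetic cohort
#'
#' One-call demonstration and smoke test: generates a cohort with
#' [cohort_config()] defaults under the given seed, runs preprocessing,
#' EMT scoring, clustering, the embedding, kinetics, the survival cutoff
#' search and concordance, and returns (optionally writes) every stage
#' summary.
#'
#' @param seed Master seed for all generators.
#' @param outdir Optional directory; when given, stage outputs are written
#'   there as CSVs.
#' @param config Optional [cohort_config()] overriding the defaults (its
#'   seed is replaced by `seed`).
#' @return Named list of stage results.
#' @export
run_demo_pipeline <- function(seed = 1L, outdir = NULL, config = NULL) {
  config <- config %||% cohort_config(seed = seed)
  config$seed <- as.integer(seed)

  sc <- sim_ct_matrix(config)
  filtered <- apply_quality_filter(sc$ct)
  imputed <- impute_undetected(filtered)
  rel <- relative_expression(delta_ct(imputed, config$reference_gene))
  zs <- zscore_transform(imputed)

  scores <- classify_emt(compute_emt_scores(rel))
  group_scores <- summarize_group_scores(
    scores, sc$annotations %>% rename(group = "group"))

  clust <- hierarchical_cluster(zs, k = length(config$groups))
  emb <- tsne_embed(zs, perplexity = 5, seed = config$seed)

  traj <- sim_ctc_trajectories(config)
  deltas <- ctc_change_ratio(traj$counts)
  paired <- pair_delta_with_response(deltas, traj$assessments)
  kinetics <- compare_response_groups(paired)

  surv <- sim_survival_cohort(config)
  km <- km_estimate(surv)
  cutoff <- optimal_cutoff_search(surv)

  calls <- egfr_call_fixture()
  conc <- concordance_rate(calls)
  emergent <- detect_emergent(calls)

  results <- list(
    config = config,
    filtered_entries = sum(filtered$ct == CT_UNDETECTED) - sum(sc$ct$ct == CT_UNDETECTED),
    emt_scores = scores, group_scores = group_scores,
    clustering = clust, embedding = emb,
    delta_ctc = paired, kinetics = kinetics,
    km = km, cutoff_search = cutoff,
    concordance = conc, emergent = emergent
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(scores, file.path(outdir, "emt_scores.csv"))
    readr::write_csv(group_scores, file.path(outdir, "group_scores.csv"))
    readr::write_csv(paired, file.path(outdir, "delta_ctc.csv"))
    readr::write_csv(kinetics, file.path(outdir, "kinetics_test.csv"))
    readr::write_csv(tidy(cutoff), file.path(outdir, "cutoff_grid.csv"))
    readr::write_csv(glance(conc), file.path(outdir, "concordance.csv"))
    readr::write_csv(emergent, file.path(outdir, "emergent.csv"))
  }
  results
}
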