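#' Apply instrument quality thresholds to a single-cell Ct matrix
#'
#' Entries whose amplification quality score falls below `quality_min`, or
#' whose Ct exceeds `ct_max`, are treated as undetected and set to the 999
#' sentinel. The defaults (quality >= 0.65, Ct <= 30) are the conventional
#' thresholds for microfluidic single-cell qRT-PCR.
#'
#' @param ct Long tibble with columns `cell_id`, `gene`, `ct` and `quality`
#'   (quality scores in \[0, 1\], higher is better).
#' @param quality_min Minimum acceptable quality score; entries below it are
#'   dropped (set to the sentinel).
#' @param ct_max Maximum acceptable Ct; later cycles are considered noise.
#' @return The same tibble with failing entries set to `CT_UNDETECTED`,
#'   tagged with stage `"filtered_ct"`.
#' @examples
#' ct <- tibble::tibble(cell_id = "c1", gene = c("GAPDH", "VIM"),
#'                      ct = c(18, 31), quality = c(0.9, 0.9))
#' apply_quality_filter(ct)
#' @export
apply_quality_filter <- function(ct, quality_min = 0.65, ct_max = 30) {
  assert_cols(ct, c("cell_id", "gene", "ct", "quality"), "Ct tibble")
  if (!is.finite(quality_min) || quality_min < 0 || quality_min > 1) {
    abort("`quality_min` must be a finite probability in [0, 1]")
  }
  if (!is.finite(ct_max)) abort("`ct_max` must be finite")
  bad_ct <- ct$ct[!(ct$ct == CT_UNDETECTED | (ct$ct > 0 & ct$ct <= 45))]
  if (length(bad_ct) > 0) {
    abort(sprintf("Ct values must lie in (0, 45] or be the 999 sentinel; found %s",
                  paste(head(bad_ct, 3), collapse = ", ")))
  }
  if (any(ct$quality < 0 | ct$quality > 1)) {
    abort("quality scores must lie in [0, 1]")
  }
  out <- ct %>%
    mutate(ct = if_else(.data$quality < quality_min | .data$ct > ct_max,
                        CT_UNDETECTED, .data$ct))
  set_stage(out, "filtered_ct")
}

#' Impute undetected Ct values
#'
#' Each undetected (sentinel) entry of a gene is replaced by the highest Ct
#' observed for that gene plus one cycle, so that missing measurements carry
#' the lowest expression weight seen for the gene rather than dominating or
#' vanishing. A gene undetected in every cell has no observed maximum; such
#' genes fall back to the global detected maximum plus one (reported via a
#' message and the `all_undetected_genes` attribute).
#'
#' @param ct Quality-filtered Ct tibble (stage `"filtered_ct"`), or an already
#'   imputed tibble, in which case it is returned unchanged (the operation is
#'   idempotent).
#' @return Tibble with columns `cell_id`, `gene`, `value` (imputed Ct),
#'   stage `"imputed_ct"`.
#' @export
impute_undetected <- function(ct) {
  if (identical(expr_stage(ct), "imputed_ct")) return(ct)
  assert_stage(ct, "filtered_ct", "impute_undetected")
  if (nrow(ct) == 0) abort("cannot impute an empty Ct matrix")
  detected <- ct$ct != CT_UNDETECTED
  if (!any(detected)) abort("no detected entries anywhere; nothing to anchor imputation")
  global_max <- max(ct$ct[detected])
  out <- ct %>%
    group_by(.data$gene) %>%
    mutate(
      .gene_max = if (any(.data$ct != CT_UNDETECTED))
        max(.data$ct[.data$ct != CT_UNDETECTED]) else NA_real_,
      value = if_else(.data$ct == CT_UNDETECTED,
                      dplyr::coalesce(.data$.gene_max, global_max) + 1,
                      .data$ct)
    ) %>%
    ungroup()
  all_missing <- unique(out$gene[is.na(out$.gene_max)])
  if (length(all_missing) > 0) {
    inform(sprintf(
      "gene(s) undetected in every cell imputed from the global maximum (%s + 1): %s",
      format(global_max), paste(all_missing, collapse = ", ")))
  }
  out <- out %>% select("cell_id", "gene", "value")
  out <- set_stage(out, "imputed_ct")
  attr(out, "all_undetected_genes") <- all_missing
  out
}

#' Normalize Ct values to a reference gene (delta-Ct)
#'
#' Subtracts the reference-gene Ct of the same cell from every gene's Ct:
#' dCt(g, c) = Ct(g, c) - Ct(ref, c). Lower dCt means higher expression
#' relative to the reference.
#'
#' @param expr Imputed-Ct tibble (stage `"imputed_ct"`).
#' @param reference_gene Housekeeping gene used as the per-cell anchor
#'   (default `"GAPDH"`).
#' @return Tibble at stage `"delta_ct"`; the reference gene's own row is zero
#'   in every cell.
#' @export
delta_ct <- function(expr, reference_gene = "GAPDH") {
  assert_stage(expr, "imputed_ct", "delta_ct")
  if (!reference_gene %in% expr$gene) {
    abort(sprintf("reference gene '%s' not present in the matrix", reference_gene))
  }
  ref <- expr %>%
    filter(.data$gene == reference_gene) %>%
    select("cell_id", ref_ct = "value")
  out <- expr %>%
    left_join(ref, by = "cell_id") %>%
    mutate(value = .data$value - .data$ref_ct) %>%
    select("cell_id", "gene", "value")
  out <- set_stage(out, "delta_ct")
  attr(out, "reference_gene") <- reference_gene
  out
}

#' Convert delta-Ct to relative expression (2^-dCt)
#'
#' @param expr Tibble at stage `"delta_ct"`.
#' @return Tibble at stage `"relative_expr"`; values are strictly positive,
#'   with 1 meaning expression equal to the reference gene.
#' @export
relative_expression <- function(expr) {
  assert_stage(expr, "delta_ct", "relative_expression")
  out <- expr %>% mutate(value = 2^(-.data$value))
  out <- set_stage(out, "relative_expr")
  attr(out, "reference_gene") <- attr(expr, "reference_gene")
  out
}

#' Z-score imputed Ct values per gene
#'
#' Mean-centers each gene across cells and divides by the sample standard
#' deviation (n - 1), so every gene contributes on the same scale to
#' clustering and embedding. Genes with zero variance map to z = 0 and are
#' reported in the `constant_genes` attribute.
#'
#' @param expr Imputed-Ct tibble (stage `"imputed_ct"`). Z-scores are taken on
#'   imputed Ct directly; the delta-Ct branch is reserved for EMT scoring.
#' @return Tibble at stage `"zscore"`.
#' @export
zscore_transform <- function(expr) {
  assert_stage(expr, "imputed_ct", "zscore_transform")
  n_cells <- dplyr::n_distinct(expr$cell_id)
  if (n_cells < 2) abort("Z-scoring needs at least 2 cells (SD undefined for 1)")
  out <- expr %>%
    group_by(.data$gene) %>%
    mutate(
      .sd = sd(.data$value),
      value = if_else(.data$.sd > 0, (.data$value - mean(.data$value)) / .data$.sd, 0)
    ) %>%
    ungroup()
  constant <- unique(out$gene[out$.sd == 0])
  if (length(constant) > 0) {
    inform(sprintf("constant gene(s) mapped to z = 0: %s",
                   paste(constant, collapse = ", ")))
  }
  out <- out %>% select("cell_id", "gene", "value")
  out <- set_stage(out, "zscore")
  attr(out, "constant_genes") <- constant
  out
}

#' Classify stained events as CTC, WBC or excluded
#'
#' Implements the immunofluorescence gating rule used for CTC enumeration:
#' an event positive for cytokeratin or EpCAM, negative for CD45, and with a
#' DAPI-stained nucleus is a circulating tumor cell; any CD45-positive event
#' is a white blood cell; everything else is excluded.
#'
#' @param events Tibble with logical columns `ck_epcam`, `cd45`, `dapi`.
#' @return The tibble with an added `event_class` column
#'   (`"CTC"`, `"WBC"` or `"excluded"`).
#' @examples
#' classify_event(tibble::tibble(ck_epcam = TRUE, cd45 = FALSE, dapi = TRUE))
#' @export
classify_event <- function(events) {
  assert_cols(events, c("ck_epcam", "cd45", "dapi"), "event tibble")
  flags <- events[, c("ck_epcam", "cd45", "dapi")]
  if (anyNA(flags)) abort("stain flags must not be missing")
  events %>%
    mutate(event_class = dplyr::case_when(
      .data$cd45 ~ "WBC",
      .data$ck_epcam & !.data$cd45 & .data$dapi ~ "CTC",
      TRUE ~ "excluded"
    ))
}
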