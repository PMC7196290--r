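#' Define an epithelial/mesenchymal marker panel
#'
#' The default panel follows the usual NSCLC CTC convention: EpCAM plus the
#' cytokeratins KRT7/KRT18/KRT19 on the epithelial side, vimentin and CD44 on
#' the mesenchymal side, with GAPDH as the normalization reference.
#'
#' @param epithelial,mesenchymal Character vectors of marker genes; the two
#'   sets must be disjoint, non-empty, and exclude the reference gene.
#' @param reference Reference (housekeeping) gene.
#' @return A `marker_panel` object.
#' @export
marker_panel <- function(epithelial = c("EpCAM", "KRT7", "KRT18", "KRT19"),
                         mesenchymal = c("VIM", "CD44"),
                         reference = "GAPDH") {
  if (length(epithelial) == 0 || length(mesenchymal) == 0) {
    abort("both marker sets must be non-empty")
  }
  if (length(intersect(epithelial, mesenchymal)) > 0) {
    abort("epithelial and mesenchymal marker sets must be disjoint")
  }
  if (reference %in% c(epithelial, mesenchymal)) {
    abort("the reference gene cannot be a scored marker")
  }
  structure(list(epithelial = epithelial, mesenchymal = mesenchymal,
                 reference = reference),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n",
      " epithelial:  ", paste(x$epithelial, collapse = ", "), "\n",
      " mesenchymal: ", paste(x$mesenchymal, collapse = ", "), "\n",
      " reference:   ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Score cells along the epithelial-mesenchymal axis
#'
#' For each cell the GAPDH-normalized relative expressions (2^-dCt) of the
#' epithelial markers are summed into `e_sum` and those of the mesenchymal
#' markers into `m_sum`; the M-score is the mesenchymal share of the total,
#' `m_score = 100 * m_sum / (e_sum + m_sum)`, and `e_score = 100 - m_score`.
#' A cell expressing mesenchymal markers k times as strongly as epithelial
#' ones therefore scores 100k/(1+k).
#'
#' @param expr Relative-expression tibble (stage `"relative_expr"`).
#' @param panel A [marker_panel()].
#' @return Tibble with one row per cell: `cell_id`, `e_sum`, `m_sum`,
#'   `e_score`, `m_score`. Cells whose marker total is zero get `NA` scores
#'   and are listed in the `undefined_cells` attribute.
#' @export
compute_emt_scores <- function(expr, panel = marker_panel()) {
  assert_stage(expr, "relative_expr", "compute_emt_scores")
  stopifnot(inherits(panel, "marker_panel"))
  markers <- c(panel$epithelial, panel$mesenchymal)
  missing <- setdiff(markers, unique(expr$gene))
  if (length(missing) > 0) {
    abort(sprintf("panel marker(s) absent from the matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  scores <- expr %>%
    filter(.data$gene %in% markers) %>%
    group_by(.data$cell_id) %>%
    summarise(
      e_sum = sum(.data$value[.data$gene %in% panel$epithelial]),
      m_sum = sum(.data$value[.data$gene %in% panel$mesenchymal]),
      .groups = "drop"
    ) %>%
    mutate(
      total = .data$e_sum + .data$m_sum,
      m_score = if_else(.data$total > 0, 100 * .data$m_sum / .data$total, NA_real_),
      e_score = 100 - .data$m_score
    ) %>%
    select("cell_id", "e_sum", "m_sum", "e_score", "m_score")
  undefined <- scores$cell_id[is.na(scores$m_score)]
  if (length(undefined) > 0) {
    warn(sprintf("EMT score undefined (zero marker total) for: %s",
                 paste(undefined, collapse = ", ")))
  }
  attr(scores, "undefined_cells") <- undefined
  attr(scores, "panel") <- panel
  scores
}

#' Label cells as epithelial, mesenchymal or hybrid
#'
#' Cells with an M-score below the hybrid band are epithelial, above it
#' mesenchymal, and inside it hybrid E/M. The band is a design choice, not a
#' biological constant; the default \[40, 60\] reproduces the qualitative
#' labels usually given to strongly skewed group means while leaving a broad
#' mixed-phenotype zone.
#'
#' @param scores Output of [compute_emt_scores()].
#' @param hybrid_band Numeric length-2 vector, lower and upper M-score edges
#'   of the hybrid zone (inclusive).
#' @return `scores` with an added `label` column.
#' @export
classify_emt <- function(scores, hybrid_band = c(40, 60)) {
  assert_cols(scores, "m_score", "EMT score tibble")
  if (length(hybrid_band) != 2 || any(!is.finite(hybrid_band)) ||
      hybrid_band[1] > hybrid_band[2] ||
      hybrid_band[1] < 0 || hybrid_band[2] > 100) {
    abort("`hybrid_band` must be two ordered values inside [0, 100]")
  }
  scores %>%
    mutate(label = dplyr::case_when(
      is.na(.data$m_score) ~ NA_character_,
      .data$m_score < hybrid_band[1] ~ "epithelial",
      .data$m_score > hybrid_band[2] ~ "mesenchymal",
      TRUE ~ "hybrid"
    ))
}

#' Summarize M-scores per cell group
#'
#' Reports the arithmetic mean and sample standard deviation (n - 1) of the
#' M-score per group, the mean +/- SD convention used for cell lines and
#' per-timepoint CTC pools. Single-cell groups report `NA` SD.
#'
#' @param scores Output of [compute_emt_scores()] (optionally labelled).
#' @param groups Tibble mapping `cell_id` to `group`.
#' @return Tibble with `group`, `mean_m_score`, `sd_m_score`, `n`.
#' @export
summarize_group_scores <- function(scores, groups) {
  assert_cols(scores, c("cell_id", "m_score"), "EMT score tibble")
  assert_cols(groups, c("cell_id", "group"), "grouping tibble")
  joined <- inner_join(scores, groups, by = "cell_id")
  if (nrow(joined) == 0) abort("grouping shares no cells with the score table")
  joined %>%
    filter(!is.na(.data$m_score)) %>%
    group_by(.data$group) %>%
    summarise(
      mean_m_score = mean(.data$m_score),
      sd_m_score = if (n() > 1) sd(.data$m_score) else NA_real_,
      n = n(),
      .groups = "drop"
    )
}
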