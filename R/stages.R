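#' Expression-stage bookkeeping
#'
#' Single-cell qRT-PCR data move through a fixed sequence of transforms:
#' raw Ct -> quality-filtered Ct -> imputed Ct, then either
#' delta-Ct -> relative expression (2^-dCt) for EMT scoring, or Z-scores for
#' clustering and embedding. Each tibble produced by the pipeline carries a
#' `stage` attribute; every transform checks the stage of its input so that
#' operations cannot be applied out of order.
#'
#' @param x A tibble produced by the pipeline.
#' @return `expr_stage()` returns the stage string (or `NA` if the tibble has
#'   never been through the pipeline).
#' @examples
#' m <- sim_ct_matrix(cohort_config(cells_per_group = 3))
#' expr_stage(impute_undetected(apply_quality_filter(m$ct)))
#' @export
expr_stage <- function(x) {
  attr(x, "stage") %||% NA_character_
}

set_stage <- function(x, stage) {
  attr(x, "stage") <- stage
  x
}

assert_stage <- function(x, expected, op) {
  st <- expr_stage(x)
  if (!st %in% expected) {
    abort(sprintf(
      "`%s()` expects input at stage %s, got %s. The pipeline order is: quality filter -> imputation -> (delta-Ct -> relative expression | Z-score).",
      op, paste0("'", expected, "'", collapse = " or "),
      if (is.na(st)) "an untagged tibble" else paste0("'", st, "'")
    ))
  }
  invisible(x)
}

assert_cols <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s must have columns: %s (missing: %s)",
                  what, paste(cols, collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  invisible(x)
}

#' Sentinel Ct value marking an undetected transcript
#'
#' qPCR instruments report a reaction that never crossed the fluorescence
#' threshold with the sentinel 999 rather than a cycle number.
#' @export
CT_UNDETECTED <- 999

# long (cell_id, gene, value) -> genes x cells numeric matrix
expr_wide <- function(x, value_col = "value") {
  genes <- unique(x$gene)
  cells <- unique(x$cell_id)
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cells))
  m[cbind(match(x$gene, genes), match(x$cell_id, cells))] <- x[[value_col]]
  if (anyNA(m)) abort("expression tibble is not a complete gene x cell grid")
  m
}
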