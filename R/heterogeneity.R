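#' Hierarchical clustering of cells from Z-scored expression
#'
#' Agglomerative clustering of cells on their Z-scored gene profiles,
#' Euclidean distance and complete linkage by default (both configurable).
#'
#' @param expr Z-scored tibble (stage `"zscore"`).
#' @param distance Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param k Optional number of flat clusters to cut the tree into.
#' @return A `ctc_hclust` object: the `stats::hclust` tree, cell ids, and (if
#'   `k` was given) a tibble of flat cluster labels.
#' @export
hierarchical_cluster <- function(expr, distance = "euclidean",
                                 linkage = "complete", k = NULL) {
  assert_stage(expr, "zscore", "hierarchical_cluster")
  m <- t(expr_wide(expr))            # cells x genes
  if (nrow(m) < 2) abort("clustering needs at least 2 cells")
  if (any(!is.finite(m))) abort("non-finite values in the expression matrix")
  hc <- hclust(dist(m, method = distance), method = linkage)
  labels <- NULL
  if (!is.null(k)) {
    labels <- tibble(cell_id = rownames(m), cluster = unname(cutree(hc, k = k)))
  }
  structure(list(hclust = hc, cell_ids = rownames(m), distance = distance,
                 linkage = linkage, k = k, labels = labels),
            class = "ctc_hclust")
}

#' @export
print.ctc_hclust <- function(x, ...) {
  cat(sprintf("<ctc_hclust> %d cells, %s distance, %s linkage\n",
              length(x$cell_ids), x$distance, x$linkage))
  if (!is.null(x$labels)) {
    cat(sprintf("  cut at k = %d: sizes %s\n", x$k,
                paste(table(x$labels$cluster), collapse = "/")))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ctc_hclust <- function(x, ...) {
  hc <- x$hclust
  tibble(
    merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
    height = hc$height, step = seq_along(hc$height)
  )
}

#' Cut a clustering into k groups
#'
#' @param x A `ctc_hclust` object.
#' @param k Number of groups.
#' @return Tibble of `cell_id`, `cluster`.
#' @export
cut_clusters <- function(x, k) {
  stopifnot(inherits(x, "ctc_hclust"))
  tibble(cell_id = x$cell_ids, cluster = unname(cutree(x$hclust, k = k)))
}

#' t-SNE embedding of cells
#'
#' Exact (theta = 0) t-distributed stochastic neighbor embedding of the
#' Z-scored cell profiles into 2 or 3 dimensions. The seed is mandatory:
#' t-SNE is stochastic and runs must be reproducible.
#'
#' @param expr Z-scored tibble (stage `"zscore"`).
#' @param dims 2 or 3 output dimensions.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `perplexity < (n_cells - 1) / 3`. Default 10 suits the 20-60 cell
#'   analyses this pipeline targets.
#' @param seed Integer RNG seed.
#' @return Tibble `cell_id`, `tsne1`, `tsne2` (and `tsne3` for `dims = 3`),
#'   with `perplexity` and `seed` attributes.
#' @export
tsne_embed <- function(expr, dims = 2, perplexity = 10, seed) {
  assert_stage(expr, "zscore", "tsne_embed")
  if (missing(seed)) abort("`seed` is required: t-SNE is stochastic")
  if (!dims %in% c(2, 3)) abort("`dims` must be 2 or 3")
  m <- t(expr_wide(expr))
  n <- nrow(m)
  if (perplexity >= (n - 1) / 3) {
    abort(sprintf("perplexity %s too large for %d cells (needs < (n-1)/3 = %.2f)",
                  format(perplexity), n, (n - 1) / 3))
  }
  fit <- withr::with_seed(seed, Rtsne::Rtsne(
    m, dims = dims, perplexity = perplexity, theta = 0,
    pca = FALSE, check_duplicates = FALSE
  ))
  coords <- as_tibble(fit$Y, .name_repair = ~ paste0("tsne", seq_len(dims)))
  out <- bind_cols(tibble(cell_id = rownames(m)), coords)
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- seed
  out
}

#' Pairwise Spearman correlation between cells
#'
#' Spearman's rank correlation of gene-expression vectors for every pair of
#' cells, with two-sided p-values and Bonferroni adjustment across all pairs
#' in the matrix (the family is the matrix itself, so separate populations
#' should be passed in separate calls).
#'
#' @param expr A pipeline expression tibble at any numeric stage.
#' @param cells Optional subset of cell ids to correlate.
#' @return A `ctc_cormat` object holding `rho`, `p_raw` and `p_adj` matrices;
#'   `tidy()` returns the upper triangle as a long tibble.
#' @export
correlation_matrix <- function(expr, cells = NULL) {
  assert_cols(expr, c("cell_id", "gene", "value"), "expression tibble")
  if (!is.null(cells)) expr <- filter(expr, .data$cell_id %in% cells)
  m <- expr_wide(expr)               # genes x cells
  if (ncol(m) < 2) abort("need at least 2 cells to correlate")
  if (nrow(m) < 3) abort("need at least 3 genes per pair for a rank correlation")
  ids <- colnames(m)
  constant <- apply(m, 2, function(v) sd(v) == 0)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  n <- ncol(m)
  p_raw <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (constant[i] || constant[j]) next
      p <- suppressWarnings(
        cor.test(m[, i], m[, j], method = "spearman", exact = FALSE)$p.value)
      p_raw[i, j] <- p_raw[j, i] <- p
    }
  }
  diag(p_raw) <- 0
  n_pairs <- n * (n - 1) / 2
  p_adj <- p_raw * n_pairs
  p_adj[!is.na(p_adj) & p_adj > 1] <- 1
  diag(p_adj) <- 0
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  structure(list(ids = ids, rho = rho, p_raw = p_raw, p_adj = p_adj,
                 n_pairs = n_pairs, constant_cells = ids[constant]),
            class = "ctc_cormat")
}

#' @export
print.ctc_cormat <- function(x, ...) {
  cat(sprintf("<ctc_cormat> %d cells, %d pairs (Bonferroni family)\n",
              length(x$ids), x$n_pairs))
  if (length(x$constant_cells) > 0) {
    cat("  constant (rho undefined) cells:",
        paste(x$constant_cells, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ctc_cormat <- function(x, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    cell_a = x$ids[idx[, 1]], cell_b = x$ids[idx[, 2]],
    rho = x$rho[idx], p_raw = x$p_raw[idx], p_adj = x$p_adj[idx]
  )
}
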