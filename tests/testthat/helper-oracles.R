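# Independent oracles and small fixtures shared across the suite.
# Everything here is written from first principles (no calls into the
# package's own implementations, and none of the library routines they wrap).

# naive O(n^3) agglomerative clustering over the rows of `m`; returns merge
# heights and the flat partition at k clusters. Cluster-to-cluster distance
# follows `linkage`; ties break toward the lowest cluster indices.
naive_agglomerate <- function(m, k = 1, linkage = "complete") {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(linkage,
           complete = max(vals),
           single = min(vals),
           average = mean(vals))
  }
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dij <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dij < best[1] - 1e-12) best <- c(dij, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    partitions[[length(clusters)]] <- clusters
  }
  labels_at <- function(k) {
    part <- partitions[[k]]
    lab <- integer(nrow(m))
    for (ci in seq_along(part)) lab[part[[ci]]] <- ci
    lab
  }
  list(heights = sort(heights), labels_at = labels_at)
}

# product-limit estimator by hand
naive_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# unweighted log-rank chi-square by summing observed-minus-expected and
# hypergeometric variances over distinct event times
naive_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n1 <- sum(time >= t & g == 1); n2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    n <- n1 + n2; d <- d1 + d2
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# pooled-variance two-sample t statistic from the textbook formula
naive_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# long Ct tibble from a genes x cells matrix (quality 1 everywhere)
ct_from_matrix <- function(m, quality = 1) {
  tibble::as_tibble(m, rownames = "gene") |>
    tidyr::pivot_longer(-gene, names_to = "cell_id", values_to = "ct") |>
    dplyr::mutate(quality = quality) |>
    dplyr::select(cell_id, gene, ct, quality)
}

# quality-filter stage tag without changing any entry (all-passing fixture)
as_filtered <- function(ct) apply_quality_filter(ct, quality_min = 0, ct_max = 45)

# noise-free cohort config with an exact mesenchymal/epithelial ratio k:
# each epithelial marker at delta-Ct 3 (sum 0.5), both mesenchymal markers
# set so their relative-expression sum is exactly k * 0.5
emt_ratio_config <- function(k, ct_noise_sd = 0, cells = 20, seed = 1) {
  genes <- c("GAPDH", "EpCAM", "KRT7", "KRT18", "KRT19", "VIM", "CD44")
  dct_m <- -log2(k * 0.5 / 2)
  means <- matrix(c(0, rep(3, 4), rep(dct_m, 2)), ncol = 1,
                  dimnames = list(genes, "G1"))
  cohort_config(groups = "G1", cells_per_group = cells, genes = genes,
                group_delta_ct_means = means, ct_noise_sd = ct_noise_sd,
                dropout_base_rate = 0, dropout_ct_slope = 0,
                low_quality_frac = 0, seed = seed)
}

# four well-separated groups (block pattern, >= `sep` cycles apart on every
# informative gene)
four_group_config <- function(ct_noise_sd = 0, cells = 6, sep = 4, seed = 1) {
  genes <- c("GAPDH", paste0("g", 1:8))
  base <- matrix(8, nrow = length(genes), ncol = 4,
                 dimnames = list(genes, paste0("G", 1:4)))
  for (grp in 1:4) base[1 + (2 * grp - 1):(2 * grp), grp] <- 8 - sep
  base["GAPDH", ] <- 0
  cohort_config(groups = paste0("G", 1:4), cells_per_group = cells,
                genes = genes, group_delta_ct_means = base,
                ct_noise_sd = ct_noise_sd, dropout_base_rate = 0,
                dropout_ct_slope = 0, low_quality_frac = 0, seed = seed)
}
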