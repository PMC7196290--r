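test_that("quality filter drops entries failing either threshold and only those", {
  ct <- tibble::tibble(
    cell_id = "c1",
    gene = c("a", "b", "c", "d", "e"),
    ct = c(29.5, 31, 25, 28, 999),
    quality = c(0.9, 0.9, 0.5, 0.65, 0.9)
  )
  out <- apply_quality_filter(ct)
  expect_equal(out$ct, c(29.5, 999, 999, 28, 999))
  expect_identical(expr_stage(out), "filtered_ct")

  # identity on an all-passing matrix
  good <- tibble::tibble(cell_id = "c1", gene = letters[1:3],
                         ct = c(20, 25, 30), quality = c(0.65, 0.8, 1))
  expect_equal(apply_quality_filter(good)$ct, good$ct)
})

test_that("quality filter is monotone in quality_min", {
  set.seed(42)
  ct <- tibble::tibble(
    cell_id = rep(paste0("c", 1:5), each = 4),
    gene = rep(letters[1:4], 5),
    ct = runif(20, 15, 35),
    quality = runif(20)
  )
  dropped <- function(q) {
    out <- apply_quality_filter(ct, quality_min = q)
    out$ct == CT_UNDETECTED
  }
  prev <- dropped(0)
  for (q in seq(0.1, 1, by = 0.1)) {
    cur <- dropped(q)
    expect_true(all(cur[prev]))   # raising the bar never un-drops
    prev <- cur
  }
})

test_that("imputation replaces sentinels with per-gene max + 1", {
  m <- rbind(
    g1 = c(25, 28, 999),
    g2 = c(20, 21, 22)
  )
  colnames(m) <- paste0("c", 1:3)
  out <- impute_undetected(as_filtered(ct_from_matrix(m)))
  wide <- tidyr::pivot_wider(out, names_from = cell_id, values_from = value)
  expect_equal(unlist(wide[wide$gene == "g1", -1], use.names = FALSE),
               c(25, 28, 29))
  expect_equal(unlist(wide[wide$gene == "g2", -1], use.names = FALSE),
               c(20, 21, 22))
  expect_identical(expr_stage(out), "imputed_ct")
})

test_that("genes undetected everywhere fall back to global max + 1", {
  m <- rbind(g1 = c(999, 999), g2 = c(30.2, 25))
  colnames(m) <- c("c1", "c2")
  expect_message(
    out <- impute_undetected(as_filtered(ct_from_matrix(m))),
    "global maximum"
  )
  expect_equal(out$value[out$gene == "g1"], c(31.2, 31.2))
  expect_identical(attr(out, "all_undetected_genes"), "g1")
})

test_that("imputation is idempotent and leaves no sentinel", {
  cfg <- cohort_config(cells_per_group = 5, dropout_base_rate = 0.3, seed = 11)
  ct <- apply_quality_filter(sim_ct_matrix(cfg)$ct)
  once <- impute_undetected(ct)
  expect_false(any(once$value == CT_UNDETECTED))
  expect_identical(impute_undetected(once), once)
  # per-gene max of imputed values is detected max + 1 exactly when imputed
  by_gene <- dplyr::inner_join(
    dplyr::summarise(
      dplyr::group_by(dplyr::filter(ct, ct != CT_UNDETECTED), gene),
      det_max = max(ct)),
    dplyr::summarise(
      dplyr::group_by(dplyr::filter(
        dplyr::left_join(once, ct, by = c("cell_id", "gene")),
        ct == CT_UNDETECTED), gene),
      imp = unique(value)),
    by = "gene")
  expect_equal(by_gene$imp, by_gene$det_max + 1)
})

test_that("delta-Ct subtracts the per-cell reference and zeroes the reference row", {
  m <- rbind(GAPDH = c(20, 22), gx = c(25, 21))
  colnames(m) <- c("c1", "c2")
  out <- delta_ct(impute_undetected(as_filtered(ct_from_matrix(m))))
  expect_equal(out$value[out$gene == "gx"], c(5, -1))
  expect_equal(out$value[out$gene == "GAPDH"], c(0, 0))
  expect_error(delta_ct(impute_undetected(as_filtered(ct_from_matrix(m))), "ACTB"),
               "not present")
})

test_that("delta-Ct matches element-wise subtraction on a random matrix", {
  set.seed(5)
  m <- matrix(runif(25, 15, 30), 5, 5,
              dimnames = list(c("GAPDH", paste0("g", 1:4)), paste0("c", 1:5)))
  out <- delta_ct(impute_undetected(as_filtered(ct_from_matrix(m))))
  wide <- as.matrix(tidyr::pivot_wider(out, names_from = cell_id,
                                       values_from = value)[, -1])
  oracle <- sweep(m, 2, m["GAPDH", ])
  expect_equal(unname(wide[match(rownames(m), unique(out$gene)), colnames(m)]),
               unname(oracle), tolerance = 1e-12)
})

test_that("relative expression is 2^-dCt and enforces its stage", {
  m <- rbind(GAPDH = c(20), gx = c(25), gy = c(20), gz = c(19))
  colnames(m) <- "c1"
  dct <- delta_ct(impute_undetected(as_filtered(ct_from_matrix(m))))
  rel <- relative_expression(dct)
  vals <- setNames(rel$value, rel$gene)
  expect_equal(unname(vals[c("gx", "gy", "gz")]), c(0.03125, 1, 2))
  expect_true(all(rel$value > 0))
  expect_error(relative_expression(rel), "stage")
})

test_that("z-scores have per-gene mean 0 and sample SD 1; constants map to 0", {
  m <- rbind(GAPDH = c(20, 20, 20), g1 = c(1, 2, 3), g2 = c(7, 7, 7))
  colnames(m) <- paste0("c", 1:3)
  expect_message(
    z <- zscore_transform(impute_undetected(as_filtered(ct_from_matrix(m)))),
    "constant"
  )
  expect_equal(z$value[z$gene == "g1"], c(-1, 0, 1))
  expect_equal(z$value[z$gene == "g2"], c(0, 0, 0))

  set.seed(9)
  m2 <- matrix(rnorm(60, 22, 3), 6, 10,
               dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  z2 <- zscore_transform(impute_undetected(as_filtered(ct_from_matrix(m2))))
  stats <- dplyr::summarise(dplyr::group_by(z2, gene),
                            mu = mean(value), s = sd(value))
  expect_true(all(abs(stats$mu) < 1e-9))
  expect_true(all(abs(stats$s - 1) < 1e-9))
})

test_that("pipeline stage tags forbid out-of-order transforms", {
  ct <- tibble::tibble(cell_id = "c1", gene = c("GAPDH", "g1"),
                       ct = c(20, 25), quality = 1)
  expect_error(impute_undetected(ct), "stage")                 # unfiltered
  filtered <- apply_quality_filter(ct)
  expect_error(delta_ct(filtered), "stage")                    # not imputed
  imp <- impute_undetected(filtered)
  expect_error(relative_expression(imp), "stage")              # needs delta-Ct
  expect_error(zscore_transform(delta_ct(imp)), "stage")       # z on imputed only
})

test_that("event gating follows the CK/EpCAM+, CD45-, DAPI+ rule", {
  events <- tibble::tibble(
    ck_epcam = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    cd45 = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    dapi = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  out <- classify_event(events)
  expect_equal(out$event_class, c("CTC", "WBC", "WBC", "excluded", "excluded"))
  expect_error(classify_event(tibble::tibble(ck_epcam = TRUE, cd45 = NA,
                                             dapi = TRUE)),
               "missing")
})
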