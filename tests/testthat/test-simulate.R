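test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(dropout_base_rate = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(cells_per_group = 0), "positive")
  expect_error(cohort_config(ct_noise_sd = -1), ">= 0")
  expect_error(cohort_config(genes = c("EpCAM", "VIM")), "reference")
  expect_error(cohort_config(survival_scale = -5), "positive")
  expect_error(cohort_config(response_effect = c(PD = 10)), "PR")
})

test_that("every generator is bit-identical under the same seed and differs across seeds", {
  cfg <- cohort_config(seed = 123)
  expect_identical(sim_ct_matrix(cfg), sim_ct_matrix(cfg))
  expect_identical(sim_ctc_trajectories(cfg), sim_ctc_trajectories(cfg))
  expect_identical(sim_survival_cohort(cfg), sim_survival_cohort(cfg))
  expect_identical(sim_mutation_table(cfg), sim_mutation_table(cfg))
  cfg2 <- cohort_config(seed = 124)
  expect_false(identical(sim_ct_matrix(cfg)$ct$ct,
                         sim_ct_matrix(cfg2)$ct$ct))
})

test_that("generators draw from independent streams off the master seed", {
  cfg <- cohort_config(seed = 55)
  surv_alone <- sim_survival_cohort(cfg)
  invisible(sim_ct_matrix(cfg))  # an extra call must not perturb other streams
  expect_identical(sim_survival_cohort(cfg), surv_alone)
})

test_that("noise-free groups are internally identical", {
  sc <- sim_ct_matrix(four_group_config(ct_noise_sd = 0, cells = 4))
  per_group <- dplyr::summarise(
    dplyr::group_by(
      dplyr::inner_join(sc$ct, sc$annotations, by = "cell_id"),
      group, gene),
    v = stats::var(ct), .groups = "drop")
  expect_true(all(per_group$v == 0))
})

test_that("dropout frequency matches the configured rate (binomial tolerance)", {
  cfg <- cohort_config(
    groups = "G1", cells_per_group = 1000,
    genes = c("GAPDH", paste0("g", 1:9)),
    group_delta_ct_means = matrix(c(0, rep(5, 9)), ncol = 1,
                                  dimnames = list(c("GAPDH", paste0("g", 1:9)), "G1")),
    dropout_base_rate = 0.2, dropout_ct_slope = 0, seed = 77)
  ct <- sim_ct_matrix(cfg)$ct
  expect_equal(nrow(ct), 10000)
  frac <- mean(ct$ct == CT_UNDETECTED)
  tol <- 3 * sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(frac - 0.2), tol)
})

test_that("a WBC group expresses the leukocyte marker and not the epithelial panel", {
  cfg <- cohort_config(cells_per_group = 8, ct_noise_sd = 0.3,
                       dropout_base_rate = 0, dropout_ct_slope = 0, seed = 19)
  sc <- sim_ct_matrix(cfg)
  joined <- dplyr::inner_join(sc$ct, sc$annotations, by = "cell_id")
  mean_ct <- function(g, gene_) {
    mean(joined$ct[joined$group == g & joined$gene == gene_])
  }
  expect_lt(mean_ct("WBC", "PTPRC"), mean_ct("PC9", "PTPRC") - 8)
  expect_gt(mean_ct("WBC", "EpCAM"), mean_ct("PC9", "EpCAM") + 8)
})

test_that("clustering recovers generated groups above chance at moderate noise", {
  sc <- sim_ct_matrix(four_group_config(ct_noise_sd = 1, cells = 8, sep = 4,
                                        seed = 3))
  z <- zscore_transform(impute_undetected(apply_quality_filter(sc$ct)))
  cl <- hierarchical_cluster(z, k = 4)
  truth <- sc$annotations$group[match(cl$labels$cell_id, sc$annotations$cell_id)]
  expect_gt(adjusted_rand(cl$labels$cluster, truth), 0.8)
})

test_that("trajectory arm means recover the configured effects within Monte-Carlo error", {
  cfg <- cohort_config(n_pd = 500, n_pr = 500, baseline_count_mean = 50,
                       seed = 41)
  tr <- sim_ctc_trajectories(cfg)
  paired <- pair_delta_with_response(ctc_change_ratio(tr$counts),
                                     tr$assessments)
  follow <- dplyr::filter(paired, day > 0)
  for (arm in c("PD", "PR")) {
    x <- follow$delta_ctc[follow$matched_response == arm]
    sem <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$response_effect[[arm]]), 3 * sem)
  }
  # counts are non-negative integers on a 3 mL basis
  expect_true(all(tr$counts$raw_count >= 0))
  expect_true(all(tr$counts$raw_count == round(tr$counts$raw_count)))
  expect_true(all(tr$counts$volume_mL == 3))
})

test_that("simulated concordance converges to the target (binomial tolerance)", {
  cfg <- cohort_config(n_samples = 10000, concordance_target = 0.8, seed = 99)
  rate <- concordance_rate(sim_mutation_table(cfg))$rate / 100
  tol <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(rate - 0.8), tol)
})

test_that("log-rank power and null calibration behave as designed", {
  # power: hazard ratio 4 at n = 200 rejects nearly always
  rejections <- vapply(1:200, function(i) {
    cfg <- cohort_config(n_patients = 200, hazard_ratio = 4,
                         censoring_rate = 0.2, seed = 10000 + i)
    rec <- sim_survival_cohort(cfg)
    rec$group <- rec$true_group
    logrank_test(rec)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.9)

  # null: fixed-cutoff log-rank p-values are approximately uniform
  pvals <- vapply(1:500, function(i) {
    cfg <- cohort_config(n_patients = 100, hazard_ratio = 1,
                         censoring_rate = 0.2, seed = 20000 + i)
    rec <- sim_survival_cohort(cfg)
    rec$group <- rec$true_group
    logrank_test(rec)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the minimal-p cutoff search is optimistically biased under the null", {
  hits <- vapply(1:500, function(i) {
    cfg <- cohort_config(n_patients = 40, hazard_ratio = 1,
                         censoring_rate = 0.2, seed = 30000 + i)
    res <- optimal_cutoff_search(sim_survival_cohort(cfg))
    res$best_p < 0.05
  }, logical(1))
  # far above the nominal 5%: the selected p must be read as exploratory
  expect_gt(mean(hits), 0.10)
})
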