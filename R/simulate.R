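#' Configuration for the synthetic cohort generators
#'
#' One config object parameterizes all four generators (single-cell Ct
#' matrices, CTC-count trajectories, censored survival cohorts, paired
#' mutation tables). A single `seed` fans out to independent per-generator
#' streams, so adding one generator call never perturbs the draws of another.
#'
#' Defaults emulate the study conditions the pipeline targets: four NSCLC
#' cell-line-like groups plus a CD45-positive WBC contrast group, ~1 cycle of
#' Ct noise, Ct-dependent dropout, a PD arm trending +70.1% and a PR arm
#' -43.1% in per-draw CTC change (the response-linked regime reported for
#' EGFR-TKI monitoring), Weibull survival times on a ~600-day scale, and a
#' fully concordant mutation table.
#'
#' @param groups Character vector of cell source groups; a group named
#'   `"WBC"` gets the leukocyte expression pattern (CD45 high, epithelial
#'   markers near the detection floor).
#' @param cells_per_group Cells simulated per group.
#' @param genes Gene identifiers; must include `reference_gene`.
#' @param reference_gene Housekeeping gene anchoring delta-Ct.
#' @param group_delta_ct_means Genes x groups matrix of mean delta-Ct
#'   (cycles above the reference); `NULL` builds a default E/M-structured
#'   matrix via [default_delta_ct_means()].
#' @param ref_ct_mean Mean reference-gene Ct (cycles).
#' @param ct_noise_sd Gaussian Ct noise SD (cycles), > 0 unless exactly 0 for
#'   noise-free limits.
#' @param dropout_base_rate,dropout_ct_slope Dropout probability is
#'   `base + slope * (Ct - min Ct)`, clipped to \[0, 1\]: dimmer transcripts
#'   (higher Ct) drop out more.
#' @param low_quality_frac Fraction of entries given a quality score below
#'   0.65.
#' @param n_pd,n_pr Patients in the PD and PR trajectory arms.
#' @param response_effect Named vector, mean per-draw delta-CTC (%) for the
#'   `PD` and `PR` arms.
#' @param baseline_count_mean Mean raw baseline CTC count per 3 mL draw.
#' @param follow_days Follow-up draw days (baseline is day 0).
#' @param count_noise `"poisson"` for counting noise, `"none"` for the
#'   deterministic rounded expectation.
#' @param n_patients Cohort size for the survival generator.
#' @param survival_shape,survival_scale Weibull shape/scale (days); shape 1
#'   gives the exponential special case.
#' @param censoring_rate Probability a record is censored (uniformly before
#'   its event time).
#' @param hazard_ratio Hazard ratio of the CTC-High arm (counts above
#'   `count_cutoff`); 1 means no association.
#' @param count_cutoff True threshold (CTCs/7.5 mL) tying baseline counts to
#'   hazard when `hazard_ratio != 1`.
#' @param count_meanlog,count_sdlog Log-normal parameters of baseline counts
#'   per 7.5 mL (default centered near a median of 37).
#' @param n_samples Rows of the simulated mutation table.
#' @param concordance_target Expected sample-level tissue/CTC concordance in
#'   \[0, 1\].
#' @param loci Assayed loci; the last is treated as the resistance locus for
#'   emergent pairs.
#' @param n_emergent Patients given a BT/AR pair in which the resistance
#'   locus flips - to + in both modalities.
#' @param seed Integer master seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(groups = c("H2228", "H460", "HCC78", "PC9", "WBC"),
                          cells_per_group = 10,
                          genes = c("GAPDH", "EpCAM", "KRT7", "KRT18", "KRT19",
                                    "VIM", "CD44", "PTPRC", "CDH1", "CDH2",
                                    "EGFR", "MKI67"),
                          reference_gene = "GAPDH",
                          group_delta_ct_means = NULL,
                          ref_ct_mean = 18,
                          ct_noise_sd = 1,
                          dropout_base_rate = 0.05,
                          dropout_ct_slope = 0.01,
                          low_quality_frac = 0.05,
                          n_pd = 17, n_pr = 24,
                          response_effect = c(PD = 70.1, PR = -43.1),
                          baseline_count_mean = 23,
                          follow_days = c(60, 120, 180),
                          count_noise = c("poisson", "none"),
                          n_patients = 38,
                          survival_shape = 1.2, survival_scale = 600,
                          censoring_rate = 0.3,
                          hazard_ratio = 1,
                          count_cutoff = 66,
                          count_meanlog = log(37), count_sdlog = 0.8,
                          n_samples = 15,
                          concordance_target = 1,
                          loci = c("activating", "T790M"),
                          n_emergent = 0,
                          seed = 1L) {
  count_noise <- match.arg(count_noise)
  probs <- c(dropout_base_rate, low_quality_frac, censoring_rate,
             concordance_target)
  if (any(probs < 0 | probs > 1)) {
    abort("dropout_base_rate, low_quality_frac, censoring_rate and concordance_target must lie in [0, 1]")
  }
  counts <- c(cells_per_group, n_pd, n_pr, n_patients, n_samples)
  if (any(counts <= 0) || any(counts != round(counts))) {
    abort("counts (cells_per_group, n_pd, n_pr, n_patients, n_samples) must be positive integers")
  }
  if (ct_noise_sd < 0) abort("ct_noise_sd must be >= 0")
  if (dropout_ct_slope < 0) abort("dropout_ct_slope must be >= 0")
  if (!reference_gene %in% genes) {
    abort(sprintf("reference gene '%s' must be in `genes`", reference_gene))
  }
  if (!all(c("PD", "PR") %in% names(response_effect))) {
    abort("`response_effect` must name PD and PR trends")
  }
  if (survival_shape <= 0 || survival_scale <= 0) {
    abort("Weibull shape and scale must be positive")
  }
  if (hazard_ratio <= 0) abort("hazard_ratio must be positive")
  if (is.null(group_delta_ct_means)) {
    group_delta_ct_means <- default_delta_ct_means(genes, groups, reference_gene)
  }
  if (!identical(dim(group_delta_ct_means), c(length(genes), length(groups)))) {
    abort("group_delta_ct_means must be a genes x groups matrix")
  }
  dimnames(group_delta_ct_means) <- list(genes, groups)
  structure(list(
    groups = groups, cells_per_group = as.integer(cells_per_group),
    genes = genes, reference_gene = reference_gene,
    group_delta_ct_means = group_delta_ct_means,
    ref_ct_mean = ref_ct_mean, ct_noise_sd = ct_noise_sd,
    dropout_base_rate = dropout_base_rate, dropout_ct_slope = dropout_ct_slope,
    low_quality_frac = low_quality_frac,
    n_pd = as.integer(n_pd), n_pr = as.integer(n_pr),
    response_effect = response_effect,
    baseline_count_mean = baseline_count_mean,
    follow_days = follow_days, count_noise = count_noise,
    n_patients = as.integer(n_patients),
    survival_shape = survival_shape, survival_scale = survival_scale,
    censoring_rate = censoring_rate, hazard_ratio = hazard_ratio,
    count_cutoff = count_cutoff,
    count_meanlog = count_meanlog, count_sdlog = count_sdlog,
    n_samples = as.integer(n_samples),
    concordance_target = concordance_target,
    loci = loci, n_emergent = as.integer(n_emergent),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default group mean delta-Ct matrix
#'
#' Builds a genes x groups matrix of mean delta-Ct values with the canonical
#' phenotypes: epithelial lines express EpCAM/cytokeratins strongly (low
#' delta-Ct), a mesenchymal-leaning line favors vimentin/CD44, the WBC group
#' expresses CD45 (PTPRC) and sits near the detection floor for epithelial
#' markers. Genes without a preset profile get an intermediate 8-cycle mean.
#'
#' @param genes,groups Identifiers to cover.
#' @param reference_gene Reference gene (delta-Ct 0 by definition).
#' @return Numeric genes x groups matrix (cycles).
#' @export
default_delta_ct_means <- function(genes, groups, reference_gene = "GAPDH") {
  presets <- list(
    H2228 = c(EpCAM = 8, KRT7 = 7, KRT18 = 7, KRT19 = 8, VIM = 5, CD44 = 6,
              PTPRC = 15, CDH1 = 9, CDH2 = 5, EGFR = 7, MKI67 = 6),
    H460  = c(EpCAM = 6, KRT7 = 6, KRT18 = 5, KRT19 = 6, VIM = 4, CD44 = 6,
              PTPRC = 15, CDH1 = 6, CDH2 = 7, EGFR = 5, MKI67 = 6),
    HCC78 = c(EpCAM = 3, KRT7 = 4, KRT18 = 3, KRT19 = 3, VIM = 5, CD44 = 9,
              PTPRC = 15, CDH1 = 4, CDH2 = 11, EGFR = 6, MKI67 = 5),
    PC9   = c(EpCAM = 4, KRT7 = 4, KRT18 = 3, KRT19 = 4, VIM = 4, CD44 = 8,
              PTPRC = 15, CDH1 = 4, CDH2 = 10, EGFR = 3, MKI67 = 5),
    WBC   = c(EpCAM = 15, KRT7 = 15, KRT18 = 15, KRT19 = 15, VIM = 6, CD44 = 7,
              PTPRC = 3, CDH1 = 15, CDH2 = 12, EGFR = 14, MKI67 = 10)
  )
  m <- matrix(8, nrow = length(genes), ncol = length(groups),
              dimnames = list(genes, groups))
  for (g in intersect(groups, names(presets))) {
    known <- intersect(genes, names(presets[[g]]))
    m[known, g] <- presets[[g]][known]
  }
  m[reference_gene, ] <- 0
  m
}

# independent per-generator streams from the one master seed
substream <- function(config, offset) (config$seed %% 100000L) * 10L + offset

#' Simulate a single-cell Ct matrix with group structure
#'
#' Every entry is the reference-gene anchor `ref_ct_mean` plus the group's
#' mean delta-Ct for that gene (zero for the reference gene itself) plus
#' independent Gaussian measurement noise. Entries then drop out (become the 999 sentinel) with
#' probability `dropout_base_rate + dropout_ct_slope * (Ct - min Ct)`,
#' clipped to \[0, 1\], so dim transcripts vanish more often. Quality scores
#' are uniform on \[0.65, 1\] except for a `low_quality_frac` fraction drawn
#' below 0.65.
#'
#' @param config A [cohort_config()].
#' @return List with `ct` (long tibble `cell_id`, `gene`, `ct`, `quality`)
#'   and `annotations` (tibble `cell_id`, `group` -- the true labels for
#'   recovery tests).
#' @export
sim_ct_matrix <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(substream(config, 1L), {
    cells <- tibble(
      group = rep(config$groups, each = config$cells_per_group),
      cell_id = paste0(rep(config$groups, each = config$cells_per_group), "_c",
                       rep(seq_len(config$cells_per_group), length(config$groups)))
    )
    grid <- tidyr::expand_grid(cells, gene = config$genes) %>%
      mutate(
        dmean = config$group_delta_ct_means[cbind(.data$gene, .data$group)],
        ct = config$ref_ct_mean + .data$dmean + rnorm(n(), sd = config$ct_noise_sd)
      )
    min_ct <- min(grid$ct)
    grid <- grid %>%
      mutate(
        p_drop = pmin(1, pmax(0, config$dropout_base_rate +
                                   config$dropout_ct_slope * (.data$ct - min_ct))),
        dropped = runif(n()) < .data$p_drop,
        ct = if_else(.data$dropped, CT_UNDETECTED, .data$ct),
        quality = if_else(runif(n()) < config$low_quality_frac,
                          runif(n(), 0, 0.65), runif(n(), 0.65, 1))
      )
    list(
      ct = grid %>% select("cell_id", "gene", "ct", "quality"),
      annotations = cells %>% select("cell_id", "group")
    )
  })
}

#' Simulate response-linked CTC count trajectories
#'
#' Patients in the PD arm have follow-up draws whose expected change from
#' baseline is the configured positive trend, PR-arm patients the configured
#' negative trend; raw counts are non-negative integers for 3 mL draws
#' (Poisson around the expected count, or the rounded expectation when
#' `count_noise = "none"`). Each patient carries a day-0 baseline and RECIST
#' assessments at scan days 5 days before each draw, labelled with the arm's
#' category.
#'
#' @param config A [cohort_config()].
#' @return List with `counts` (tibble `patient_id`, `arm`, `day`,
#'   `raw_count`, `volume_mL`) and `assessments` (tibble `patient_id`, `day`,
#'   `category`).
#' @export
sim_ctc_trajectories <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(substream(config, 2L), {
    arms <- tibble(
      patient_id = c(paste0("PD", seq_len(config$n_pd)),
                     paste0("PR", seq_len(config$n_pr))),
      arm = c(rep("PD", config$n_pd), rep("PR", config$n_pr))
    )
    draw_count <- function(lambda) {
      lambda <- pmax(lambda, 0)
      if (config$count_noise == "poisson") rpois(length(lambda), lambda)
      else round(lambda)
    }
    baselines <- arms %>%
      mutate(baseline = pmax(1, draw_count(rep(config$baseline_count_mean, n()))))
    followups <- tidyr::expand_grid(baselines, day = config$follow_days) %>%
      mutate(raw_count = draw_count(
        .data$baseline * (1 + config$response_effect[.data$arm] / 100)))
    counts <- bind_rows(
      baselines %>% mutate(day = 0, raw_count = .data$baseline),
      followups
    ) %>%
      arrange(.data$patient_id, .data$day) %>%
      mutate(volume_mL = 3) %>%
      select("patient_id", "arm", "day", "raw_count", "volume_mL")
    assessments <- tidyr::expand_grid(arms, scan_day = config$follow_days - 5) %>%
      mutate(category = .data$arm) %>%
      select("patient_id", day = "scan_day", "category")
    list(counts = counts, assessments = assessments)
  })
}

#' Simulate a censored survival cohort with baseline CTC counts
#'
#' Event times are Weibull(shape, scale); baseline counts per 7.5 mL are
#' log-normal. When `hazard_ratio != 1`, patients whose count exceeds
#' `count_cutoff` have their hazard multiplied by it (proportional-hazards
#' Weibull), giving the high-count arm stochastically shorter times. Each
#' record is independently censored with probability `censoring_rate`, at a
#' uniform time before its event.
#'
#' @param config A [cohort_config()].
#' @return Tibble `patient_id`, `time` (days), `event` (1/0),
#'   `baseline_count_75`, `true_group` (High/Low at the generating cutoff).
#' @export
sim_survival_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(substream(config, 3L), {
    n <- config$n_patients
    count <- rlnorm(n, config$count_meanlog, config$count_sdlog)
    high <- count > config$count_cutoff
    hr <- if_else(high, config$hazard_ratio, 1)
    u <- runif(n)
    time <- config$survival_scale * (-log(u) / hr)^(1 / config$survival_shape)
    censored <- runif(n) < config$censoring_rate
    obs_time <- if_else(censored, runif(n) * time, time)
    tibble(
      patient_id = paste0("P", seq_len(n)),
      time = pmax(obs_time, 0.5),
      event = as.integer(!censored),
      baseline_count_75 = count,
      true_group = if_else(high, "High", "Low")
    )
  })
}

#' Simulate a paired tissue/CTC mutation call table
#'
#' Tissue calls are drawn per locus (the activating locus positive in 90% of
#' samples, others in 20%); CTC calls start as copies and each locus is then
#' flipped independently with probability `1 - concordance_target^(1/n_loci)`,
#' so the expected sample-level (all-loci) concordance equals
#' `concordance_target`. Optionally, `n_emergent` patients contribute a
#' concordant BT/AR pair in which the last locus flips - to + in both tissue
#' and CTC at relapse.
#'
#' @param config A [cohort_config()].
#' @return Long tibble `sample_id`, `patient_id`, `stage`, `locus`,
#'   `tissue_call`, `ctc_call`.
#' @export
sim_mutation_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(substream(config, 4L), {
    loci <- config$loci
    q <- 1 - config$concordance_target^(1 / length(loci))
    base <- tidyr::expand_grid(
      patient_id = paste0("S", seq_len(config$n_samples)), locus = loci
    ) %>%
      mutate(
        sample_id = .data$patient_id, stage = "BT",
        tissue_call = if_else(
          runif(n()) < if_else(.data$locus == loci[1], 0.9, 0.2), "+", "-"),
        flip = runif(n()) < q,
        ctc_call = if_else(.data$flip,
                           if_else(.data$tissue_call == "+", "-", "+"),
                           .data$tissue_call)
      ) %>%
      select("sample_id", "patient_id", "stage", "locus",
             "tissue_call", "ctc_call")
    if (config$n_emergent > 0) {
      res_locus <- loci[length(loci)]
      emergent <- purrr::map_dfr(seq_len(config$n_emergent), function(i) {
        pid <- paste0("E", i)
        tibble(
          sample_id = paste0(pid, c("-BT", "-BT", "-AR", "-AR")),
          patient_id = pid,
          stage = c("BT", "BT", "AR", "AR"),
          locus = rep(c(loci[1], res_locus), 2),
          tissue_call = c("+", "-", "+", "+"),
          ctc_call = c("+", "-", "+", "+")
        )
      })
      base <- bind_rows(base, emergent)
    }
    base
  })
}
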