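---
title: "Models and methods behind the ctcdx pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ctcdx pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcdx)
```

This vignette explains the science implemented by `ctcdx`: the models, the
parameters that matter, the numerical decisions, and what the synthetic
cohorts do and do not demonstrate about real data.

## The setting

In EGFR-mutant non-small cell lung cancer, a tumor sheds circulating tumor
cells (CTCs) into peripheral blood. Counting those cells at serial draws,
genotyping them, and profiling single-CTC expression offers a minimally
invasive window on therapy response and emerging drug resistance.
`ctcdx` covers the downstream analysis of such a study: single-cell qRT-PCR
matrices, per-draw CTC counts with radiographic response labels, censored
survival records, and paired tissue/CTC mutation calls.

## Single-cell Ct preprocessing

A qRT-PCR measurement is a cycle-threshold value Ct; lower Ct means more
transcript, and a reaction that never crosses threshold carries the
sentinel 999. The preprocessing chain is fixed, and every tibble carries a
`stage` attribute so the transforms compose only in the legal order:

1. **Quality filter** (`apply_quality_filter`): entries with quality score
   < 0.65 or Ct > 30 cycles become undetected. The defaults are the
   conventional trust region for microfluidic single-cell qPCR: beyond
   ~30 cycles amplification is dominated by noise. Both thresholds are
   arguments. The filter only ever *removes* detections, so raising
   `quality_min` is monotone — it can never resurrect an entry.
2. **Imputation** (`impute_undetected`): each sentinel is replaced by the
   *per-gene* maximum detected Ct plus 1 cycle. The idea is that a missing
   measurement should carry the smallest expression weight observed for
   that gene without creating an outlier. "Observed" is taken per analyzed
   matrix, not per study. A gene undetected in *every* cell has no
   per-gene maximum; we fall back to the global detected maximum + 1,
   which preserves the "worst observed + 1" semantics, and report the gene
   via a message and an attribute. Imputation is idempotent and leaves no
   sentinel behind.
3. **Branch A — ΔCt → 2^−ΔCt** (`delta_ct`, `relative_expression`): per
   cell, `ΔCt(g, c) = Ct(g, c) − Ct(GAPDH, c)`; relative expression is
   `2^−ΔCt`, i.e. fold expression relative to the housekeeping reference.
   This branch feeds EMT scoring only. A cell in which the reference gene
   itself was undetected has no meaningful normalization; its imputed
   reference value still allows the arithmetic, but such cells should be
   treated with suspicion (the imputation message identifies the
   situation).
4. **Branch B — Z-scores** (`zscore_transform`): per gene across cells,
   `z = (x − mean) / SD` with the n−1 sample SD, computed on **imputed Ct**
   (not ΔCt), so that clustering and embedding weight every gene equally.
   Zero-variance genes map to z = 0 (flagged) rather than NaN; this keeps
   the matrix shape and is neutral for Euclidean distances. The output
   invariant — per-gene mean 0 and SD 1 within 1e−9 for non-degenerate
   genes — is asserted in the tests.

Stained events are gated by `classify_event` with the standard
immunofluorescence rule: CK or EpCAM positive, CD45 negative and DAPI
positive is a CTC; any CD45-positive event is a white blood cell;
everything else is excluded.

## EMT scoring

Epithelial–mesenchymal transition (EMT) is associated with invasiveness and
TKI resistance, and CTCs occupy a continuum between the E and M states.
Per cell we sum relative expression over an epithelial panel
(EpCAM, KRT7, KRT18, KRT19) and a mesenchymal panel (vimentin, CD44):

> `m_score = 100 · m_sum / (e_sum + m_sum)`, `e_score = 100 − m_score`.

The score is a relative percentage, so it is invariant to any common
scaling of a cell's expression (e.g. cell size or RT efficiency), always
sums to 100 with the E-score, and increases strictly in any mesenchymal
marker. A cell generated with `m_sum = k · e_sum` scores exactly
`100k/(1+k)` — the recovery property the tests exercise at k up to 3.

Undetected markers contribute their imputed tiny 2^−ΔCt value rather than
zero. This follows from placing the scoring downstream of the imputation
step and keeps the score defined for every cell with any detected marker;
a cell with zero marker total is flagged `NA` instead of silently scored.

Labels come from a **hybrid band**: `m_score` below 40 is epithelial,
above 60 mesenchymal, in between hybrid E/M. No numeric threshold for
these verbal categories is established in the field; the band is a design
choice of this package, chosen wide enough that strongly skewed group
means (around 20% or 80%) land in the pure classes while mixed phenotypes
(around 50%) read as hybrid. Both edges are arguments to `classify_emt`.
Group summaries report mean ± sample SD (n−1); singleton groups report
`NA` SD rather than 0.

## Heterogeneity analysis

- **Hierarchical clustering** (`hierarchical_cluster`): Euclidean distance
  and complete linkage by default — the defaults of the classic heatmap
  tooling this analysis style comes from — both configurable. The
  implementation delegates to `stats::hclust`; the test suite proves
  equivalence against a from-scratch O(n³) agglomerator (lowest-index
  tie-break) on random matrices up to n = 10, comparing merge heights and
  every flat partition.
- **t-SNE** (`tsne_embed`): exact (theta = 0) embeddings in 2 or 3
  dimensions, perplexity 10 by default, which suits the 20–60 cell
  analyses this pipeline targets; the hard precondition
  `perplexity < (n−1)/3` is enforced. A seed is *mandatory* because t-SNE
  is stochastic; embeddings are validated by separation properties
  (positive silhouette against generated labels), never by coordinate
  values, which are not comparable across implementations.
- **Spearman correlation matrices** (`correlation_matrix`): pairwise rank
  correlations between cells over genes, two-sided p-values, and
  Bonferroni adjustment `p_adj = min(1, m · p_raw)` with m = all pairs in
  the computed matrix. The family is one matrix: correlate patient CTCs,
  cell lines and WBCs in separate calls to match the "computed separately
  per population" convention. Cells with constant expression have no
  defined rank correlation and are flagged rather than imputed.

## CTC count kinetics

Counts from 3 mL draws are reported per 7.5 mL (`× 2.5`), the conventional
enumeration basis — hence half-integer counts like 57.5. The per-draw
change ratio is

> `ΔCTC(%) = 100 · (CTC_i − CTC_0) / CTC_0`

with CTC_0 the day-0 baseline. It is invariant to the volume basis and is
undefined for a zero baseline; such patients are *excluded with a warning*
rather than rescued by a pseudo-count, which would silently distort group
means.

Draws pair to the nearest-in-time RECIST assessment within 45 days
(half a typical two-to-three-cycle scan interval), ties to the earlier
scan; unpaired draws are kept but excluded from group comparisons. The
PD-vs-PR comparison is a classical two-tailed Student's t-test with pooled
variance (`var_equal = FALSE` gives Welch), reported with group means and
sizes. The test statistic is verified against the textbook formula in the
suite.

## Survival stratification

Kaplan–Meier estimation and the unweighted log-rank test delegate to the
`survival` package; both are cross-checked against hand-rolled
product-limit and observed-minus-expected/variance oracles in the tests.
Conventions:

- time is handled in days and reported also in months (÷ 30.44);
- the reported median is the first time the curve reaches 0.5 or below
  (`NA` when it never does);
- confidence intervals are log–log (Greenwood-based), a standard default
  when no method is specified for printed CIs.

`optimal_cutoff_search` implements the minimal-p stratification: every
distinct baseline count is a candidate cutoff, CTC-High means count
**strictly greater** than the cutoff (so boundary counts stay Low), and
splits leaving either group under `min_group_frac = 10%` of the cohort are
inadmissible — minimal-p searches on tiny groups are numerically unstable
and clinically meaningless. The winning p-value is *exploratory*: choosing
the cutoff that minimizes p inflates significance, and the package both
prints that flag and demonstrates it (under a null with no
count–survival association, the selected p falls below 0.05 far more
often than 5%; the suite asserts > 10% over 500 simulated cohorts).

## Mutation concordance

A sample is concordant when the CTC call equals the tissue call at every
assayed locus; the rate is over samples (rows), so a patient sampled
before treatment and at relapse contributes twice. Per-locus rates are
reported alongside. `detect_emergent` flags loci negative in both
modalities at an earlier stage and positive in either at a later stage —
the signature of acquired resistance (EGFR T790M at relapse) — with the
modality (tissue/CTC/both) in which the mutation surfaced. Stage order
comes from the BT/AR labels, not dates, which call tables typically lack.
The bundled `egfr_call_fixture()` (15 samples, 13 patients) exercises both
operations.

## The synthetic cohort generators

`cohort_config()` centralizes all generator parameters; one master seed
fans out to independent per-generator streams, so adding a generator call
never perturbs another's draws, and everything is bit-reproducible.

What the generators emulate — and their defaults:

- **Ct matrices** (`sim_ct_matrix`): every entry is
  `ref_ct_mean (18) + group mean ΔCt + N(0, ct_noise_sd)` with
  `ct_noise_sd = 1` cycle, about the measurement spread of single-cell
  qPCR. Dropout is `base (0.05) + slope (0.01/cycle) · (Ct − min Ct)`,
  clipped to [0, 1] — the simplest monotone model of the fact that dim
  transcripts are lost more often. The default ΔCt means encode four
  NSCLC-line-like phenotypes (one mesenchymal-leaning with an M/E
  expression ratio near 2, two strongly epithelial, one intermediate) and
  a WBC group with CD45 (PTPRC) high and epithelial markers at the
  detection floor. Per-gene Ct distributions of any real instrument run
  are *not* reproduced; the defaults are chosen for testability of the
  group structure, not to mimic any published heatmap.
- **Count trajectories** (`sim_ctc_trajectories`): a PD arm (n = 17) whose
  follow-up draws trend +70.1% from baseline and a PR arm (n = 24)
  trending −43.1% — the response-linked regime the pipeline is built to
  detect — with Poisson counting noise on integer 3 mL counts and scans
  5 days before each draw. Poisson noise understates the biological
  dispersion of real per-draw change rates, so simulated group
  comparisons separate more sharply than a clinical cohort would; the
  arms' means, not the p-value's magnitude, are the calibrated quantity.
  `count_noise = "none"` gives the deterministic limit used by exactness
  tests.
- **Survival cohorts** (`sim_survival_cohort`): Weibull times
  (shape 1.2, scale 600 days; shape 1 recovers the exponential),
  log-normal baseline counts centered near a median of 37 CTCs/7.5 mL,
  censoring with probability 0.3 at a uniform fraction of the event time,
  and an optional proportional-hazards effect (`hazard_ratio`) for counts
  above a planted cutoff (66 by default). Censoring independent of the
  count group keeps the log-rank null exact.
- **Mutation tables** (`sim_mutation_table`): CTC calls copy tissue calls
  and flip per locus with probability `1 − target^(1/n_loci)`, making the
  expected all-loci sample concordance exactly the target; optional
  emergent BT/AR pairs plant a − → + resistance flip in both modalities.

Simulation scale in the shipped tests: binomial calibrations use 10,000
entries/samples; power and recovery properties use 200 replicates; null
calibrations use 500 replicates at cohorts of 38–200 patients. These sizes
put Monte-Carlo error well below the asserted margins while keeping the
suite quick.

## Numerical and degenerate-input decisions

- Sample SD (n−1) everywhere a spread is reported; singletons give `NA`.
- Z-scores: constant genes → 0, flagged; one-cell matrices are an error.
- EMT: zero marker total → `NA` score, flagged; missing panel genes error.
- Change ratio: zero baseline → excluded with warning; missing day-0
  baseline is an error; duplicate (patient, day) draws are an error.
- Cutoff search: all-equal counts error ("no admissible split"); the grid
  of every admissible cutoff is returned so the minimum can be audited.
- Clustering tie-break: delegated to `hclust`; the oracle tests use
  continuous random data where ties have probability zero.
- Stage tags make out-of-order transforms (e.g. 2^−ΔCt before imputation)
  an error rather than a silent wrong answer.

## Limitations

- The hybrid band, the 45-day pairing window and the 10% group-size guard
  are reasoned defaults, not estimated quantities; sensitivity to them
  should be checked on real data.
- The generators produce idealized noise (Gaussian Ct, Poisson counts,
  independent censoring). Passing recovery tests shows the estimators are
  correct under the stated models, not that real data satisfy those
  models — batch effects, preamplification bias, and inter-patient count
  dispersion are all absent.
- The minimal-p cutoff is exploratory by construction; the package flags
  but does not correct the selection bias (no cross-validation or
  maximally-selected-rank-statistic adjustment is attempted).
- No variant calling, droplet-level ddPCR modeling, RECIST measurement, or
  image analysis: counts, categories and calls are inputs.
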