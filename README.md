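# fibrosign

Transcriptomic stricture-signature analysis for fibrostenotic Crohn's
disease.

Intestinal fibrosis is a common complication of Crohn's disease: chronic
inflammation drives extracellular-matrix deposition until the bowel narrows
into a stricture that often requires surgery. A resection specimen offers a
matched design for studying this process — from each patient one sample of
the ileal stricture and one each of the non-strictured proximal and distal
margins. `fibrosign` implements the full analysis chain for such a cohort,
for bioinformaticians and translational researchers who want to find and
evaluate stricture-specific gene signatures:

- **Synthetic cohorts with known truth.** A generator emulating the matched
  9-patient x 3-site design: multivariate log-normal expression with
  block-correlated genes, per-patient random intercepts, and a configurable
  injected DEG set (default 81 genes: 64 up, 17 down), plus paired qPCR Ct
  tables. Every downstream stage is testable without any data download.
- **Preprocessing.** `log2(TPM + 1)` transformation; removal of genes with a
  transformed value below 1 in any sample and of the lowest-variance decile.
- **Differential expression.** Empirical-Bayes moderated t-statistics
  (method-of-moments prior fit), per gene
  `s2_tilde = (d0 s0^2 + df s2) / (d0 + df)`,
  `t = log2FC / sqrt(s2_tilde * c)` on `d0 + df` degrees of freedom,
  Benjamini–Hochberg FDR control, a two-fold-change gate, and the
  sign-consistent overlap of the two stricture-versus-margin contrasts.
- **PLS-DA gene selection.** Deterministic NIPALS partial least squares for
  stricture vs margin on autoscaled genes, VIP scores
  `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` (so `mean(VIP^2) = 1`),
  cross-validated R2/Q2, selection at VIP > 1.
- **Random-forest panels.** Bagged-forest AUC for single genes and combined
  panels, scored by pooled stratified cross-validation (or out-of-bag), with
  percentile-bootstrap confidence intervals.
- **Power and sample size.** The simulation procedure for planning a
  validation cohort: fit a multivariate log-normal model, inject a Cohen's d
  shift into a target gene and its highly correlated neighbors, run a
  per-variable one-way ANOVA, and trace power over a sample-size grid
  (default 5, 10, 15, 20, 50, 100).
- **qPCR validation.** Relative quantification by `2^-ddCt` against a
  housekeeping gene and a per-patient calibrator site, Kruskal–Wallis
  comparison across sites, bootstrap median confidence intervals.

## Worked example

```r
library(fibrosign)

cohort <- generate_cohort(cohort_design(seed = 1))
filt <- filter_genes(log_transform(cohort$expression))
d1 <- moderated_t(filt$matrix, cohort$metadata, contrast_spec("stricture", "proximal"))
d2 <- moderated_t(filt$matrix, cohort$metadata, contrast_spec("stricture", "distal"))
overlap_deg(d1, d2)
#> <overlap_result> 25 shared DEGs (19 up, 6 down); per-contrast 32 / 39

labels <- ifelse(cohort$metadata$site == "stricture", "stricture", "margin")
model <- fit_plsda(filt$matrix, labels)
sel <- select_genes(model, 1)
panel <- head(sel$genes$gene, 8)
rf_panel_auc(filt$matrix, labels, panel, seed = 1)
#> <auc_result> g0775+g0370+g1876+g0212+g0055+g1296+g1857+g0714: AUC 1.000
#> (95% CI 1.000-1.000), cv scoring, 9 pos / 18 neg
```

The overlap is the cohort's stricture signature: genes significant against
both margins with the same sign (here 25 of the 81 injected DEGs clear the
FDR and fold-change gates at n = 9 — the small matched cohort detects only
the strongest part of the injected signal). The combined top-VIP panel
separates stricture from margin samples essentially perfectly under pooled
5-fold cross-validation.

Power planning for a follow-up cohort, using the effect size a gene shows in
the pilot:

```r
stric <- cohort$metadata$sample_id[cohort$metadata$site == "stricture"]
marg <- cohort$metadata$sample_id[cohort$metadata$site != "stricture"]
x <- expr_values(filt$matrix)
d_hat <- cohens_d(x[panel[1], stric], x[panel[1], marg])   # 2.56
lnm <- fit_lognormal(cohort$expression, genes = panel)
power_curve(lnm, effect_spec(panel[1], d_hat), n_reps = 500, seed = 1)
#> <power_curve> g0775, d = 2.56, alpha = 0.05, 500 reps/n
#>    n power      mc_se
#>    5 0.946 0.01010782
#>   10 1.000 0.00000000
#>   15 1.000 0.00000000
#>   20 1.000 0.00000000
#>   50 1.000 0.00000000
#>  100 1.000 0.00000000
```

A gene with a standardized effect this large is detectable with near
certainty even at 5 patients per group; weaker genes need the larger grid
sizes. `run_pipeline(pipeline_config(...))` chains all stages and writes
TSV/JSON outputs plus a reproducibility manifest.

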