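#' Design of a synthetic matched three-site cohort
#'
#' Describes the desk-scale stand-in for the study design: `n_patients`
#' patients each contributing one sample from the ileal stricture and from the
#' non-strictured proximal and distal resection margins. Expression is
#' multivariate log-normal on the log2 scale: gene baselines plus
#' block-correlated patient intercepts and residual noise, with a configurable
#' set of injected differentially expressed genes whose stricture-site mean is
#' shifted by `effect_log2fc` log2 units (up or down).
#'
#' Null genes draw their log2 baselines uniformly over
#' `[baseline_min, baseline_max]`; injected DEGs draw theirs from the
#' expressed upper range (at least `deg_baseline_min`) so that the injected
#' truth remains identifiable after the low-count filter - signature genes in
#' this design are robustly expressed transcripts.
#'
#' @param n_patients Number of matched patients (default 9).
#' @param sites Ordered site labels; must be exactly the three study sites.
#' @param n_genes Number of genes (default 2000).
#' @param n_deg_up,n_deg_down Number of injected up-/down-regulated genes
#'   (defaults 64 and 17).
#' @param effect_log2fc Injected absolute log2 fold change (default 1.5).
#' @param block_size Size of contiguous gene correlation blocks (default 50).
#' @param within_block_corr Exchangeable correlation within a block, in
#'   `[0, 1)` (default 0.6). Applies to both the residual noise and the
#'   patient intercepts, so it is also the marginal log2-scale correlation.
#' @param noise_sd_log2 Residual log2-scale standard deviation (default 1.0).
#' @param patient_sd_log2 Standard deviation of the per-patient, per-gene
#'   random intercept shared across that patient's three samples (default 0.5);
#'   this is what makes the design paired.
#' @param baseline_min,baseline_max Range of the log2 baseline (defaults 0, 10).
#' @param deg_baseline_min Minimum log2 baseline for injected DEGs (default 5).
#' @param seed Master seed; all stage streams derive from it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 9, sites = c("stricture", "proximal", "distal"),
                          n_genes = 2000, n_deg_up = 64, n_deg_down = 17,
                          effect_log2fc = 1.5, block_size = 50,
                          within_block_corr = 0.6, noise_sd_log2 = 1.0,
                          patient_sd_log2 = 0.5, baseline_min = 0,
                          baseline_max = 10, deg_baseline_min = 5, seed = 1L) {
  d <- list(n_patients = n_patients, sites = sites, n_genes = n_genes,
            n_deg_up = n_deg_up, n_deg_down = n_deg_down,
            effect_log2fc = effect_log2fc, block_size = block_size,
            within_block_corr = within_block_corr,
            noise_sd_log2 = noise_sd_log2, patient_sd_log2 = patient_sd_log2,
            baseline_min = baseline_min, baseline_max = baseline_max,
            deg_baseline_min = deg_baseline_min, seed = seed)
  class(d) <- "cohort_design"
  validate_design(d)
  d
}

validate_design <- function(d) {
  chk_count <- function(field, x, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
      field_stop(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_count("n_patients", d$n_patients, 2)
  chk_count("n_genes", d$n_genes, 1)
  chk_count("n_deg_up", d$n_deg_up, 0)
  chk_count("n_deg_down", d$n_deg_down, 0)
  chk_count("block_size", d$block_size, 1)
  if (!setequal(d$sites, c("stricture", "proximal", "distal")) ||
      length(d$sites) != 3L) {
    field_stop("sites", "must contain exactly the labels stricture, proximal, distal")
  }
  if (d$n_deg_up + d$n_deg_down > d$n_genes) {
    field_stop("n_deg_up", "n_deg_up + n_deg_down must not exceed n_genes")
  }
  if (!is.numeric(d$within_block_corr) || d$within_block_corr < 0 ||
      d$within_block_corr >= 1) {
    field_stop("within_block_corr", "must lie in [0, 1) so the covariance is positive definite")
  }
  if (d$effect_log2fc < 0) field_stop("effect_log2fc", "must be non-negative")
  if (d$noise_sd_log2 <= 0) field_stop("noise_sd_log2", "must be positive")
  if (d$patient_sd_log2 < 0) field_stop("patient_sd_log2", "must be non-negative")
  if (d$baseline_min > d$baseline_max) {
    field_stop("baseline_min", "must not exceed baseline_max")
  }
  invisible(d)
}

## Draw a genes x k matrix with exchangeable correlation rho inside contiguous
## blocks of block_size genes and independence across blocks (unit marginal sd).
block_normal <- function(n_genes, k, block_size, rho) {
  n_blocks <- ceiling(n_genes / block_size)
  shared <- matrix(rnorm(n_blocks * k), n_blocks, k)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_genes)]
  indiv <- matrix(rnorm(n_genes * k), n_genes, k)
  sqrt(rho) * shared[block_of, , drop = FALSE] + sqrt(1 - rho) * indiv
}

#' Generate a synthetic cohort with known differential-expression truth
#'
#' Draws log2-scale expression as
#' `baseline_g + u_{pg} + e_{sg} + shift_g * 1[site == stricture]`
#' with block-correlated patient intercepts `u` (sd `patient_sd_log2`, shared
#' across a patient's three samples) and residual noise `e`
#' (sd `noise_sd_log2`), then maps to the TPM scale as
#' `pmax(2^x - 1, 0)` so that the preprocessing transform `log2(TPM + 1)`
#' recovers the simulated log2 values exactly for expressed genes (values
#' below zero on the log2 scale are clamped; negligible at the default
#' baselines). Deterministic given `design$seed`.
#'
#' @param design A [cohort_design()].
#' @return A list with elements `expression` (TPM-scale
#'   [expression_matrix()]), `metadata` (sample_id/patient_id/site
#'   data.frame) and `truth` (per-gene data.frame with `is_deg`, `direction`
#'   in up/down/null and `injected_log2fc`).
#' @examples
#' cohort <- generate_cohort(cohort_design(n_patients = 4, n_genes = 100,
#'                                         n_deg_up = 6, n_deg_down = 2))
#' table(cohort$truth$direction)
#' @export
generate_cohort <- function(design) {
  validate_design(design)
  d <- design
  set.seed(stream_seed(d$seed, "expression"))

  genes <- sprintf("g%0*d", max(4L, nchar(d$n_genes)), seq_len(d$n_genes))
  patients <- sprintf("P%02d", seq_len(d$n_patients))
  sites <- c("stricture", "proximal", "distal")
  meta <- data.frame(
    sample_id = as.vector(outer(patients, sites, paste, sep = "_")),
    patient_id = rep(patients, times = 3L),
    site = rep(sites, each = d$n_patients),
    stringsAsFactors = FALSE
  )

  baseline <- runif(d$n_genes, d$baseline_min, d$baseline_max)

  ## injected DEGs live in the expressed range so the truth survives filtering
  n_deg <- d$n_deg_up + d$n_deg_down
  deg_idx <- integer(0)
  if (n_deg > 0) {
    eligible <- which(baseline >= min(d$deg_baseline_min, d$baseline_max))
    if (length(eligible) < n_deg) {
      field_stop("n_genes", "too few genes in the expressed baseline range to host the injected DEGs")
    }
    deg_idx <- sort(sample(eligible, n_deg))
  }
  direction <- rep("null", d$n_genes)
  if (n_deg > 0) {
    up_idx <- sample(deg_idx, d$n_deg_up)
    direction[up_idx] <- "up"
    direction[setdiff(deg_idx, up_idx)] <- "down"
  }
  shift <- ifelse(direction == "up", d$effect_log2fc,
                  ifelse(direction == "down", -d$effect_log2fc, 0))

  n_samples <- nrow(meta)
  noise <- d$noise_sd_log2 *
    block_normal(d$n_genes, n_samples, d$block_size, d$within_block_corr)
  intercept <- d$patient_sd_log2 *
    block_normal(d$n_genes, d$n_patients, d$block_size, d$within_block_corr)
  pat_of <- match(meta$patient_id, patients)

  log2x <- baseline + intercept[, pat_of, drop = FALSE] + noise +
    outer(shift, as.numeric(meta$site == "stricture"))
  tpm <- pmax(2^log2x - 1, 0)
  dimnames(tpm) <- list(genes, meta$sample_id)

  truth <- data.frame(gene = genes, is_deg = direction != "null",
                      direction = direction, injected_log2fc = shift,
                      stringsAsFactors = FALSE)
  list(expression = expression_matrix(tpm, "tpm"), metadata = meta,
       truth = truth)
}

#' Site-level qPCR ground truth for the Ct simulator
#'
#' Specifies, per target gene, the mean delta-Ct shift of each site relative
#' to the calibrator site (whose shift must be 0: a lower Ct means higher
#' expression, one PCR cycle per two-fold change) plus the Gaussian Ct noise
#' standard deviation.
#'
#' @param shifts Named list, one element per target gene, each a numeric
#'   vector named by site giving the mean Ct shift (cycles).
#' @param ct_noise_sd Ct noise sd in cycles (default 0.25).
#' @param calibrator_site Site whose shift must be zero (default "proximal").
#' @param target_ct_baseline,housekeeping_ct Baseline cycle numbers for the
#'   target genes and the housekeeping gene (defaults 24 and 18).
#' @return An object of class `qpcr_truth`.
#' @export
qpcr_truth <- function(shifts, ct_noise_sd = 0.25,
                       calibrator_site = "proximal",
                       target_ct_baseline = 24, housekeeping_ct = 18) {
  if (!is.list(shifts) || is.null(names(shifts)) || any(names(shifts) == "")) {
    field_stop("shifts", "must be a named list (one element per gene)")
  }
  for (g in names(shifts)) {
    s <- shifts[[g]]
    if (is.null(names(s))) field_stop("shifts", sprintf("site names missing for gene '%s'", g))
    if (!calibrator_site %in% names(s)) {
      field_stop("shifts", sprintf("gene '%s' lacks the calibrator site '%s'", g, calibrator_site))
    }
    if (s[[calibrator_site]] != 0) {
      field_stop("shifts", sprintf("calibrator-site shift must be 0 (gene '%s')", g))
    }
  }
  if (ct_noise_sd < 0) field_stop("ct_noise_sd", "must be non-negative")
  structure(list(shifts = shifts, ct_noise_sd = ct_noise_sd,
                 calibrator_site = calibrator_site,
                 target_ct_baseline = target_ct_baseline,
                 housekeeping_ct = housekeeping_ct), class = "qpcr_truth")
}

#' Generate a paired qPCR Ct table
#'
#' For every sample in the design and every target gene in `truth`, draws one
#' housekeeping Ct near its fixed baseline and one target Ct equal to
#' `target_ct_baseline + site shift + noise`. With all shifts 0 and zero
#' noise, downstream `2^-ddCt` relative expression is identically 1.
#' Deterministic given `design$seed`.
#'
#' @param design A [cohort_design()] (only the patient/site layout and seed
#'   are used).
#' @param truth A [qpcr_truth()] whose sites match the design.
#' @return Data.frame with columns `sample_id`, `patient_id`, `site`, `gene`,
#'   `ct_target`, `ct_housekeeping` - the input expected by [ddct()].
#' @export
generate_qpcr <- function(design, truth) {
  validate_design(design)
  stopifnot(inherits(truth, "qpcr_truth"))
  for (g in names(truth$shifts)) {
    unknown <- setdiff(names(truth$shifts[[g]]), design$sites)
    if (length(unknown)) {
      field_stop("shifts", sprintf("unknown site label '%s' (gene '%s')", unknown[1L], g))
    }
  }
  set.seed(stream_seed(design$seed, "qpcr"))
  patients <- sprintf("P%02d", seq_len(design$n_patients))
  sites <- c("stricture", "proximal", "distal")
  grid <- expand.grid(patient_id = patients, site = sites, gene = names(truth$shifts),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$patient_id, grid$site, sep = "_")
  shift <- mapply(function(g, s) {
    sh <- truth$shifts[[g]]
    if (s %in% names(sh)) sh[[s]] else 0
  }, grid$gene, grid$site)
  n <- nrow(grid)
  grid$ct_target <- truth$target_ct_baseline + shift +
    rnorm(n, 0, truth$ct_noise_sd)
  grid$ct_housekeeping <- truth$housekeeping_ct + rnorm(n, 0, truth$ct_noise_sd)
  grid[, c("sample_id", "patient_id", "site", "gene", "ct_target",
           "ct_housekeeping")]
}
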