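#' Relative quantification by the 2^-ddCt method
#'
#' Per sample and gene: `dCt = Ct_target - Ct_housekeeping`;
#' `ddCt = dCt - dCt` of the same patient's calibrator-site sample; relative
#' quantity `rq = 2^-ddCt` (so `log2(rq) = -ddCt` identically and the
#' calibrator samples get rq = 1 by construction). Technical replicates -
#' repeated rows for the same sample and gene - are averaged on the Ct scale
#' first. Patients lacking a calibrator-site sample for a gene are excluded
#' with a warning.
#'
#' @param ct Data.frame with columns `sample_id`, `patient_id`, `site`,
#'   `gene`, `ct_target`, `ct_housekeeping`; Ct values must lie in (0, 45].
#' @param calibrator_site Site serving as the within-patient calibrator
#'   (default `"proximal"`, the non-strictured margin).
#' @return Data.frame with `sample_id`, `patient_id`, `site`, `gene`,
#'   `delta_ct`, `delta_delta_ct`, `rq`.
#' @examples
#' ct <- data.frame(sample_id = c("s1", "s2"), patient_id = "P1",
#'                  site = c("proximal", "stricture"), gene = "GREM1",
#'                  ct_target = c(26, 25), ct_housekeeping = c(20, 20))
#' ddct(ct)  # stricture rq = 2: one cycle earlier = two-fold more transcript
#' @export
ddct <- function(ct, calibrator_site = "proximal") {
  need <- c("sample_id", "patient_id", "site", "gene", "ct_target",
            "ct_housekeeping")
  miss <- setdiff(need, names(ct))
  if (length(miss)) field_stop("ct", paste("missing column(s):", paste(miss, collapse = ", ")))
  cts <- c(ct$ct_target, ct$ct_housekeeping)
  if (any(!is.finite(cts)) || any(cts <= 0) || any(cts > 45)) {
    field_stop("ct", "Ct values must lie in (0, 45]")
  }
  if (!calibrator_site %in% ct$site) {
    field_stop("calibrator_site", sprintf("site '%s' absent from the table", calibrator_site))
  }

  ## average technical replicates on the Ct scale
  key <- interaction(ct$sample_id, ct$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(d) {
    data.frame(sample_id = d$sample_id[1L], patient_id = d$patient_id[1L],
               site = d$site[1L], gene = d$gene[1L],
               ct_target = mean(d$ct_target),
               ct_housekeeping = mean(d$ct_housekeeping),
               stringsAsFactors = FALSE)
  }))
  agg$delta_ct <- agg$ct_target - agg$ct_housekeeping

  out <- do.call(rbind, lapply(split(agg, agg$gene), function(d) {
    cal <- d[d$site == calibrator_site, , drop = FALSE]
    cal_dct <- tapply(cal$delta_ct, cal$patient_id, mean)
    has_cal <- d$patient_id %in% names(cal_dct)
    if (any(!has_cal)) {
      warning(sprintf("gene %s: excluded %d sample(s) from patient(s) without a %s calibrator",
                      d$gene[1L], sum(!has_cal), calibrator_site))
      d <- d[has_cal, , drop = FALSE]
    }
    d$delta_delta_ct <- as.numeric(d$delta_ct - cal_dct[d$patient_id])
    d
  }))
  out$rq <- 2^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out[order(out$gene, out$patient_id, out$site),
      c("sample_id", "patient_id", "site", "gene", "delta_ct",
        "delta_delta_ct", "rq")]
}

#' Kruskal-Wallis comparison of relative expression across sites
#'
#' Rank-based k-group test with tie correction and a chi-square reference on
#' k - 1 degrees of freedom, the study's non-parametric comparison of qPCR
#' relative expression between stricture and the two margins. The statistic
#' is invariant under strictly monotone transforms, so rq and -ddCt give the
#' same answer. All-identical values return H = 0, p = 1.
#'
#' @param values Numeric vector (e.g. rq or ddCt values).
#' @param groups Grouping vector of the same length (>= 2 non-empty groups).
#' @return List with `statistic` (H), `df` and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2L) field_stop("groups", "need at least 2 non-empty groups")
  if (length(values) != length(g)) field_stop("groups", "length mismatch")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Median with a bootstrap percentile confidence interval
#'
#' The study summary for qPCR relative expression: the sample median with a
#' seeded percentile-bootstrap interval.
#'
#' @param values Numeric vector (length >= 3).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling.
#' @return List with `median`, `ci_low`, `ci_high`.
#' @export
median_ci <- function(values, n_boot = 2000, level = 0.95, seed = 1) {
  if (length(values) < 3L) field_stop("values", "need at least 3 values")
  if (level <= 0 || level >= 1) field_stop("level", "must lie in (0, 1)")
  set.seed(stream_seed(seed, "median-ci"))
  boot <- vapply(seq_len(n_boot),
                 function(b) median(sample(values, replace = TRUE)),
                 numeric(1))
  alpha2 <- (1 - level) / 2
  ci <- quantile(boot, c(alpha2, 1 - alpha2), names = FALSE)
  list(median = median(values), ci_low = ci[1L], ci_high = ci[2L])
}
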