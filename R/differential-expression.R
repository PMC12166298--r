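#' Specify a pairwise site contrast
#'
#' The study compares the three resection sites pairwise; orientation is
#' A minus B, so with A = stricture an up-regulated gene has positive log2
#' fold change. Pairing by patient (the default) exploits the matched design:
#' each patient's per-site samples share a random intercept that the paired
#' difference cancels.
#'
#' @param a,b Site labels of groups A and B (must differ).
#' @param paired Block on patient (default `TRUE`); use `FALSE` for external
#'   unmatched cohorts.
#' @param name Optional contrast name (default `"a_vs_b"`).
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(a, b, paired = TRUE, name = NULL) {
  if (identical(a, b)) field_stop("b", "groups A and B must differ")
  structure(list(a = a, b = b, paired = isTRUE(paired),
                 name = name %||% paste0(a, "_vs_", b)),
            class = "contrast_spec")
}

#' Construct an empirical-Bayes variance prior
#'
#' The shrinkage hyperparameters of the moderated t-statistic: a scaled
#' inverse-chi-square prior on per-gene variances with `d0` prior degrees of
#' freedom and prior value `s0_sq`. `d0 = 0` disables shrinkage (ordinary t);
#' `d0 = Inf` shrinks every gene fully to `s0_sq`.
#'
#' @param d0 Prior degrees of freedom (non-negative, possibly `Inf`).
#' @param s0_sq Prior variance (positive).
#' @return An object of class `eb_prior`.
#' @export
eb_prior <- function(d0, s0_sq) {
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0) {
    field_stop("d0", "must be a single non-negative number (possibly Inf)")
  }
  if (!is.numeric(s0_sq) || length(s0_sq) != 1L || !is.finite(s0_sq) || s0_sq <= 0) {
    field_stop("s0_sq", "must be a single positive finite number")
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf("<eb_prior> d0 = %s, s0_sq = %.6g\n",
              if (is.infinite(x$d0)) "Inf" else sprintf("%.4g", x$d0), x$s0_sq))
  invisible(x)
}

## Newton inversion of the trigamma function (used by the method-of-moments
## prior fit); monotone decreasing, so the iteration is safe.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Fit the empirical-Bayes variance prior by method of moments
#'
#' Matches the first two moments of `log(s2)` under the scaled
#' inverse-chi-square model: per-gene sample variances are df-scaled
#' chi-square draws around gene variances that are themselves inverse
#' chi-square around `s0_sq`. When the observed spread of `log(s2)` does not
#' exceed its expected pure-sampling spread, the gene variances are taken as
#' exchangeable: `d0 = Inf` and `s0_sq = mean(s2)` (which reduces to the
#' common value when all variances are identical).
#'
#' @param s2 Vector of per-gene sample variances (>= 0; at least 10 genes).
#' @param df_residual Residual degrees of freedom each `s2` was computed with.
#' @return An [eb_prior()].
#' @export
fit_eb_prior <- function(s2, df_residual) {
  if (length(s2) < 10L) {
    field_stop("s2", "need at least 10 genes to estimate the prior")
  }
  if (any(s2 < 0)) field_stop("s2", "variances must be non-negative")
  if (df_residual <= 0) field_stop("df_residual", "must be positive")
  pos <- s2[s2 > 0]
  if (length(pos) < length(s2)) {
    warning(sprintf("%d zero variance(s) excluded from the prior fit",
                    length(s2) - length(pos)))
  }
  if (length(pos) == 0L) field_stop("s2", "all variances are zero")
  if (length(pos) < 2L || var(pos) == 0) {
    return(eb_prior(Inf, mean(pos)))
  }
  df <- df_residual
  e <- log(pos) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar <= 0) {
    eb_prior(Inf, mean(pos))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    eb_prior(d0, s0)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control, order-preserving with respect to the
#' input indexing and clipped at 1. Inputs must be valid P values in (0, 1].
#'
#' @param p Vector of raw P values.
#' @return Vector of BH-adjusted P values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    field_stop("p", "all P values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Moderated-t differential expression for one site contrast
#'
#' Per gene, the group difference in mean log2 expression is tested with a
#' t-statistic whose variance is shrunk toward the empirical-Bayes prior:
#' `s2_tilde = (d0 * s0_sq + df_g * s2_g) / (d0 + df_g)`,
#' `t_mod = log2fc / sqrt(s2_tilde * c)` on `d0 + df_g` degrees of freedom,
#' where `c` is the contrast variance coefficient (1/n_pairs paired,
#' 1/n_A + 1/n_B unpaired). P values are BH-adjusted across genes within the
#' contrast and a gene is flagged `is_deg` when the adjusted P falls below
#' `alpha` and the absolute log2 fold change reaches `log2(fc_threshold)`.
#'
#' @param m A filtered log2-scale [expression_matrix()].
#' @param meta Sample metadata (`sample_id`, `patient_id`, `site`).
#' @param contrast A [contrast_spec()].
#' @param prior An [eb_prior()]; fitted from the contrast's residual
#'   variances when `NULL` (the default).
#' @param alpha Adjusted-P significance level (default 0.05).
#' @param fc_threshold Fold-change gate on the natural scale (default 2,
#'   i.e. |log2fc| >= 1).
#' @return Data.frame, one row per gene: `gene`, `log2fc`, `s2`, `s2_tilde`,
#'   `t_mod`, `df_total`, `p_raw`, `p_adj`, `is_deg`; the contrast and prior
#'   are attached as attributes.
#' @export
moderated_t <- function(m, meta, contrast, prior = NULL, alpha = 0.05,
                        fc_threshold = 2) {
  stopifnot(inherits(m, "expr_matrix"), inherits(contrast, "contrast_spec"))
  if (expr_scale(m) != "log2") field_stop("scale", "expression must be log2-transformed")
  meta <- check_meta(m, meta)
  for (g in c(contrast$a, contrast$b)) {
    if (!g %in% meta$site) field_stop("contrast", sprintf("site '%s' absent from metadata", g))
  }
  v <- expr_values(m)
  a_cols <- meta$sample_id[meta$site == contrast$a]
  b_cols <- meta$sample_id[meta$site == contrast$b]

  if (contrast$paired) {
    pa <- meta$patient_id[match(a_cols, meta$sample_id)]
    pb <- meta$patient_id[match(b_cols, meta$sample_id)]
    shared <- intersect(pa, pb)
    if (length(shared) < 2L) {
      stop("fewer than 2 complete pairs for the paired contrast", call. = FALSE)
    }
    D <- v[, a_cols[match(shared, pa)], drop = FALSE] -
      v[, b_cols[match(shared, pb)], drop = FALSE]
    log2fc <- rowMeans(D)
    s2 <- apply(D, 1L, var)
    df_g <- length(shared) - 1L
    cc <- 1 / length(shared)
  } else {
    if (length(a_cols) < 2L || length(b_cols) < 2L) {
      stop("fewer than 2 observations in a group for the unpaired contrast",
           call. = FALSE)
    }
    va <- v[, a_cols, drop = FALSE]
    vb <- v[, b_cols, drop = FALSE]
    log2fc <- rowMeans(va) - rowMeans(vb)
    ssa <- apply(va, 1L, function(x) sum((x - mean(x))^2))
    ssb <- apply(vb, 1L, function(x) sum((x - mean(x))^2))
    df_g <- length(a_cols) + length(b_cols) - 2L
    s2 <- (ssa + ssb) / df_g
    cc <- 1 / length(a_cols) + 1 / length(b_cols)
  }

  if (is.null(prior)) prior <- fit_eb_prior(s2, df_g)
  stopifnot(inherits(prior, "eb_prior"))
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) rep(prior$s0_sq, length(s2)) else
    (d0 * prior$s0_sq + df_g * s2) / (d0 + df_g)
  t_mod <- log2fc / sqrt(s2_tilde * cc)
  df_total <- d0 + df_g
  p_raw <- 2 * pt(-abs(t_mod), df = df_total)
  p_raw <- pmax(p_raw, .Machine$double.xmin)  # keep within (0, 1]
  p_adj <- bh_adjust(p_raw)
  res <- data.frame(gene = rownames(v), log2fc = unname(log2fc),
                    s2 = unname(s2),
                    s2_tilde = unname(s2_tilde), t_mod = unname(t_mod),
                    df_total = df_total, p_raw = unname(p_raw),
                    p_adj = unname(p_adj),
                    is_deg = unname(p_adj < alpha &
                                      abs(log2fc) >= log2(fc_threshold)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast
  attr(res, "prior") <- prior
  attr(res, "alpha") <- alpha
  attr(res, "fc_threshold") <- fc_threshold
  res
}

#' Sign-consistent overlap of two DEG contrasts
#'
#' Genes significant in both contrasts with agreeing fold-change sign -
#' the study's definition of the stricture signature (significant against
#' both the proximal and the distal margin, in the same direction).
#'
#' @param a,b Results of [moderated_t()] computed on the same gene universe.
#' @return List of class `overlap_result`: `genes` (data.frame with `gene`,
#'   `direction`, per-contrast log2fc), counts `n_up`, `n_down`, and the
#'   per-contrast DEG counts `n_deg_a`, `n_deg_b`.
#' @export
overlap_deg <- function(a, b) {
  if (!setequal(a$gene, b$gene)) {
    stop("mismatched gene universes between the two contrasts", call. = FALSE)
  }
  b <- b[match(a$gene, b$gene), , drop = FALSE]
  both <- a$is_deg & b$is_deg & sign(a$log2fc) == sign(b$log2fc) &
    a$log2fc != 0
  genes <- data.frame(gene = a$gene[both],
                      direction = ifelse(a$log2fc[both] > 0, "up", "down"),
                      log2fc_a = a$log2fc[both], log2fc_b = b$log2fc[both],
                      row.names = NULL, stringsAsFactors = FALSE)
  genes <- genes[order(-abs(genes$log2fc_a)), , drop = FALSE]
  structure(list(genes = genes,
                 n_up = sum(genes$direction == "up"),
                 n_down = sum(genes$direction == "down"),
                 n_deg_a = sum(a$is_deg), n_deg_b = sum(b$is_deg)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %d shared DEGs (%d up, %d down); per-contrast %d / %d\n",
              nrow(x$genes), x$n_up, x$n_down, x$n_deg_a, x$n_deg_b))
  invisible(x)
}
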