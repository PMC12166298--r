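#' Multivariate log-normal expression model
#'
#' Gaussian model on the log2(TPM + 1) scale: per-gene means `mu` and a
#' covariance matrix `sigma`. An indefinite input covariance (e.g. a
#' hand-built one) is repaired to the nearest positive-semidefinite matrix by
#' clipping negative eigenvalues at zero, with the repair flagged.
#'
#' @param genes Gene ids.
#' @param mu Per-gene log2-scale means.
#' @param sigma Log2-scale covariance matrix (symmetric).
#' @return List of class `lognormal_model` with `genes`, `mu`, `sigma`,
#'   `repair_applied` and `constant_genes`.
#' @export
lognormal_model <- function(genes, mu, sigma) {
  sigma <- as.matrix(sigma)
  p <- length(genes)
  if (length(mu) != p || nrow(sigma) != p || ncol(sigma) != p) {
    field_stop("sigma", "dimensions must match the gene count")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    field_stop("sigma", "must be symmetric")
  }
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  tol <- 1e-8 * max(1, abs(ev$values[1L]))
  repair <- any(ev$values < -tol)
  if (any(ev$values < 0)) {
    sigma <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    sigma <- (sigma + t(sigma)) / 2
    dimnames(sigma) <- list(genes, genes)
    if (repair) warning("covariance repaired to nearest positive semidefinite (eigenvalue clipping)")
  }
  constant <- genes[diag(sigma) <= 0]
  if (length(constant)) warning(sprintf("%d constant gene(s) in the model", length(constant)))
  dimnames(sigma) <- list(genes, genes)
  structure(list(genes = as.character(genes), mu = setNames(as.numeric(mu), genes),
                 sigma = sigma, repair_applied = repair,
                 constant_genes = constant),
            class = "lognormal_model")
}

#' Fit the multivariate log-normal model to a TPM matrix
#'
#' `mu` and `sigma` are the sample mean and covariance of log2(TPM + 1)
#' across samples. With more genes than samples the sample covariance is
#' singular but still positive semidefinite, which is all the simulator
#' needs; fitting is best restricted to a modest gene subset (the selected
#' signature genes).
#'
#' @param m A TPM-scale [expression_matrix()].
#' @param genes Optional gene subset (default: all genes).
#' @return A [lognormal_model()].
#' @export
fit_lognormal <- function(m, genes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "tpm") field_stop("scale", "fit expects a TPM-scale matrix")
  v <- expr_values(m)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) field_stop("genes", sprintf("gene '%s' absent from the matrix", miss[1L]))
    v <- v[genes, , drop = FALSE]
  }
  if (ncol(v) < 3L) field_stop("samples", "need at least 3 samples to fit")
  x <- log2(v + 1)
  lognormal_model(rownames(x), rowMeans(x), cov(t(x)))
}

#' Specify a Cohen's d effect for the power simulator
#'
#' The effect is realized as a log2-scale mean shift of `d` standard
#' deviations of the target gene (the scale on which the Gaussian machinery
#' lives - d on the TPM scale would differ). When `propagate` is set, every
#' model gene whose absolute correlation with the target reaches
#' `corr_threshold` receives the same standardized shift, mirroring how a
#' biological effect carries its co-expressed neighbors.
#'
#' @param target Target gene id.
#' @param d Cohen's d (standardized mean difference).
#' @param corr_threshold Correlation cutoff in `[0, 1]` for propagation
#'   (default 0.8).
#' @param propagate Shift highly correlated genes too (default `TRUE`).
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(target, d, corr_threshold = 0.8, propagate = TRUE) {
  if (!is.numeric(corr_threshold) || corr_threshold < 0 || corr_threshold > 1) {
    field_stop("corr_threshold", "must lie in [0, 1]")
  }
  structure(list(target = target, d = d, corr_threshold = corr_threshold,
                 propagate = isTRUE(propagate)), class = "effect_spec")
}

## genes receiving the shift: target plus (optionally) its correlated set
shifted_genes <- function(model, effect) {
  if (!effect$target %in% model$genes) {
    field_stop("target", sprintf("gene '%s' absent from the model", effect$target))
  }
  if (!effect$propagate) return(effect$target)
  sds <- sqrt(diag(model$sigma))
  ok <- sds > 0
  r <- rep(0, length(model$genes))
  names(r) <- model$genes
  ti <- match(effect$target, model$genes)
  if (sds[ti] > 0) {
    r[ok] <- model$sigma[ok, ti] / (sds[ok] * sds[ti])
  }
  r[ti] <- 1
  model$genes[abs(r) >= effect$corr_threshold]
}

#' Simulate two groups from the log-normal model with an injected effect
#'
#' Both groups are drawn from the fitted Gaussian on the log2 scale; group
#' B's mean for the target gene (and, when propagated, its highly correlated
#' genes) is shifted by `d` times that gene's log-scale standard deviation.
#' Returned matrices are on the log2(TPM + 1) scale, ready for the ANOVA
#' readout.
#'
#' @param model A [lognormal_model()].
#' @param effect An [effect_spec()].
#' @param n_per_group Samples per group (>= 2).
#' @param seed Optional seed; `NULL` continues the caller's RNG stream.
#' @return List with genes x n matrices `a` (null group) and `b` (shifted
#'   group) and the `shifted_genes` character vector.
#' @export
simulate_two_groups <- function(model, effect, n_per_group, seed = NULL) {
  stopifnot(inherits(model, "lognormal_model"), inherits(effect, "effect_spec"))
  if (n_per_group < 2L) field_stop("n_per_group", "must be at least 2")
  if (!is.null(seed)) set.seed(stream_seed(seed, "two-groups"))
  sh <- shifted_genes(model, effect)
  mu_b <- model$mu
  mu_b[sh] <- mu_b[sh] + effect$d * sqrt(diag(model$sigma))[sh]
  draw <- function(mu, tag) {
    x <- mvrnorm(n_per_group, mu, model$sigma)
    if (is.null(dim(x))) x <- matrix(x, ncol = length(mu))
    x <- t(x)
    dimnames(x) <- list(model$genes, paste0(tag, seq_len(n_per_group)))
    x
  }
  a <- draw(model$mu, "a")
  b <- draw(mu_b, "b")
  list(a = a, b = b, shifted_genes = sh)
}

#' One-way ANOVA P value for a two-group comparison
#'
#' Fixed-effects one-way ANOVA F test on log-scale values (for two groups,
#' F is exactly the square of the pooled two-sample t statistic). Degenerate
#' inputs with zero within-group variance return p = 1 when the means also
#' agree (flagged with a warning) and p = 0 when they differ (the F = Inf
#' limit).
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return The P value, with the F statistic attached as attribute
#'   `statistic`.
#' @export
anova_pvalue <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) field_stop("groups", "each group needs >= 2 values")
  v <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (ssw == 0) {
    if (mean(a) == mean(b)) {
      warning("zero within-group variance with equal means; p = 1 by convention")
      p <- 1
      f <- 0
    } else {
      p <- 0
      f <- Inf
    }
  } else {
    ow <- oneway.test(v ~ g, var.equal = TRUE)
    p <- ow$p.value
    f <- unname(ow$statistic)
  }
  attr(p, "statistic") <- f
  p
}

#' Simulated power curve over a sample-size grid
#'
#' For each grid size n, draws `n_reps` paired datasets from the model with
#' the effect injected into group B and records how often the target gene's
#' one-way ANOVA rejects at `alpha`. The grid default includes n = 20, the
#' headline size at which the strongest signature genes reach 75% power.
#' Only the genes whose distribution matters for the readout are simulated;
#' `sweep = TRUE` instead runs the per-variable screen across every model
#' gene.
#'
#' @param model A [lognormal_model()].
#' @param effect An [effect_spec()].
#' @param n_grid Strictly increasing group sizes
#'   (default `c(5, 10, 15, 20, 50, 100)`).
#' @param n_reps Monte-Carlo replicates per n (>= 100; default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed; each grid size gets its own derived stream.
#' @param sweep Report per-gene power for all model genes instead of the
#'   target only (default `FALSE`).
#' @return For the default readout, a list of class `power_curve` with a
#'   `curve` data.frame (`n`, `power`, `mc_se`) plus the effect, alpha,
#'   `n_reps` and seed; for `sweep = TRUE`, a genes x grid matrix of power.
#' @export
power_curve <- function(model, effect, n_grid = c(5, 10, 15, 20, 50, 100),
                        n_reps = 1000, alpha = 0.05, seed = 1, sweep = FALSE) {
  stopifnot(inherits(model, "lognormal_model"), inherits(effect, "effect_spec"))
  if (length(n_grid) < 1L || any(diff(n_grid) <= 0)) {
    field_stop("n_grid", "must be strictly increasing")
  }
  if (any(n_grid < 2)) field_stop("n_grid", "group sizes must be >= 2")
  if (n_reps < 100L) field_stop("n_reps", "need at least 100 replicates")
  if (alpha <= 0 || alpha >= 1) field_stop("alpha", "must lie in (0, 1)")

  if (!sweep) {
    ## the target's marginal law is unaffected by shifts on other genes,
    ## so simulating the target alone is exact and fast
    ti <- match(effect$target, model$genes)
    if (is.na(ti)) field_stop("target", sprintf("gene '%s' absent from the model", effect$target))
    model_use <- lognormal_model(model$genes[ti], model$mu[ti],
                                 model$sigma[ti, ti, drop = FALSE])
    eff_use <- effect_spec(effect$target, effect$d, effect$corr_threshold,
                           propagate = FALSE)
    genes_out <- effect$target
  } else {
    model_use <- model
    eff_use <- effect
    genes_out <- model$genes
  }

  rej <- matrix(0, length(genes_out), length(n_grid),
                dimnames = list(genes_out, n_grid))
  for (i in seq_along(n_grid)) {
    set.seed(stream_seed(seed, paste0("power-n", n_grid[i])))
    for (r in seq_len(n_reps)) {
      sim <- simulate_two_groups(model_use, eff_use, n_grid[i], seed = NULL)
      for (g in genes_out) {
        p <- suppressWarnings(anova_pvalue(sim$a[g, ], sim$b[g, ]))
        rej[g, i] <- rej[g, i] + (as.numeric(p) < alpha)
      }
    }
  }
  pow <- rej / n_reps
  if (sweep) return(pow)
  curve <- data.frame(n = n_grid, power = pow[1L, ],
                      mc_se = sqrt(pow[1L, ] * (1 - pow[1L, ]) / n_reps),
                      row.names = NULL)
  structure(list(curve = curve, target = effect$target, d = effect$d,
                 alpha = alpha, n_reps = n_reps, seed = seed),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("<power_curve> %s, d = %.3g, alpha = %g, %d reps/n\n",
              x$target, x$d, x$alpha, x$n_reps))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Smallest grid sample size reaching a target power
#'
#' @param curve A [power_curve()] result.
#' @param target_power Power to reach, in (0, 1) (default 0.75).
#' @return The smallest grid n whose simulated power reaches
#'   `target_power`, or `NA_integer_` (with attribute `reached = FALSE`)
#'   when no grid size does.
#' @export
required_n <- function(curve, target_power = 0.75) {
  stopifnot(inherits(curve, "power_curve"))
  if (target_power <= 0 || target_power >= 1) {
    field_stop("target_power", "must lie in (0, 1)")
  }
  hit <- which(curve$curve$power >= target_power)
  if (length(hit) == 0L) {
    return(structure(NA_integer_, reached = FALSE))
  }
  structure(as.integer(curve$curve$n[hit[1L]]), reached = TRUE)
}

#' Cohen's d between two groups
#'
#' Standardized mean difference with the pooled standard deviation - the
#' effect-size currency of the sample-size simulator.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) field_stop("groups", "each group needs >= 2 values")
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}
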