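test_that("the variance prior collapses to the common value under zero dispersion", {
  pr <- fit_eb_prior(rep(2, 50), df_residual = 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 2)
  expect_error(fit_eb_prior(c(1, 2), 4), "at least 10")
})

test_that("the prior fit recovers simulated inverse-chi-square hyperparameters", {
  set.seed(11)
  d0 <- 4; s0 <- 1; df <- 8; n <- 6000
  sig2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sig2 * rchisq(n, df) / df
  pr <- fit_eb_prior(s2, df)
  expect_lt(abs(pr$d0 - d0), 1)
  expect_lt(abs(pr$s0_sq - s0), 0.2)
})

test_that("moderated t matches the hand-evaluated shrinkage formula", {
  # two groups of 3, mean difference 2, pooled s2 = 1 on 4 df
  x <- rbind(gene = c(1, 2, 3, -1, 0, 1))
  m <- toy_expr(x, genes = "gene", samples = paste0("s", 1:6))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     patient_id = paste0("p", 1:6),
                     site = rep(c("stricture", "proximal"), each = 3))
  res <- moderated_t(m, meta, contrast_spec("stricture", "proximal", paired = FALSE),
                     prior = eb_prior(4, 1))
  expect_equal(res$log2fc, 2)
  expect_equal(res$s2, 1)
  expect_equal(res$s2_tilde, 1)
  expect_equal(res$t_mod, 2 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(res$df_total, 8)
})

test_that("a d0 = 0 prior reproduces the ordinary two-sample t exactly", {
  set.seed(4)
  n <- 10
  x <- matrix(rnorm(40 * n, 5, 1), 40, n,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:n)))
  m <- expression_matrix(x, "log2")
  meta <- data.frame(sample_id = paste0("s", 1:n), patient_id = paste0("p", 1:n),
                     site = rep(c("stricture", "proximal"), each = n / 2))
  res <- moderated_t(m, meta, contrast_spec("stricture", "proximal", paired = FALSE),
                     prior = eb_prior(0, 1))
  ref <- apply(x, 1, function(v) {
    tt <- t.test(v[1:5], v[6:10], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_equal(res$t_mod, unname(ref[1, ]), tolerance = 1e-9)
  expect_equal(res$p_raw, unname(ref[2, ]), tolerance = 1e-9)
})

test_that("a null gene with identical group means gets t = 0, p = 1", {
  x <- rbind(flat = rep(c(2, 3, 4), 2))
  m <- toy_expr(x, genes = "flat", samples = paste0("s", 1:6))
  meta <- data.frame(sample_id = paste0("s", 1:6), patient_id = paste0("p", 1:6),
                     site = rep(c("stricture", "distal"), each = 3))
  res <- moderated_t(m, meta, contrast_spec("stricture", "distal", paired = FALSE),
                     prior = eb_prior(4, 1))
  expect_equal(res$t_mod, 0)
  expect_equal(res$p_raw, 1)
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(42)
  g <- 500; n <- 12
  sig <- sqrt(4 * 0.8 / rchisq(g, 4))   # heterogeneous true variances
  x <- matrix(rnorm(g * n, 5, sig), g, n,
              dimnames = list(sprintf("g%03d", 1:g), paste0("s", 1:n)))
  x[1:25, 1:6] <- x[1:25, 1:6] + 1.5
  m <- expression_matrix(x, "log2")
  meta <- data.frame(sample_id = paste0("s", 1:n), patient_id = paste0("p", 1:n),
                     site = rep(c("stricture", "proximal"), each = 6))
  mine <- moderated_t(m, meta, contrast_spec("stricture", "proximal", paired = FALSE))
  design <- cbind(B = 1, A = rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(mine, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "prior")$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t_mod, unname(fit$t[, "A"]), tolerance = 1e-9)
  expect_equal(mine$p_raw, unname(fit$p.value[, "A"]), tolerance = 1e-6)
})

test_that("moderated-t p-values are uniform under a fully null matrix", {
  set.seed(8)
  g <- 3000; n <- 10
  x <- matrix(rnorm(g * n, 5, 1), g, n,
              dimnames = list(sprintf("g%04d", 1:g), paste0("s", 1:n)))
  m <- expression_matrix(x, "log2")
  meta <- data.frame(sample_id = paste0("s", 1:n), patient_id = paste0("p", 1:n),
                     site = rep(c("stricture", "proximal"), each = 5))
  res <- moderated_t(m, meta, contrast_spec("stricture", "proximal", paired = FALSE))
  expect_gt(ks.test(res$p_raw, "punif")$p.value, 0.01)
})

test_that("|t_mod| is monotone in the mean difference, all else fixed", {
  base <- c(0.3, -0.1, 0.2, -0.4, 0.1, -0.1)
  meta <- data.frame(sample_id = paste0("s", 1:6), patient_id = paste0("p", 1:6),
                     site = rep(c("stricture", "proximal"), each = 3))
  tstat <- sapply(seq(0, 3, by = 0.25), function(delta) {
    x <- rbind(g1 = base + c(delta, delta, delta, 0, 0, 0))
    m <- toy_expr(x, genes = "g1", samples = paste0("s", 1:6))
    abs(moderated_t(m, meta, contrast_spec("stricture", "proximal", paired = FALSE),
                    prior = eb_prior(4, 1))$t_mod)
  })
  expect_true(all(diff(tstat) >= 0))
})

test_that("BH adjustment matches the hand example and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.02 * 4 / 3, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")

  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
  }
  # adjusted values never fall below raw ones
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("DEG overlap applies set logic with sign consistency", {
  mk <- function(genes, lfc, deg) {
    data.frame(gene = genes, log2fc = lfc, is_deg = deg,
               stringsAsFactors = FALSE)
  }
  a <- mk(c("g1", "g2", "g3", "g4"), c(2, 1.5, -1.2, 0.1),
          c(TRUE, TRUE, TRUE, FALSE))
  b <- mk(c("g1", "g2", "g3", "g4"), c(-1.1, 1.2, -2, 1.4),
          c(TRUE, TRUE, TRUE, TRUE))
  ov <- overlap_deg(a, b)
  # g1 flips sign between contrasts and is excluded; g4 not deg in a
  expect_setequal(ov$genes$gene, c("g2", "g3"))
  expect_equal(ov$n_up, 1)
  expect_equal(ov$n_down, 1)
  expect_equal(ov$n_deg_a, 3)
  expect_equal(ov$n_deg_b, 4)
  expect_error(overlap_deg(a, b[1:3, ]), "mismatched gene universes")
})
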