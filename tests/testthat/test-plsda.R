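make_labeled_matrix <- function(n_genes, n_samples, seed = 1,
                                signal_genes = 0, delta = 2) {
  set.seed(seed)
  lab <- rep(c("margin", "stricture"), length.out = n_samples)
  x <- matrix(rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (signal_genes > 0) {
    x[seq_len(signal_genes), lab == "stricture"] <-
      x[seq_len(signal_genes), lab == "stricture"] + delta
  }
  list(m = expression_matrix(x, "log2"), labels = lab)
}

test_that("the informative gene dominates the first weight vector", {
  lab <- rep(c("margin", "stricture"), each = 6)
  set.seed(2)
  x <- rbind(signal = 5 + 2 * (lab == "stricture") + rnorm(12, 0, 0.1),
             noise = rnorm(12, 5, 1))
  m <- toy_expr(x, genes = c("signal", "noise"))
  fit <- fit_plsda(m, lab, n_components = 1)
  expect_gt(abs(fit$weights["signal", 1]), abs(fit$weights["noise", 1]))
  expect_gt(fit$vip["signal"], fit$vip["noise"])
})

test_that("VIP identities hold: single predictor = 1, mean square = 1, hand case", {
  lab <- rep(c("margin", "stricture"), each = 4)
  set.seed(3)
  single <- toy_expr(matrix(rnorm(8, 5, 1), 1, 8), genes = "only")
  expect_equal(unname(vip_scores(fit_plsda(single, lab, 1))), 1, tolerance = 1e-12)

  # gene 1 carries the response, gene 2 is orthogonal: weights (1, 0)
  y <- c(-1, -1, 1, 1)
  x <- cbind(g1 = y, g2 = c(1, -1, -1, 1))
  m <- toy_expr(t(x), genes = c("g1", "g2"), samples = paste0("s", 1:4))
  fit <- fit_plsda(m, c("a", "a", "b", "b"), n_components = 1)
  expect_equal(unname(fit$vip), c(sqrt(2), 0), tolerance = 1e-8)

  for (seed in 1:5) {
    inst <- make_labeled_matrix(15, 14, seed = seed, signal_genes = 3)
    fit <- fit_plsda(inst$m, inst$labels, n_components = 2)
    expect_equal(mean(vip_scores(fit)^2), 1, tolerance = 1e-8)
  }
})

test_that("NIPALS scores are orthogonal across components", {
  for (seed in 1:5) {
    inst <- make_labeled_matrix(20, 16, seed = seed, signal_genes = 4)
    fit <- fit_plsda(inst$m, inst$labels, n_components = 3)
    gram <- crossprod(fit$scores)
    expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  }
})

test_that("one-component predictions equal the independent PLS1 oracle", {
  for (seed in 1:5) {
    inst <- make_labeled_matrix(10, 20, seed = seed, signal_genes = 2)
    fit <- fit_plsda(inst$m, inst$labels, n_components = 1)
    x <- t(expr_values(inst$m))
    y <- as.numeric(inst$labels == "stricture")
    expect_equal(unname(predict(fit, x, n_components = 1)),
                 unname(pls1_oracle_predict(x, y)), tolerance = 1e-6)
  }
})

test_that("cross-validation separates signal from permuted labels", {
  # labels perfectly encoded by one gene, no noise genes
  set.seed(7)
  lab <- rep(c("margin", "stricture"), each = 10)
  x <- rbind(encode = ifelse(lab == "stricture", 7, 3) + rnorm(20, 0, 0.05))
  m <- toy_expr(x, genes = "encode")
  cv <- cross_validate_plsda(m, lab, n_components = 2)
  expect_gte(cv$q2_cum[1], 0.9)
  expect_true(all(cv$r2_cum >= cv$q2_cum - 1e-12))

  inst <- make_labeled_matrix(30, 20, seed = 7, signal_genes = 1, delta = 6)
  set.seed(99)
  q2_perm <- replicate(20, {
    perm <- sample(inst$labels)
    max(cross_validate_plsda(inst$m, perm, n_components = 1)$q2_cum)
  })
  expect_lte(mean(q2_perm), 0)
})

test_that("VIP selection respects the strict threshold", {
  lab <- rep(c("a", "b"), each = 4)
  y <- rep(c(-1, 1), each = 4)
  # every gene identical to the response: all VIP exactly 1
  x <- rbind(g1 = y, g2 = y, g3 = y) + 5
  m <- toy_expr(x, genes = c("g1", "g2", "g3"), samples = paste0("s", 1:8))
  fit <- fit_plsda(m, lab, n_components = 1)
  expect_equal(unname(fit$vip), rep(1, 3), tolerance = 1e-10)
  expect_equal(nrow(select_genes(fit, 1)$genes), 0)
  sel0 <- select_genes(fit, 0)
  expect_setequal(sel0$genes$gene, c("g1", "g2", "g3"))

  inst <- make_labeled_matrix(12, 10, seed = 2, signal_genes = 2)
  fit2 <- fit_plsda(inst$m, inst$labels)
  sel <- select_genes(fit2, 1)
  expect_true(all(sel$genes$vip > 1))
  expect_false(is.unsorted(rev(sel$genes$vip)))
})

test_that("degenerate inputs are rejected or excluded with a warning", {
  lab <- rep(c("a", "b"), each = 3)
  x <- rbind(flat = rep(5, 6), ok = c(1, 2, 3, 6, 7, 8))
  m <- toy_expr(x, genes = c("flat", "ok"))
  expect_warning(fit <- fit_plsda(m, lab, 1), "zero-variance")
  expect_equal(fit$genes, "ok")
  expect_error(fit_plsda(m, rep("a", 6), 1), "two classes")
})
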