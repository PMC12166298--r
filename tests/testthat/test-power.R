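test_that("the log-normal fit matches a hand-computed mean and covariance", {
  tpm <- rbind(g1 = c(1, 3, 7, 15),
               g2 = c(0, 1, 3, 7))
  m <- toy_expr(tpm, scale = "tpm", genes = c("g1", "g2"),
                samples = paste0("s", 1:4))
  fit <- fit_lognormal(m)
  x1 <- log2(tpm[1, ] + 1)  # 1 2 3 4
  x2 <- log2(tpm[2, ] + 1)  # 0 1 2 3
  expect_equal(unname(fit$mu), c(mean(x1), mean(x2)))
  expect_equal(unname(fit$sigma),
               unname(cov(cbind(x1, x2))), tolerance = 1e-12)
  expect_false(fit$repair_applied)
  expect_error(fit_lognormal(toy_expr(tpm[, 1:2], scale = "tpm")), "3 samples")
})

test_that("model parameters are recovered from simulated data", {
  mu <- c(a = 4, b = 6, c = 5)
  sig <- matrix(c(1, 0.6, 0, 0.6, 1, 0, 0, 0, 2), 3, 3)
  model <- lognormal_model(names(mu), mu, sig)
  sim <- simulate_two_groups(model, effect_spec("a", 0), 500, seed = 12)
  tpm <- pmax(2^sim$a - 1, 0)
  refit <- fit_lognormal(expression_matrix(tpm, "tpm"))
  expect_true(all(abs(refit$mu - mu) < 0.05 * pmax(1, abs(mu)) + 0.05))
  expect_true(all(abs(cov2cor(refit$sigma) - cov2cor(sig)) < 0.1))
})

test_that("an indefinite covariance is repaired to PSD with a flag", {
  sig <- matrix(c(1, 1.5, 1.5, 1), 2, 2)  # eigenvalues 2.5 and -0.5
  expect_warning(model <- lognormal_model(c("a", "b"), c(0, 0), sig),
                 "repaired")
  expect_true(model$repair_applied)
  expect_gte(min(eigen(model$sigma, symmetric = TRUE)$values), 0)
})

test_that("effect propagation respects the correlation threshold", {
  sig <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.1,
                  0.1, 0.1, 1), 3, 3)
  model <- lognormal_model(c("t", "hi", "lo"), c(0, 0, 0), sig)
  sim_all <- simulate_two_groups(model, effect_spec("t", 1, corr_threshold = 0.8),
                                 5, seed = 1)
  expect_setequal(sim_all$shifted_genes, c("t", "hi"))
  sim_one <- simulate_two_groups(model, effect_spec("t", 1, corr_threshold = 1.0),
                                 5, seed = 1)
  expect_identical(sim_one$shifted_genes, "t")
  expect_error(simulate_two_groups(model, effect_spec("zz", 1), 5, seed = 1),
               "absent")
})

test_that("the injected d is consistent with the realized standardized difference", {
  model <- lognormal_model("g", 5, matrix(1.7))
  sim <- simulate_two_groups(model, effect_spec("g", 1), 2000, seed = 4)
  expect_lt(abs(cohens_d(sim$b["g", ], sim$a["g", ]) - 1), 0.05)
  # d = 0: the two groups are exchangeable
  sim0 <- simulate_two_groups(model, effect_spec("g", 0), 2000, seed = 4)
  expect_lt(abs(mean(sim0$a) - mean(sim0$b)), 0.1)
})

test_that("the two-group ANOVA handles hand cases and equals t-squared", {
  p_eq <- suppressWarnings(anova_pvalue(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(as.numeric(p_eq), 1)
  expect_equal(attr(p_eq, "statistic"), 0)
  p_inf <- anova_pvalue(c(0, 0), c(1, 1))
  expect_lt(as.numeric(p_inf), 0.01)

  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), 0.5)
    p <- anova_pvalue(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(attr(p, "statistic"), unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(as.numeric(p), tt$p.value, tolerance = 1e-9)
  }
})

test_that("power curves are seeded, monotone in n, and required_n behaves at the extremes", {
  model <- lognormal_model("g", 5, matrix(1))
  strong <- power_curve(model, effect_spec("g", 3), n_grid = c(5, 10, 20),
                        n_reps = 200, seed = 2)
  expect_equal(required_n(strong), 5L, ignore_attr = TRUE)
  expect_true(all(diff(strong$curve$power) >= -2 * max(strong$curve$mc_se)))

  null <- power_curve(model, effect_spec("g", 0), n_grid = c(5, 20),
                      n_reps = 200, seed = 2)
  rn <- required_n(null)
  expect_true(is.na(rn))
  expect_false(attr(rn, "reached"))

  again <- power_curve(model, effect_spec("g", 3), n_grid = c(5, 10, 20),
                       n_reps = 200, seed = 2)
  expect_identical(strong$curve, again$curve)
})

test_that("cohens_d matches its definition on a hand example", {
  # means 3 and 1, pooled sd 1: d = 2
  expect_equal(cohens_d(c(2, 3, 4), c(0, 1, 2)), 2)
})
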