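test_that("log-CPM matches the offset formula exactly", {
  m <- matrix(c(0L, 1L), 1, 2, dimnames = list("g1", c("s1", "s2")))
  cm <- count_matrix(m, library_sizes = c(s1 = 999999, s2 = 3999999))
  expect_warning(we <- logcpm_transform(cm), "unit weights")
  expect_equal(unname(we$E["g1", "s1"]), log2(0.5), tolerance = 1e-12)
  expect_equal(unname(we$E["g1", "s2"]), log2(0.375), tolerance = 1e-12)
})

test_that("homoscedastic data yields near-constant precision weights", {
  set.seed(1)
  n_g <- 200
  n_s <- 20
  counts <- matrix(rpois(n_g * n_s, 1000), n_g, n_s,
                   dimnames = list(sprintf("g%03d", 1:n_g),
                                   sprintf("s%02d", 1:n_s)))
  cm <- count_matrix(counts)
  we <- logcpm_transform(cm)
  expect_lt(max(we$weights) / min(we$weights), 1.2)
})

test_that("voom-style weights agree with the reference implementation", {
  skip_if_not_installed("limma")
  cfg <- null_config(n_genes = 500, seed = 8, n = 5)
  sim <- simulate_counts(cfg)
  design <- cbind(1, as.numeric(sim$meta$group == "disease"))
  we <- logcpm_transform(sim$gene, design = design)
  v <- limma::voom(sim$gene$counts, design = design,
                   lib.size = sim$gene$library_sizes)
  expect_equal(we$E, v$E, tolerance = 1e-10)
  expect_gt(cor(as.vector(we$weights), as.vector(v$weights)), 0.95)
})

test_that("weighted LM recovers group means, is weight-scale invariant, flags df 0", {
  E <- rbind(g1 = c(1, 3, 6, 10), g2 = c(0, 0, 2, 2))
  colnames(E) <- paste0("s", 1:4)
  design <- cbind(intercept = 1, grp = c(0, 0, 1, 1))
  fit <- fit_weighted_lm(make_we(E), design)
  expect_equal(unname(fit$coefficients["g1", "grp"]), mean(c(6, 10)) - mean(c(1, 3)))
  expect_equal(unname(fit$coefficients["g2", "grp"]), 2)
  w2 <- matrix(2, 2, 4)
  fit2 <- fit_weighted_lm(make_we(E, w2), design)
  expect_equal(fit2$coefficients, fit$coefficients)

  E1 <- E[, 1:2]
  fit0 <- fit_weighted_lm(make_we(E1), cbind(1, c(0, 1)))
  expect_true(all(is.na(fit0$sigma)))
  expect_equal(fit0$df_residual, c(0, 0))
})

test_that("rank-deficient designs are rejected naming the aliased column", {
  E <- matrix(rnorm(8), 2, 4)
  design <- cbind(a = 1, b = c(0, 0, 1, 1), c = c(0, 0, 1, 1))
  expect_error(fit_weighted_lm(make_we(E), design), "c")
})

test_that("moderation obeys its limit cases and the posterior formula", {
  set.seed(2)
  n <- 200
  E <- matrix(rnorm(n * 6), n, 6, dimnames = list(sprintf("g%03d", 1:n), NULL))
  design <- cbind(1, c(0, 0, 0, 1, 1, 1))
  fit <- fit_weighted_lm(make_we(E), design)
  mod <- moderate(fit)
  # posterior variances lie between prior and sample variances
  lo <- pmin(mod$var_prior, fit$sigma^2)
  hi <- pmax(mod$var_prior, fit$sigma^2)
  expect_true(all(mod$var_post >= lo - 1e-12 & mod$var_post <= hi + 1e-12))
  expect_true(all(mod$p_value >= 0 & mod$p_value <= 1))
  # prior df -> 0 recovers the ordinary t exactly
  mod0 <- moderate(fit, df_prior = 0)
  t_ord <- fit$coefficients[, 2] / (fit$stdev_unscaled[, 2] * fit$sigma)
  expect_equal(unname(mod0$t[, 2]), unname(t_ord), tolerance = 1e-12)
  # identical residual variances give a constant posterior
  fit_c <- fit
  fit_c$sigma <- rep(1.3, n)
  mod_c <- moderate(fit_c)
  expect_true(is.infinite(mod_c$df_prior))
  expect_equal(unname(mod_c$var_post), rep(1.3^2, n), tolerance = 1e-9)
})

test_that("prior df is recovered within 25% on simulated chi-square variances", {
  set.seed(5)
  n <- 5000
  d0 <- 4
  s02 <- 0.05
  d <- 10
  sigma2 <- d0 * s02 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  fit <- structure(list(coefficients = matrix(1, n, 1),
                        stdev_unscaled = matrix(1, n, 1),
                        sigma = sqrt(s2), df_residual = rep(d, n),
                        design = matrix(1, 1, 1),
                        feature_ids = as.character(seq_len(n))),
                   class = "linear_fit")
  mod <- moderate(fit)
  expect_lt(abs(mod$df_prior - d0) / d0, 0.25)
  expect_lt(abs(mod$var_prior - s02) / s02, 0.25)
})

test_that("BH adjustment matches hand cases and the brute-force step-up", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_warning(bh_adjust(c(0.1, NaN)), "NaN")
  set.seed(3)
  for (i in 1:30) {
    p <- runif(sample(2:8, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("Simes combination matches hand values and bounds", {
  expect_equal(simes_combine(c(0.01, 0.04)), 0.02)
  expect_equal(simes_combine(0.3), 0.3)
  expect_equal(simes_combine(c(0.001, 0.5, 0.9)), 0.003)
  expect_error(simes_combine(numeric(0)), "at least one")
  set.seed(4)
  for (i in 1:30) {
    p <- runif(sample(1:6, 1))
    expect_equal(simes_combine(p), brute_simes(p))
    expect_lte(simes_combine(p), min(1, min(p) * length(p)))
  }
})

test_that("null moderated-t p-values are approximately uniform", {
  cfg <- null_config(n_genes = 2000, seed = 17)
  sim <- simulate_counts(cfg)
  sel <- sim$meta$day == 5
  cm <- count_matrix(sim$gene$counts[, sel],
                     library_sizes = sim$gene$library_sizes[sel])
  design <- cbind(1, as.numeric(sim$meta$group[sel] == "disease"))
  we <- logcpm_transform(cm, design = design)
  mod <- moderate(fit_weighted_lm(we, design))
  p <- mod$p_value[, 2]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
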