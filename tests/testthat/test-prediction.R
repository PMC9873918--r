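test_that("signature PCs capture a single planted direction with fixed sign", {
  set.seed(21)
  n_s <- 30
  dir_score <- rnorm(n_s)
  E <- outer(runif(20, 0.5, 2), dir_score) + rnorm(20 * n_s, sd = 0.01)
  dimnames(E) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n_s))
  we <- make_we(E)
  pcs <- signature_pcs(we, rownames(E), n = 3)
  expect_gt(pcs$var_share[1], 0.98)
  expect_gt(abs(cor(pcs$scores[, 1], dir_score)), 0.99)
  expect_gt(sum(pcs$loadings[, 1]), 0)
  # projecting the training data reproduces the fit scores
  expect_equal(project_pcs(we, pcs), pcs$scores, tolerance = 1e-10)
})

test_that("signature PCs warn and shrink when the signature is too small", {
  E <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:20)))
  expect_warning(pcs <- signature_pcs(make_we(E), c("g1", "g2"), n = 3),
                 "reducing")
  expect_equal(ncol(pcs$scores), 2)
  expect_error(signature_pcs(make_we(E), "absent"), "intersect")
})

test_that("median scores behave like per-sample medians", {
  E <- matrix(c(1, 2, 9, 5, 5, 5), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  we <- make_we(E)
  expect_equal(unname(median_score(we, c("g1", "g2", "g3"))), c(2, 5))
  expect_equal(unname(median_score(we, "g3")), c(9, 5))
  expect_equal(median_score(make_we(E + 3), rownames(E)),
               median_score(we, rownames(E)) + 3)
})

test_that("feature assembly composes its parts and errors on missing samples", {
  cfg <- planted_config(n_genes = 200, seed = 29, n = 3)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth$labels
  sig <- truth$gene_id[truth$label != "null"][1:30]
  exon_sig <- sim$annotation$exon_id[sim$annotation$gene_id %in%
                                       truth$gene_id[truth$label == "splice"]]
  we_gene <- logcpm_transform(sim$gene)
  we_use <- relative_exon_usage(logcpm_transform(sim$exon), sim$annotation)
  vp <- vdj_profile(sim$vdj, sim$gene$library_sizes)
  feats <- build_features(we_gene, we_use, sig, exon_sig, vp)
  expect_identical(colnames(feats),
                   c("PC1_gene", "PC2_gene", "PC3_gene",
                     "PC1_exon", "PC2_exon", "PC3_exon",
                     "median_expression", "median_splice",
                     "vdj_read_cpm", "vdj_clonality"))
  expect_false(anyNA(feats))
  fits <- attr(feats, "fits")
  expect_equal(unname(as.matrix(feats[, 1:3])), unname(fits$gene$scores))
  expect_equal(feats$median_expression, unname(median_score(we_gene, sig)))
  vp_short <- vp[-1, ]
  expect_error(build_features(we_gene, we_use, sig, exon_sig, vp_short),
               vp$sample_id[1])
  expect_warning(
    f0 <- build_features(we_gene, we_use, sig, "absent_exon", vp),
    "zero-filled"
  )
  expect_true(all(f0$PC1_exon == 0))
})

test_that("random forest training is seed-deterministic and finds a linear driver", {
  set.seed(33)
  n <- 60
  feats <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  colnames(feats) <- c("PC1_gene", "PC2_gene", "PC3_gene", "PC1_exon",
                       "PC2_exon", "PC3_exon", "median_expression",
                       "median_splice", "vdj_read_cpm", "vdj_clonality")
  rownames(feats) <- sprintf("s%02d", 1:n)
  y <- setNames(3 * feats$PC1_gene, rownames(feats))
  rf1 <- train_rf(feats, y, seed = 5)
  rf2 <- train_rf(feats, y, seed = 5)
  expect_identical(predict(rf1, feats), predict(rf2, feats))
  expect_true("PC1_gene" %in% rf1$retained)
  expect_gt(cor(predict(rf1, feats), y, method = "spearman"), 0.95)
  expect_error(train_rf(feats, setNames(rep(1, n), rownames(feats))),
               "constant")
})

test_that("pure-noise outcomes give near-zero validation correlation", {
  set.seed(34)
  n <- 40
  mk <- function(seed) {
    set.seed(seed)
    f <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    colnames(f) <- paste0("f", 1:10)
    rownames(f) <- sprintf("%d_s%02d", seed, 1:n)
    f
  }
  rhos <- vapply(1:5, function(s) {
    ftr <- mk(s)
    fva <- mk(100 + s)
    ytr <- setNames(rnorm(n), rownames(ftr))
    yva <- setNames(rnorm(n), rownames(fva))
    rf <- train_rf(ftr, ytr, seed = s)
    validate(rf, fva, yva)$rho
  }, numeric(1))
  expect_gt(mean(abs(rhos) < 0.3), 0.5)
})

test_that("validation reports agreement statistics and refuses leakage", {
  set.seed(35)
  n <- 30
  feats <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  colnames(feats) <- paste0("f", 1:4)
  rownames(feats) <- sprintf("s%02d", 1:n)
  y <- setNames(2 * feats$f1 + rnorm(n, sd = 0.1), rownames(feats))
  rf <- train_rf(feats, y, cv_folds = 5, seed = 2)
  expect_error(validate(rf, feats, y), "overlap")
  fva <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  colnames(fva) <- paste0("f", 1:4)
  rownames(fva) <- sprintf("v%02d", 1:n)
  yva <- setNames(2 * fva$f1 + rnorm(n, sd = 0.1), rownames(fva))
  rep1 <- validate(rf, fva, yva)
  # row order of the validation set does not change the report
  perm <- sample(n)
  rep2 <- validate(rf, fva[perm, ], yva[perm])
  expect_equal(rep1$rho, rep2$rho)
  expect_equal(rep1$kappa, rep2$kappa)
  expect_gt(rep1$rho, 0.8)
})

test_that("Cohen's kappa matches the hand formula and exhaustive small tables", {
  # confusion [[2,1],[1,2]]: po = 2/3, pe = 1/2, kappa = 1/3
  obs <- c(0, 0, 0, 1, 1, 1)
  pred <- c(0, 0, 1, 0, 1, 1)
  expect_equal(cohen_kappa(obs, pred), 1 / 3)
  expect_equal(cohen_kappa(1:3, 1:3), 1)
})

test_that("Spearman helper matches exact enumeration on small vectors", {
  set.seed(36)
  for (n in 4:6) {
    x <- sample(100, n)
    y <- sample(100, n)
    ours <- spearman_cor(x, y)
    brute <- brute_spearman(x, y)
    expect_equal(ours$rho, brute$rho, tolerance = 1e-12)
    expect_equal(ours$p, brute$p, tolerance = 1e-8)
  }
})
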