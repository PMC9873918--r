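fake_modfit <- function(beta, se_unscaled = rep(1, length(beta)),
                        var_post = rep(1, length(beta)), df_total = 20,
                        ids = sprintf("e%02d", seq_along(beta))) {
  structure(list(
    coefficients = matrix(beta, ncol = 1, dimnames = list(ids, "disease")),
    stdev_unscaled = matrix(se_unscaled, ncol = 1,
                            dimnames = list(ids, "disease")),
    var_post = var_post, df_total = rep(df_total, length(beta)),
    sigma = sqrt(var_post), df_residual = rep(df_total, length(beta)),
    feature_ids = ids
  ), class = c("moderated_fit", "linear_fit"))
}

test_that("shared exon coefficients give zero deviations and p near 1", {
  ids <- sprintf("e%02d", 1:4)
  ann <- data.frame(exon_id = ids, gene_id = "g1", bin_index = 1:4)
  fit <- fake_modfit(rep(1.7, 4), ids = ids)
  res <- diff_splice(fit, ann, "disease")
  expect_true(all(abs(res$exon$logFC_dev) < 1e-12))
  expect_true(all(res$gene$p_simes > 0.999))
  expect_true(all(res$gene$p_f > 0.999))
})

test_that("equal-precision opposite exons split symmetrically around a zero average", {
  ids <- c("e01", "e02")
  ann <- data.frame(exon_id = ids, gene_id = "g1", bin_index = 1:2)
  res <- diff_splice(fake_modfit(c(1, -1), ids = ids), ann, "disease")
  expect_equal(sort(res$exon$logFC_dev), c(-1, 1))
})

test_that("weighted deviations sum to zero within each gene", {
  set.seed(11)
  ids <- sprintf("e%02d", 1:12)
  ann <- data.frame(exon_id = ids,
                    gene_id = rep(c("g1", "g2", "g3"), each = 4),
                    bin_index = rep(1:4, 3))
  fit <- fake_modfit(rnorm(12), se_unscaled = runif(12, 0.5, 2),
                     var_post = runif(12, 0.5, 2), ids = ids)
  res <- diff_splice(fit, ann, "disease")
  se2 <- (fit$stdev_unscaled[, 1]^2) * fit$var_post
  for (g in unique(ann$gene_id)) {
    sel <- res$exon$gene_id == g
    w <- 1 / se2[match(res$exon$exon_id[sel], ids)]
    expect_lt(abs(sum(w * res$exon$logFC_dev[sel])), 1e-8)
  }
})

test_that("single-exon genes are excluded and logged", {
  ids <- c("e01", "e02", "e03")
  ann <- data.frame(exon_id = ids, gene_id = c("g1", "g1", "g2"),
                    bin_index = c(1, 2, 1))
  res <- diff_splice(fake_modfit(c(1, -1, 5), ids = ids), ann, "disease")
  expect_false("g2" %in% res$gene$gene_id)
  expect_equal(attr(res, "excluded"), "g2")
})

test_that("planted switches are flagged while uniform shifts are not", {
  cfg <- planted_config(n_genes = 500, seed = 41)
  sim <- simulate_counts(cfg)
  sp <- splice_at_day(sim$exon, sim$annotation, sim$meta, day = 5)
  truth <- sim$truth$labels
  flagged <- sp$gene$gene_id[sp$gene$flagged]
  splice_genes <- truth$gene_id[truth$label == "splice"]
  uniform <- truth$gene_id[truth$label %in% c("fixed-day-5", "fixed-persistent")]
  expect_gt(mean(splice_genes %in% flagged), 0.8)
  expect_lt(mean(uniform %in% flagged), 0.1)
  # orthogonality the other way: switch genes are not called DE
  de <- timepoint_de(sim$gene, sim$meta, day = 5, engine = "nbglm")
  sig <- extract_signature(de, direction = "both")
  expect_lt(mean(splice_genes %in% sig$genes), 0.1)
  rep <- orthogonality_report(
    list(`5` = sig), list(`5` = flagged),
    de_tables = list(`5` = de), ds_tables = list(`5` = sp$gene)
  )
  expect_lt(rep$frac_ds_also_de, 0.1)
  expect_lt(rep$frac_de_also_ds, 0.1)
})

test_that("orthogonality report handles identical and disjoint sets", {
  r1 <- orthogonality_report(list(d = c("a", "b")), list(d = c("a", "b")))
  expect_equal(r1$jaccard, 1)
  r2 <- orthogonality_report(list(d = c("a", "b")), list(d = c("c")))
  expect_equal(r2$jaccard, 0)
  expect_true(is.na(r2$cor_lfc_ds))
})

test_that("relative exon usage removes the gene-level component", {
  cfg <- planted_config(n_genes = 60, seed = 3, n = 3)
  sim <- simulate_counts(cfg)
  we <- suppressWarnings(logcpm_transform(sim$exon))
  ru <- relative_exon_usage(we, sim$annotation)
  gene_of <- sim$annotation$gene_id[match(rownames(ru$E), sim$annotation$exon_id)]
  sums <- rowsum(ru$E, gene_of)
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("isoform scores follow the designated exons and are CPM-invariant", {
  counts <- matrix(c(10L, 40L, 20L, 80L), 2, 2,
                   dimnames = list(c("g1_e01", "g1_e02"), c("s1", "s2")))
  cm <- count_matrix(counts, library_sizes = c(s1 = 1000, s2 = 2000))
  map <- data.frame(gene_id = "g1", isoform = c("short", "long"),
                    exon_id = c("g1_e01", "g1_e02"))
  sc <- isoform_specific_expression(cm, map)
  expect_equal(unname(sc["g1:short", "s1"]),
               log2((10 + 0.5) / (1000 + 1) * 1e6))
  cm2 <- count_matrix(counts * 2L, library_sizes = c(s1 = 2000, s2 = 4000))
  sc2 <- isoform_specific_expression(cm2, map)
  expect_equal(sc, sc2, tolerance = 0.1)
  bad_map <- data.frame(gene_id = "g1", isoform = c("short", "long"),
                        exon_id = c("g1_e01", "g1_e01"))
  expect_error(isoform_specific_expression(cm, bad_map), "overlap")
})

test_that("planted switches move isoform scores in opposite directions", {
  cfg <- planted_config(n_genes = 300, seed = 43)
  sim <- simulate_counts(cfg)
  map <- sim$truth$splice_exons
  colnames(map)[colnames(map) == "isoform"] <- "isoform"
  sc <- isoform_specific_expression(sim$exon, map)
  dis <- sim$meta$group == "disease"
  # switch exons are up-weighted in disease, the complementary set down
  dsw <- rowMeans(sc[grepl(":switch$", rownames(sc)), dis]) -
    rowMeans(sc[grepl(":switch$", rownames(sc)), !dis])
  doth <- rowMeans(sc[grepl(":other$", rownames(sc)), dis]) -
    rowMeans(sc[grepl(":other$", rownames(sc)), !dis])
  # the within-gene contrast is the isoform-switch signature
  expect_gt(mean(dsw > doth), 0.9)
  expect_gt(mean(dsw), 0)
  expect_lt(mean(doth), 0)
})

test_that("co-correlated gene lists respect the correlation threshold", {
  set.seed(12)
  E <- matrix(rnorm(200), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:20)))
  E["g01", ] <- seq_len(20)
  E["g02", ] <- -seq_len(20)
  E["g03", ] <- 0                      # zero variance, skipped
  iso <- matrix(seq_len(20), 1, dimnames = list("gX:short", colnames(E)))
  out <- correlated_gene_lists(iso, make_we(E), r_min = 0.8)
  expect_true("g01" %in% out[["gX:short"]])
  expect_false("g02" %in% out[["gX:short"]])
  expect_false("g03" %in% out[["gX:short"]])
  out_hi <- correlated_gene_lists(iso, make_we(E), r_min = 1 + 1e-9)
  expect_length(out_hi[["gX:short"]], 0)
})

test_that("hypergeometric enrichment matches enumeration and degenerate cases", {
  # universe 10, query 5, set 5, overlap 5 -> 1 / C(10,5)
  universe <- letters[1:10]
  res <- geneset_enrichment(letters[1:5], list(S = letters[1:5]), universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  res2 <- geneset_enrichment(universe, list(S = universe), universe)
  expect_equal(res2$p, 1)
  expect_equal(res2$overlap, 10)
  res3 <- geneset_enrichment(letters[1:2], list(S = letters[9:10]), universe)
  expect_gt(res3$p, 0.5)
  expect_error(geneset_enrichment(c("zz"), list(S = letters[1:3]), universe),
               "outside")
})
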