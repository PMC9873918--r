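test_that("day-matched copies give a zero LRT statistic and df = days - 1", {
  set.seed(2)
  n_per <- 3
  days <- c(5, 12, 17, 36)
  ctl <- matrix(rnbinom(40 * n_per * length(days), mu = 150, size = 8),
                40, n_per * length(days))
  counts <- cbind(ctl, ctl)
  dimnames(counts) <- list(
    sprintf("g%03d", 1:40),
    c(sprintf("c%02d", seq_len(ncol(ctl))), sprintf("d%02d", seq_len(ncol(ctl))))
  )
  meta <- data.frame(
    sample_id = colnames(counts),
    group = rep(c("control", "disease"), each = ncol(ctl)),
    day = rep(rep(days, each = n_per), 2),
    cohort = "X", tissue = "colon", stringsAsFactors = FALSE
  )
  res <- interaction_lrt(count_matrix(counts), meta)
  expect_true(all(res$stat < 1e-6))
  expect_true(all(res$p > 0.999))
  expect_true(all(res$df == 3))
})

test_that("the LRT is invariant to relabeling the reference day", {
  cfg <- planted_config(n_genes = 80, seed = 13, n = 3)
  sim <- simulate_counts(cfg)
  res <- interaction_lrt(sim$gene, sim$meta)
  meta2 <- sim$meta
  # bijective relabeling of the day values permutes factor levels only
  meta2$day <- c(`5` = 36, `12` = 17, `17` = 12, `36` = 5)[as.character(meta2$day)]
  res2 <- interaction_lrt(sim$gene, meta2)
  expect_equal(res$stat, res2$stat, tolerance = 1e-6)
})

test_that("median disease trajectories are medians of disease samples only", {
  E <- rbind(g1 = c(1, 2, 100, 3, 4, 5))
  colnames(E) <- paste0("s", 1:6)
  we <- make_we(E)
  meta <- data.frame(
    sample_id = colnames(E),
    group = c("control", "disease", "disease", "disease", "control", "disease"),
    day = c(5, 5, 5, 5, 12, 12), cohort = "X", tissue = "c",
    stringsAsFactors = FALSE
  )
  tr <- median_disease_trajectories(we, meta, "g1")
  expect_equal(unname(tr["g1", "5"]), 3)   # median of (2, 100, 3)
  expect_equal(unname(tr["g1", "12"]), 5)
  meta_bad <- meta
  meta_bad$group[meta_bad$day == 12] <- "control"
  expect_error(median_disease_trajectories(we, meta_bad, "g1"), "day 12")
  expect_error(median_disease_trajectories(we, meta, "missing"), "absent")
})

test_that("trajectory standardization matches hand computation and symmetries", {
  z <- standardize_trajectories(rbind(a = c(1, 2, 3, 4)))
  expect_equal(unname(z["a", ]), c(-1.1619, -0.3873, 0.3873, 1.1619),
               tolerance = 1e-4)
  expect_equal(standardize_trajectories(z), z, tolerance = 1e-12)
  zz <- standardize_trajectories(rbind(a = c(1, 2, 3, 4), b = -c(1, 2, 3, 4)))
  expect_equal(unname(zz["a", ]), unname(-zz["b", ]))
  expect_warning(standardize_trajectories(rbind(a = 1:4, b = rep(2, 4))),
                 "constant")
  expect_error(standardize_trajectories(rbind(a = rep(1, 4))), "constant")
})

test_that("fuzzy c-means memberships are a proper partition and recover planted groups", {
  set.seed(6)
  g1 <- matrix(rep(c(0, 0, 1, 1), each = 30), 30, 4) + rnorm(120, sd = 0.05)
  g2 <- matrix(rep(c(1, 1, 0, 0), each = 30), 30, 4) + rnorm(120, sd = 0.05)
  x <- standardize_trajectories(rbind(g1, g2))
  fc <- fuzzy_cmeans(x, k = 2, seed = 4)
  expect_equal(unname(rowSums(fc$membership)), rep(1, nrow(x)), tolerance = 1e-8)
  expect_true(all(fc$membership >= 0 & fc$membership <= 1))
  tab <- table(fc$hard, rep(1:2, each = 30))
  expect_equal(ari_from_table(tab), 1)
})

test_that("fuzzy c-means approaches hard assignments as m -> 1+ and is deterministic", {
  shapes <- canonical_trajectory_shapes()
  set.seed(8)
  x <- shapes[rep(1:5, each = 20), ] + rnorm(400, sd = 0.05)
  rownames(x) <- sprintf("g%03d", 1:100)
  xz <- standardize_trajectories(x)
  fc_soft <- fuzzy_cmeans(xz, k = 5, m = 1.25, seed = 2)
  fc_hardish <- fuzzy_cmeans(xz, k = 5, m = 1.01, seed = 2)
  expect_gt(mean(apply(fc_hardish$membership, 1, max)), 0.99)
  fc_rep <- fuzzy_cmeans(xz, k = 5, m = 1.25, seed = 2)
  expect_identical(fc_soft$membership, fc_rep$membership)
  # each centre matches a distinct canonical shape
  expect_setequal(fc_soft$letters, rownames(shapes))
  cors <- vapply(1:5, function(i) {
    cor(fc_soft$centers[i, ], shapes[fc_soft$letters[i], ])
  }, numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("a point coinciding with a centre takes membership one", {
  x <- rbind(a = c(0, 0, 1, 1), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  fc <- fuzzy_cmeans(standardize_trajectories(x), k = 2, seed = 1)
  expect_equal(max(fc$membership["a", ]), 1, tolerance = 1e-6)
})

test_that("the fuzzifier heuristic exceeds one and agrees with independent soft clustering", {
  expect_gt(estimate_fuzzifier(500, 4), 1)
  skip_if_not_installed("e1071")
  shapes <- canonical_trajectory_shapes()
  set.seed(9)
  x <- shapes[rep(1:5, each = 30), ] + rnorm(600, sd = 0.1)
  rownames(x) <- sprintf("g%03d", 1:150)
  xz <- standardize_trajectories(x)
  fc <- fuzzy_cmeans(xz, k = 5, m = 1.5, seed = 3)
  cm <- e1071::cmeans(xz, centers = fc$centers, m = 1.5, iter.max = 200)
  tab <- table(fc$hard, cm$cluster)
  expect_equal(ari_from_table(tab), 1)
})

test_that("splicing trajectory test ignores shared interaction effects and finds switches", {
  # planted time-varying isoform switch
  cfg <- planted_config(n_genes = 300, seed = 37,
                        splice_profile = c(0, 2 / 3, 4 / 3, 2))
  sim <- simulate_counts(cfg)
  st <- splicing_trajectory_lrt(sim$exon, sim$annotation, sim$meta)
  truth <- sim$truth$labels
  splice_genes <- truth$gene_id[truth$label == "splice"]
  expect_gt(mean(splice_genes %in% st$gene_id[st$q < 0.05]), 0.7)
  # genes whose exons share the gene-level interaction (cluster genes) are not called
  cl_genes <- truth$gene_id[grepl("^cluster-", truth$label)]
  expect_lt(mean(cl_genes %in% st$gene_id[st$q < 0.05]), 0.1)
})
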