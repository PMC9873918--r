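# Brute-force oracles, independent of the package implementations, plus a
# few shared fixtures.

# BH by the step-up definition: q_i = min_{j >= rank(i)} p_(j) * m / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

brute_simes <- function(p) {
  m <- length(p)
  min(1, min(sort(p) * m / seq_len(m)))
}

# Exact Spearman p by full permutation enumeration (small n, no ties)
brute_spearman <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- perm_all(n)
  rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
  list(rho = rho_obs,
       p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Kappa from a 2x2 confusion matrix by the hand formula
brute_kappa_2x2 <- function(tab) {
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

# Upper-tail hypergeometric by exhaustive enumeration over subsets of the
# universe (universe <= 12)
brute_hyper <- function(overlap, k_a, k_b, n_universe) {
  b_set <- seq_len(k_b)
  draws <- utils::combn(n_universe, k_a)
  hits <- apply(draws, 2, function(d) sum(d %in% b_set))
  mean(hits >= overlap)
}

brute_clonality <- function(ab) {
  ab <- ab[ab > 0]
  if (length(ab) == 1) return(1)
  f <- ab / sum(ab)
  1 - (-sum(f * log(f))) / log(length(ab))
}

# Adjusted Rand index from a contingency table
ari_from_table <- function(tab) {
  n <- sum(tab)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  e <- b * cc / choose(n, 2)
  (a - e) / ((b + cc) / 2 - e)
}

# A minimal weighted_expression for direct tests of the LM machinery
make_we <- function(E, weights = NULL) {
  if (is.null(weights)) weights <- matrix(1, nrow(E), ncol(E),
                                          dimnames = dimnames(E))
  structure(list(E = E, weights = weights, design = NULL, lib_sizes = NULL),
            class = "weighted_expression")
}

# A null configuration (no planted effects) at a chosen size
null_config <- function(n_genes = 2000, seed = 1, n = 10) {
  sim_config(
    n_genes = n_genes, n_per_group_per_day = n,
    fixed_effect = list(n_per_day = 0, effect = 0, n_persistent = 0),
    trajectory = list(n_per_cluster = 0, amplitude = 0),
    splice = list(n_genes = 0, effect = 0, time_profile = c(1, 1, 1, 1)),
    seed = seed
  )
}

# The standard planted configuration used by recovery tests; planted set
# sizes scale with the gene count
planted_config <- function(n_genes = 1000, seed = 1, n = 10,
                           splice_profile = c(1, 1, 1, 1)) {
  per_day <- max(4, n_genes %/% 40)
  per_cluster <- max(4, n_genes %/% 25)
  sim_config(
    n_genes = n_genes, n_per_group_per_day = n,
    fixed_effect = list(n_per_day = per_day, effect = 2,
                        n_persistent = round(3.27 * per_day)),
    trajectory = list(n_per_cluster = per_cluster, amplitude = 2),
    splice = list(n_genes = per_day, effect = 1.5,
                  time_profile = splice_profile),
    seed = seed
  )
}

# Build the ten-term feature table of a simulated cohort from a gene
# signature and a DS-gene exon signature
cohort_features <- function(sim, gene_sig, exon_sig, loadings = NULL) {
  we_gene <- logcpm_transform(sim$gene)
  we_use <- relative_exon_usage(logcpm_transform(sim$exon), sim$annotation)
  vp <- vdj_profile(sim$vdj, sim$gene$library_sizes)
  build_features(we_gene, we_use, gene_sig, exon_sig, vp, loadings = loadings)
}
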