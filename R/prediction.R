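# Signature-derived per-sample features and the cross-cohort random-forest
# histology model. The feature vector mirrors the histology formula:
# HistoScore ~ PC1..3_gene + PC1..3_exon + median_expression + median_splice
#              + vdj_read_cpm + vdj_clonality

#' Signature-restricted principal components
#'
#' PCA on the gene-centred, signature-restricted training expression matrix
#' (samples as observations). Loadings are retained so validation cohorts
#' can be projected without refitting. Component signs are fixed so each
#' loading vector has a positive sum (tie: first nonzero loading positive).
#'
#' @param we a `weighted_expression` (training cohort).
#' @param signature a `signature` or gene vector.
#' @param n number of components (reduced with a warning when the signature
#'   intersection is smaller).
#' @return object of class `signature_pcs`: `scores` (samples x n),
#'   `loadings` (genes x n), `center`, `var_share`, `genes`.
#' @export
signature_pcs <- function(we, signature, n = 3) {
  genes <- if (inherits(signature, "signature")) signature$genes else signature
  genes <- intersect(genes, rownames(we$E))
  if (length(genes) == 0L) stop("signature does not intersect the features")
  if (length(genes) < n) {
    warning(sprintf("signature has %d usable gene(s); reducing n to %d",
                    length(genes), length(genes)))
    n <- length(genes)
  }
  X <- t(we$E[genes, , drop = FALSE])      # samples x genes
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = n, nv = n)
  n <- min(n, length(sv$d))
  loadings <- sv$v[, seq_len(n), drop = FALSE]
  # deterministic sign: positive loading sum
  for (j in seq_len(n)) {
    s <- sum(loadings[, j])
    if (abs(s) < 1e-12) {
      nz <- which(abs(loadings[, j]) > 1e-12)[1]
      s <- loadings[nz, j]
    }
    if (s < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- genes
  colnames(loadings) <- paste0("PC", seq_len(n))
  scores <- Xc %*% loadings
  structure(list(scores = scores, loadings = loadings, center = ctr,
                 var_share = sv$d[seq_len(n)]^2 / sum(sv$d^2), genes = genes),
            class = "signature_pcs")
}

#' Project samples onto trained signature PCs
#'
#' @param we a `weighted_expression` (validation cohort).
#' @param pcs a `signature_pcs` fit from the training cohort.
#' @return samples x components score matrix.
#' @export
project_pcs <- function(we, pcs) {
  missing <- setdiff(pcs$genes, rownames(we$E))
  if (length(missing)) {
    stop("validation matrix lacks signature gene(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  X <- t(we$E[pcs$genes, , drop = FALSE])
  sweep(X, 2, pcs$center) %*% pcs$loadings
}

#' Median expression score over a signature
#'
#' @param we a `weighted_expression`.
#' @param signature a `signature` or gene vector.
#' @return named per-sample medians of log2-CPM over signature genes.
#' @export
median_score <- function(we, signature) {
  genes <- if (inherits(signature, "signature")) signature$genes else signature
  genes <- intersect(genes, rownames(we$E))
  if (length(genes) == 0L) stop("signature does not intersect the features")
  apply(we$E[genes, , drop = FALSE], 2, stats::median)
}

#' Assemble the per-sample feature table
#'
#' Builds the ten model terms from gene- and exon-level expression, the
#' signatures, and the VDJ profile. On the training cohort (`loadings =
#' NULL`) PCA fits are computed and attached; validation cohorts must pass
#' the training fits and are projected, never refit. An empty exon signature
#' zero-fills the exon columns and records a flag.
#'
#' @param we_gene,we_exon `weighted_expression` objects over the same
#'   samples.
#' @param gene_signature,exon_signature signatures (gene ids / exon feature
#'   ids).
#' @param vdj [vdj_profile()] table covering every sample.
#' @param loadings `NULL`, or the `"fits"` attribute of the training feature
#'   table.
#' @return data.frame (rownames = sample ids) with columns `PC1_gene` ..
#'   `PC3_gene`, `PC1_exon` .. `PC3_exon`, `median_expression`,
#'   `median_splice`, `vdj_read_cpm`, `vdj_clonality`. Attributes: `"fits"`
#'   (PCA fits, training only), `"exon_zero_filled"`.
#' @export
build_features <- function(we_gene, we_exon, gene_signature, exon_signature,
                           vdj, loadings = NULL) {
  samples <- colnames(we_gene$E)
  if (!identical(sort(samples), sort(colnames(we_exon$E)))) {
    miss <- setdiff(samples, colnames(we_exon$E))
    stop("sample(s) missing from the exon matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  miss_vdj <- setdiff(samples, vdj$sample_id)
  if (length(miss_vdj)) {
    stop("sample(s) missing from the VDJ profile: ",
         paste(utils::head(miss_vdj, 3), collapse = ", "))
  }
  exon_genes <- if (inherits(exon_signature, "signature"))
    exon_signature$genes else exon_signature
  exon_zero <- length(intersect(exon_genes, rownames(we_exon$E))) == 0L

  if (is.null(loadings)) {
    gene_fit <- signature_pcs(we_gene, gene_signature, n = 3)
    exon_fit <- if (!exon_zero) signature_pcs(we_exon, exon_signature, n = 3)
    fits <- list(gene = gene_fit, exon = exon_fit)
    g_scores <- gene_fit$scores
    e_scores <- if (!exon_zero) exon_fit$scores
  } else {
    fits <- loadings
    g_scores <- project_pcs(we_gene, fits$gene)
    e_scores <- if (!is.null(fits$exon)) project_pcs(we_exon, fits$exon)
    exon_zero <- is.null(fits$exon)
  }
  pad3 <- function(m, what) {
    out <- matrix(0, length(samples), 3,
                  dimnames = list(samples, paste0("PC", 1:3, "_", what)))
    if (!is.null(m)) out[rownames(m), seq_len(ncol(m))] <- m
    out
  }
  if (exon_zero) {
    warning("exon signature empty after intersection; exon PC and median ",
            "columns zero-filled")
  }
  med_splice <- if (exon_zero) stats::setNames(rep(0, length(samples)), samples)
    else median_score(we_exon, exon_signature)
  feats <- data.frame(
    pad3(g_scores, "gene"),
    pad3(e_scores, "exon"),
    median_expression = median_score(we_gene, gene_signature)[samples],
    median_splice = med_splice[samples],
    vdj_read_cpm = vdj$vdj_read_cpm[match(samples, vdj$sample_id)],
    vdj_clonality = vdj$clonality[match(samples, vdj$sample_id)],
    row.names = samples, check.names = FALSE
  )
  feats$vdj_clonality[is.na(feats$vdj_clonality)] <- 0
  if (anyNA(feats)) stop("missing values in assembled features")
  attr(feats, "fits") <- fits
  attr(feats, "exon_zero_filled") <- exon_zero
  feats
}

#' Train the random-forest histology model
#'
#' Regression forest (bootstrap aggregation, random feature subsampling)
#' with cross-validated feature retention: features whose permutation
#' importance is <= 0 in a majority of folds are dropped, then the forest is
#' refit on the retained set. The candidate set is always the ten formula
#' terms, regardless of signature size. Deterministic given the seed.
#'
#' @param features [build_features()] table (training cohort).
#' @param histo named (or feature-row-ordered) non-negative histology
#'   scores.
#' @param n_trees trees per forest.
#' @param cv_folds folds for the retention step (>= 2; needs at least
#'   `cv_folds` samples).
#' @param seed integer seed.
#' @return object of class `rf_histo`: `model` (ranger), `retained`,
#'   `importance` (permutation, full model), `train_samples`.
#' @export
train_rf <- function(features, histo, n_trees = 500, cv_folds = 10, seed = 1) {
  y <- if (!is.null(names(histo))) histo[rownames(features)] else histo
  if (anyNA(y)) stop("histology score missing for some training samples")
  if (stats::sd(y) == 0) stop("constant outcome")
  n <- nrow(features)
  if (n < cv_folds) stop("need at least cv_folds samples")
  dat <- data.frame(.y = as.numeric(y), features, check.names = FALSE)

  set.seed(seed)
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  votes <- matrix(0, ncol(features), cv_folds,
                  dimnames = list(colnames(features), NULL))
  for (f in seq_len(cv_folds)) {
    tr <- dat[fold != f, , drop = FALSE]
    rf <- ranger::ranger(
      dependent.variable.name = ".y", data = tr, num.trees = n_trees,
      importance = "permutation", seed = seed + f,
      num.threads = 1
    )
    votes[names(rf$variable.importance), f] <-
      as.numeric(rf$variable.importance > 0)
  }
  retained <- rownames(votes)[rowSums(votes) > cv_folds / 2]
  full_rf <- ranger::ranger(
    dependent.variable.name = ".y", data = dat, num.trees = n_trees,
    importance = "permutation", seed = seed, num.threads = 1
  )
  if (length(retained) == 0L) {
    retained <- names(which.max(full_rf$variable.importance))
  }
  model <- ranger::ranger(
    dependent.variable.name = ".y",
    data = dat[, c(".y", retained), drop = FALSE],
    num.trees = n_trees, importance = "permutation", seed = seed,
    num.threads = 1
  )
  structure(list(model = model, retained = retained,
                 importance = model$variable.importance,
                 full_importance = full_rf$variable.importance,
                 train_samples = rownames(features), seed = seed),
            class = "rf_histo")
}

#' @export
predict.rf_histo <- function(object, newdata, ...) {
  pred <- stats::predict(object$model,
                         data = newdata[, object$retained, drop = FALSE],
                         num.threads = 1)
  stats::setNames(pred$predictions, rownames(newdata))
}

#' Validate the histology model on an independent cohort
#'
#' Predicts histology for the validation cohort and reports Spearman rho and
#' p between predicted and observed scores, Cohen's kappa for disease-status
#' classification under `status_rule`, and the top-3 retained predictors by
#' permutation importance. Validation samples must be disjoint from the
#' training cohort.
#'
#' @param model an `rf_histo`.
#' @param features_val validation [build_features()] table (projected with
#'   training loadings).
#' @param histo_val named observed scores.
#' @param status_rule function mapping a score vector to disease status
#'   (default: score > 0, matching synthetic controls scoring 0).
#' @return one-row data.frame: `rho`, `p`, `neg_log10_p`, `kappa`, `top1` ..
#'   `top3`, `n_val`.
#' @export
validate <- function(model, features_val, histo_val,
                     status_rule = function(h) h > 0) {
  if (nrow(features_val) < 3) stop("need >= 3 validation samples")
  if (length(intersect(rownames(features_val), model$train_samples))) {
    stop("validation samples overlap the training cohort")
  }
  obs <- if (!is.null(names(histo_val))) histo_val[rownames(features_val)]
    else histo_val
  pred <- predict(model, features_val)
  sc <- spearman_cor(as.numeric(pred), as.numeric(obs))
  kap <- cohen_kappa(status_rule(obs), status_rule(pred))
  imp <- sort(model$importance, decreasing = TRUE)
  top <- c(names(imp), rep(NA_character_, 3))[1:3]
  data.frame(rho = sc$rho, p = sc$p,
             neg_log10_p = -log10(pmax(sc$p, 1e-300)),
             kappa = kap, top1 = top[1], top2 = top[2], top3 = top[3],
             n_val = nrow(features_val), stringsAsFactors = FALSE)
}
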