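# Ortholog projection of mouse signatures, AIC-penalized restricted cubic
# spline regression of histology indices on signature PCs with bootstrap
# optimism correction, and hypergeometric network overlap.

#' Project a mouse signature to human orthologs
#'
#' @param signature a `signature` or mouse gene vector.
#' @param map data.frame `mouse`, `human` (see [read_ortholog_map()]).
#' @param policy `"all"` expands one-to-many pairs; `"one_to_one"` keeps
#'   only genes with a unique partner in both directions.
#' @return human `signature`; unmapped-gene count logged.
#' @export
map_orthologs <- function(signature, map, policy = c("all", "one_to_one")) {
  policy <- match.arg(policy)
  genes <- if (inherits(signature, "signature")) signature$genes else signature
  label <- if (inherits(signature, "signature")) signature$label else "signature"
  sub <- map[map$mouse %in% genes, , drop = FALSE]
  if (policy == "one_to_one") {
    m_multi <- names(which(table(map$mouse) > 1))
    h_multi <- names(which(table(map$human) > 1))
    sub <- sub[!(sub$mouse %in% m_multi) & !(sub$human %in% h_multi), ,
               drop = FALSE]
  }
  unmapped <- setdiff(genes, sub$mouse)
  ct_log(sprintf("ortholog mapping (%s): %d/%d mouse genes mapped",
                 policy, length(genes) - length(unmapped), length(genes)))
  human <- sort(unique(sub$human))
  if (length(human) == 0L) stop("no genes mapped to human orthologs")
  structure(list(label = paste0(label, "-human"), genes = human,
                 direction = NULL, n_unmapped = length(unmapped)),
            class = "signature")
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline with linear tails: `n_knots`
#' knots at default quantiles (0.10, 0.50, 0.90 for three knots) yield
#' `n_knots - 1` basis columns (the linear term plus `n_knots - 2` nonlinear
#' terms). The basis is continuous with continuous first and second
#' derivatives at the knots.
#'
#' @param x numeric vector.
#' @param n_knots number of knots (>= 3).
#' @param knots explicit knot locations (overrides `n_knots`).
#' @return matrix with columns `lin`, `nl1`, ... and a `"knots"` attribute;
#'   with too few distinct values, the linear column only, with a warning.
#' @export
rcs_basis <- function(x, n_knots = 3, knots = NULL) {
  auto <- is.null(knots)
  if (auto) {
    probs <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      seq(0.05, 0.95, length.out = n_knots)
    )
    knots <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
  }
  if (length(knots) < 3 || (auto && length(unique(x)) < length(knots))) {
    warning("insufficient distinct values for a restricted cubic spline; ",
            "returning the linear column only")
    out <- matrix(x, ncol = 1, dimnames = list(NULL, "lin"))
    attr(out, "knots") <- NULL
    return(out)
  }
  k <- length(knots)
  t1 <- knots[1]
  tk <- knots[k]
  tk1 <- knots[k - 1]
  tau <- (tk - t1)^2
  pp <- function(u) pmax(u, 0)^3
  nl <- sapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pp(x - tj) - pp(x - tk1) * (tk - tj) / (tk - tk1) +
       pp(x - tk) * (tk1 - tj) / (tk - tk1)) / tau
  })
  out <- cbind(lin = x, nl)
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

# Build the candidate design: per PC a linear column and its nonlinear
# spline columns; returns the column matrix plus term-group bookkeeping.
.spline_design <- function(pcs, n_knots, knot_list = NULL) {
  pcs <- as.matrix(pcs)
  if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  cols <- list()
  groups <- list()
  knots_out <- list()
  for (j in seq_len(ncol(pcs))) {
    nm <- colnames(pcs)[j]
    b <- suppressWarnings(
      rcs_basis(pcs[, j], n_knots = n_knots, knots = knot_list[[nm]])
    )
    knots_out[[nm]] <- attr(b, "knots")
    colnames(b) <- paste0(nm, "_", colnames(b))
    cols[[nm]] <- b
    groups[[paste0(nm, ":lin")]] <- colnames(b)[1]
    if (ncol(b) > 1) groups[[paste0(nm, ":nl")]] <- colnames(b)[-1]
  }
  list(X = do.call(cbind, cols), groups = groups, knots = knots_out)
}

.ols_rss <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  sum(fit$residuals^2)
}

#' AIC-penalized spline regression on signature PCs
#'
#' Regresses an outcome (histology index) on the first PCs of a projected
#' signature, each expanded into a restricted cubic spline basis, and prunes
#' terms by backward stepwise deletion minimizing
#' `AIC = n ln(RSS/n) + 2k`. Nonlinear spline columns of a PC are deleted
#' jointly, and a PC's linear term only after (or with) its nonlinear part,
#' preserving the spline hierarchy. Perfectly collinear columns are dropped
#' with a warning before selection.
#'
#' @param pcs samples x PCs score matrix (typically the first five PCs).
#' @param outcome numeric outcome, length = rows of `pcs`.
#' @param n_knots knots per spline (default 3).
#' @return object of class `spline_model`: `terms` (retained groups),
#'   `columns`, `coefficients`, `aic`, `r2`, `adj_r2`, `fitted`, `knots`,
#'   `n`.
#' @export
penalized_ols_aic <- function(pcs, outcome, n_knots = 3) {
  y <- as.numeric(outcome)
  des <- .spline_design(pcs, n_knots)
  X <- des$X
  if (nrow(X) <= ncol(X) + 1) stop("need n > number of candidate columns")
  # collinearity screen
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep_idx <- sort(qrX$pivot[seq_len(qrX$rank)])
    keep_idx <- setdiff(keep_idx, 1) - 1
    dropped <- setdiff(colnames(X), colnames(X)[keep_idx])
    warning("dropped collinear column(s): ", paste(dropped, collapse = ", "))
    X <- X[, keep_idx, drop = FALSE]
    des$groups <- lapply(des$groups, intersect, colnames(X))
    des$groups <- des$groups[lengths(des$groups) > 0]
  }
  n <- length(y)
  aic_of <- function(cols) {
    k <- length(cols) + 1
    rss <- if (length(cols)) .ols_rss(X[, cols, drop = FALSE], y)
      else sum((y - mean(y))^2)
    n * log(max(rss, 1e-300) / n) + 2 * k
  }
  active <- names(des$groups)
  current_cols <- unlist(des$groups[active], use.names = FALSE)
  current_aic <- aic_of(current_cols)
  repeat {
    droppable <- Filter(function(g) {
      # a linear term is droppable only when its nonlinear partner is out
      !(endsWith(g, ":lin") && paste0(sub(":lin$", "", g), ":nl") %in% active)
    }, active)
    if (length(droppable) == 0L) break
    trial <- vapply(droppable, function(g) {
      aic_of(unlist(des$groups[setdiff(active, g)], use.names = FALSE))
    }, numeric(1))
    best <- which.min(trial)
    if (trial[best] < current_aic - 1e-10) {
      active <- setdiff(active, droppable[best])
      current_cols <- unlist(des$groups[active], use.names = FALSE)
      current_aic <- trial[best]
    } else break
  }
  Xf <- if (length(current_cols)) X[, current_cols, drop = FALSE]
    else matrix(0, n, 0)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xf), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  k <- length(current_cols)
  r2 <- if (k == 0) 0 else 1 - rss / tss
  adj_r2 <- if (k == 0) 0 else 1 - (1 - r2) * (n - 1) / (n - k - 1)
  structure(list(terms = active, columns = current_cols,
                 coefficients = fit$coefficients, aic = current_aic,
                 r2 = r2, adj_r2 = adj_r2,
                 fitted = drop(cbind(1, Xf) %*% fit$coefficients),
                 knots = des$knots, n_knots = n_knots, n = n),
            class = "spline_model")
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf("spline_model: %d term group(s), AIC %.2f, R2 %.3f (adj %.3f)\n",
              length(x$terms), x$aic, x$r2, x$adj_r2))
  invisible(x)
}

# Predict a fitted spline model on (possibly new) PC scores, reusing the
# training knots so the basis is identical.
.predict_spline <- function(model, pcs) {
  des <- .spline_design(pcs, model$n_knots, knot_list = model$knots)
  X <- des$X[, model$columns, drop = FALSE]
  drop(cbind(1, X) %*% model$coefficients[c("(Intercept)", model$columns)])
}

#' Bootstrap bias-corrected R-squared
#'
#' Optimism correction with the model-selection step rerun inside every
#' bootstrap replicate: optimism is the mean over replicates of
#' `R2(boot model on boot sample) - R2(boot model on original sample)`, and
#' the corrected value is the apparent R2 minus that optimism. An
#' intercept-only model has R2 defined as exactly 0 on any data, so its
#' corrected value is exactly 0. Replicates with a degenerate (constant)
#' outcome are skipped and counted.
#'
#' @param pcs samples x PCs matrix.
#' @param outcome numeric outcome.
#' @param B bootstrap replicates (default 300).
#' @param seed integer seed.
#' @param n_knots knots per spline.
#' @return list: `apparent`, `optimism`, `corrected`, `B_used`, `model`
#'   (the apparent fit).
#' @export
bootstrap_bias_corrected_r2 <- function(pcs, outcome, B = 300, seed = 1,
                                        n_knots = 3) {
  stopifnot(B >= 1)
  pcs <- as.matrix(pcs)
  y <- as.numeric(outcome)
  model <- penalized_ols_aic(pcs, y, n_knots = n_knots)
  tss <- sum((y - mean(y))^2)
  r2_on_original <- function(m) {
    if (length(m$columns) == 0L) return(0)
    pred <- .predict_spline(m, pcs)
    1 - sum((y - pred)^2) / tss
  }
  set.seed(seed)
  opt <- numeric(0)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(length(y), replace = TRUE)
    yb <- y[idx]
    if (stats::sd(yb) == 0) {
      skipped <- skipped + 1L
      next
    }
    mb <- tryCatch(
      penalized_ols_aic(pcs[idx, , drop = FALSE], yb, n_knots = n_knots),
      error = function(e) NULL
    )
    if (is.null(mb)) {
      skipped <- skipped + 1L
      next
    }
    opt <- c(opt, mb$r2 - r2_on_original(mb))
  }
  if (skipped > 0) ct_log(sprintf("%d degenerate bootstrap replicate(s) skipped",
                                  skipped))
  optimism <- if (length(opt)) mean(opt) else 0
  list(apparent = model$r2, optimism = optimism,
       corrected = model$r2 - optimism, B_used = length(opt), model = model)
}

#' Average per-biopsy scores to patients
#'
#' Unweighted mean per patient over non-excluded regions (ileum excluded by
#' default, matching the non-ileal analyses). Patients with all regions
#' excluded are dropped with a log entry.
#'
#' @param scores per-biopsy numeric scores.
#' @param patient_ids patient of each biopsy.
#' @param regions region of each biopsy.
#' @param exclude_regions regions to drop (case-insensitive).
#' @return named per-patient means.
#' @export
region_average <- function(scores, patient_ids, regions,
                           exclude_regions = "ileum") {
  stopifnot(length(scores) == length(patient_ids),
            length(scores) == length(regions))
  keep <- !(tolower(regions) %in% tolower(exclude_regions))
  dropped <- setdiff(unique(patient_ids), unique(patient_ids[keep]))
  if (length(dropped)) {
    ct_log(sprintf("%d patient(s) dropped (all regions excluded)",
                   length(dropped)))
  }
  if (!any(keep)) stop("all biopsies excluded")
  tapply(scores[keep], patient_ids[keep], mean)
}

#' Hypergeometric overlap of a signature with a subnetwork
#'
#' Upper-tail hypergeometric probability of the observed intersection of two
#' gene sets within a finite universe (both sets are intersected with the
#' universe first).
#'
#' @param signature_genes,subnetwork_genes gene vectors.
#' @param universe background gene vector, at least as large as either set.
#' @return list of class `overlap_result`: `n_a`, `n_b`, `overlap`,
#'   `n_universe`, `p`, `neg_log10_p`.
#' @export
network_overlap <- function(signature_genes, subnetwork_genes, universe) {
  a <- unique(signature_genes)
  b <- unique(subnetwork_genes)
  universe <- unique(universe)
  if (length(universe) < max(length(a), length(b))) {
    stop("universe smaller than one of the gene sets")
  }
  a <- intersect(a, universe)
  b <- intersect(b, universe)
  k <- length(intersect(a, b))
  p <- hypergeom_overlap_p(k, length(a), length(b), length(universe))
  structure(list(n_a = length(a), n_b = length(b), overlap = k,
                 n_universe = length(universe), p = p,
                 neg_log10_p = -log10(max(p, 1e-300))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of |A|=%d, |B|=%d in universe %d: p = %.3g (-log10 p = %.1f)\n",
              x$overlap, x$n_a, x$n_b, x$n_universe, x$p, x$neg_log10_p))
  invisible(x)
}

#' First neighbors of seed genes in an undirected network
#'
#' @param network a `gene_network` (see [read_network()]).
#' @param seed_genes seed gene vector.
#' @return sorted union of the seeds present in the network and all adjacent
#'   nodes; empty with a warning when no seed is present.
#' @export
first_neighbors <- function(network, seed_genes) {
  seeds <- intersect(unique(seed_genes), network$nodes)
  if (length(seeds) == 0L) {
    warning("no seed gene present in the network")
    return(character(0))
  }
  e <- network$edges
  hit_a <- e[, 1] %in% seeds
  hit_b <- e[, 2] %in% seeds
  sort(unique(c(seeds, e[hit_a, 2], e[hit_b, 1])))
}
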