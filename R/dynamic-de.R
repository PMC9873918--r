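# Disease-by-time interaction testing and soft clustering of disease
# trajectories into temporal classes.

.interaction_designs <- function(meta, days) {
  dayf <- factor(meta$day, levels = days)
  grp <- factor(meta$group, levels = c("control", "disease"))
  full <- stats::model.matrix(~ grp * dayf)
  reduced <- stats::model.matrix(~ grp + dayf)
  list(full = full, reduced = reduced, dayf = dayf)
}

#' Likelihood-ratio test for a disease-by-time interaction
#'
#' Per gene, negative-binomial log-likelihoods of the full
#' (`group + day + group:day`) and reduced (`group + day`) log-linear models
#' are maximized with a shared per-gene dispersion estimated under the full
#' model (Pearson moments); the statistic `2(l_full - l_reduced)` is referred
#' to a chi-square with `n_days - 1` df. Day enters as a categorical factor
#' (control and the first day as references).
#'
#' @param gene_counts a [count_matrix].
#' @param meta sample metadata; both groups must be observed at every day.
#' @param min_mean_count pre-filter threshold (see [timepoint_de()]).
#' @param normalize use median-of-ratios effective library sizes.
#' @return data.frame: `gene_id`, `stat`, `df`, `p`, `q` (BH). Genes whose
#'   fits did not converge carry NA p, counted in the `"n_nonconverged"`
#'   attribute; filtered genes in `"filtered"`.
#' @export
interaction_lrt <- function(gene_counts, meta, min_mean_count = 1,
                            normalize = TRUE) {
  meta <- .align_meta(gene_counts, meta)
  days <- sort(unique(meta$day))
  if (!all(table(meta$group, meta$day) > 0)) {
    stop("both groups must be observed at every day")
  }
  if (normalize) {
    gene_counts <- suppressWarnings(normalize_library_sizes(gene_counts))
  }
  flt <- .filter_counts(gene_counts, min_mean_count)
  cm <- flt$cm
  des <- .interaction_designs(meta, days)
  off <- log(cm$library_sizes)
  df_lrt <- length(days) - 1
  n_g <- nrow(cm$counts)
  stat <- rep(NA_real_, n_g)
  for (g in seq_len(n_g)) {
    y <- cm$counts[g, ]
    f0 <- nb_irls(des$full, y, off, phi = 0.1)
    phi <- estimate_dispersion(y, f0$mu, ncol(des$full))
    ffull <- nb_irls(des$full, y, off, phi = phi)
    fred <- nb_irls(des$reduced, y, off, phi = phi)
    if (!ffull$converged || !fred$converged) next
    lr <- 2 * (nb_loglik(y, ffull$mu, phi) - nb_loglik(y, fred$mu, phi))
    stat[g] <- max(lr, 0)
  }
  n_bad <- sum(is.na(stat))
  if (n_bad > 0) ct_log(sprintf("%d gene(s) did not converge in the LRT", n_bad))
  res <- data.frame(
    gene_id = rownames(cm$counts), stat = stat, df = df_lrt,
    p = stats::pchisq(stat, df = df_lrt, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$gene_id), ]
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  attr(res, "filtered") <- flt$filtered
  attr(res, "n_nonconverged") <- n_bad
  res
}

#' Median disease trajectories
#'
#' Per gene and day, the median log2-CPM over disease samples.
#'
#' @param we a `weighted_expression` (typically gene-level).
#' @param meta sample metadata aligned to `we` samples.
#' @param genes genes to extract (must be present in `we`).
#' @return matrix genes x days (columns named by day, ascending).
#' @export
median_disease_trajectories <- function(we, meta, genes) {
  missing <- setdiff(genes, rownames(we$E))
  if (length(missing)) {
    stop("gene(s) absent from the expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  meta <- meta[match(colnames(we$E), meta$sample_id), , drop = FALSE]
  days <- sort(unique(meta$day))
  out <- sapply(days, function(d) {
    sel <- meta$group == "disease" & meta$day == d
    if (!any(sel)) stop("no disease samples at day ", d)
    apply(we$E[genes, sel, drop = FALSE], 1, stats::median)
  })
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, as.character(days)))
  out
}

#' Row-standardize trajectories
#'
#' Each row is centred to mean 0 and scaled to sample standard deviation 1.
#' Constant rows are dropped with a warning.
#'
#' @param traj matrix genes x days.
#' @return standardized matrix (possibly fewer rows).
#' @export
standardize_trajectories <- function(traj) {
  sds <- apply(traj, 1, stats::sd)
  if (all(sds == 0)) stop("all trajectories are constant")
  if (any(sds == 0)) {
    warning(sprintf("dropped %d constant trajectory row(s)", sum(sds == 0)))
    traj <- traj[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (traj - rowMeans(traj)) / sds
}

#' Heuristic fuzzifier estimate
#'
#' Data-driven choice of the fuzzy c-means fuzzifier as a function of the
#' number of objects `n` and dimensions `d` (Schwaemmle-Jensen rule).
#'
#' @param n number of clustered objects.
#' @param d dimensionality (number of days).
#' @return fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(n, d) {
  1 + (1418 / n + 22.05) * d^(-2) +
    (12.33 / n + 0.243) * d^(-0.0406 * log(n) - 0.1134)
}

#' Fuzzy c-means clustering of standardized trajectories
#'
#' Alternating membership/centre updates:
#' `U_gc` proportional to `(1 / ||t_g - c_c||^2)^(1/(m-1))` normalized per
#' gene, and `c_c = sum_g U_gc^m t_g / sum_g U_gc^m`, iterated until the
#' maximum centre shift drops below `tol`. Centres are initialized by a
#' seeded k-means++-style draw, so results are deterministic given the seed.
#' A point coinciding with a centre receives membership 1 for that centre.
#'
#' @param x matrix of standardized trajectories (rows = genes).
#' @param k number of clusters (>= 2, <= rows).
#' @param m fuzzifier (> 1); `NULL` uses [estimate_fuzzifier()].
#' @param tol convergence tolerance on centre movement.
#' @param max_iter iteration cap.
#' @param seed integer seed for initialization.
#' @param nstart number of seeded initializations; the run with the lowest
#'   fuzzy within-cluster objective is kept.
#' @return object of class `trajectory_clusters`: `membership` (rows sum to
#'   1), `centers` (k x days), `m`, `hard` (argmax labels), `letters`
#'   (canonical class letter per cluster, when days match the canonical
#'   templates), `iterations`.
#' @export
fuzzy_cmeans <- function(x, k = 5, m = 1.25, tol = 1e-6, max_iter = 1000,
                         seed = 1, nstart = 5) {
  x <- as.matrix(x)
  stopifnot(k >= 2, nrow(x) >= k)
  if (is.null(m)) m <- estimate_fuzzifier(nrow(x), ncol(x))
  stopifnot(m > 1)
  expo <- 1 / (m - 1)

  kpp_init <- function() {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(nrow(x), 1), ]
    for (j in 2:k) {
      d2 <- apply(x, 1, function(r) {
        min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - r)^2))
      })
      if (sum(d2) == 0) {
        centers[j, ] <- x[sample.int(nrow(x), 1), ]
      } else {
        centers[j, ] <- x[sample.int(nrow(x), 1, prob = d2), ]
      }
    }
    centers
  }

  run_once <- function(centers) {
    U <- NULL
    d2 <- NULL
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
        outer(rep(1, nrow(x)), rowSums(centers^2))
      d2 <- pmax(d2, 0)
      zero <- d2 < 1e-14
      # scale by the row minimum before exponentiating so small fuzzifiers
      # (large exponents) cannot overflow
      d2min <- apply(d2, 1, min)
      inv <- (pmax(d2, 1e-14) / pmax(d2min, 1e-14))^(-expo)
      U <- inv / rowSums(inv)
      hit <- rowSums(zero) > 0
      if (any(hit)) {
        U[hit, ] <- 0
        U[cbind(which(hit), max.col(-d2[hit, , drop = FALSE]))] <- 1
      }
      um <- U^m
      new_centers <- (t(um) %*% x) / colSums(um)
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol) break
    }
    list(U = U, centers = centers, iterations = it,
         objective = sum((U^m) * d2))
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    cand <- run_once(kpp_init())
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }
  U <- best$U
  centers <- best$centers
  it <- best$iterations
  rownames(centers) <- paste0("cluster", seq_len(k))
  colnames(centers) <- colnames(x)
  dimnames(U) <- list(rownames(x), rownames(centers))
  letters <- tryCatch(assign_cluster_letters(centers, table(max.col(U))),
                      error = function(e) NULL)
  structure(list(membership = U, centers = centers, m = m,
                 hard = max.col(U), letters = letters, iterations = it),
            class = "trajectory_clusters")
}

#' Assign canonical class letters to cluster centres
#'
#' Greedy matching of centres to the canonical temporal shapes (A early,
#' B late, C very-early, D day-12-up, E day-12-down) by maximal Pearson
#' correlation; ties broken by cluster size (larger clusters first).
#'
#' @param centers k x days matrix.
#' @param sizes optional cluster sizes used for tie-breaking.
#' @return character vector of letters, one per centre (NA when k exceeds
#'   the number of canonical shapes).
#' @export
assign_cluster_letters <- function(centers, sizes = NULL) {
  shapes <- canonical_trajectory_shapes(colnames(centers))
  if (ncol(shapes) != ncol(centers)) stop("day grids do not match")
  k <- nrow(centers)
  if (is.null(sizes)) sizes <- rep(1, k)
  cors <- matrix(-Inf, k, nrow(shapes),
                 dimnames = list(rownames(centers), rownames(shapes)))
  for (i in seq_len(k)) {
    for (j in seq_len(nrow(shapes))) {
      if (stats::sd(centers[i, ]) > 0 && stats::sd(shapes[j, ]) > 0) {
        cors[i, j] <- stats::cor(centers[i, ], shapes[j, ])
      }
    }
  }
  letters <- rep(NA_character_, k)
  free_c <- seq_len(k)
  free_s <- seq_len(nrow(shapes))
  while (length(free_c) && length(free_s)) {
    sub <- cors[free_c, free_s, drop = FALSE]
    best <- max(sub)
    cand <- which(sub == best, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      cand <- cand[order(-sizes[free_c[cand[, 1]]]), , drop = FALSE]
    }
    ci <- free_c[cand[1, 1]]
    si <- free_s[cand[1, 2]]
    letters[ci] <- rownames(shapes)[si]
    free_c <- setdiff(free_c, ci)
    free_s <- setdiff(free_s, si)
  }
  letters
}

#' Gene-level disease-by-time splicing interaction test
#'
#' Fits the full interaction model on exon-level log-CPM with precision
#' weights, removes each gene's average interaction effect from its exons
#' (inverse-variance weighting), forms a moderated F over the per-exon
#' interaction deviations, and combines exons per gene with Simes. BH across
#' genes. Single-exon genes are untestable and excluded.
#'
#' @param exon_counts exon-level [count_matrix].
#' @param annotation exon-to-gene map (see [read_exon_annotation()]).
#' @param meta sample metadata; both groups at every day.
#' @param min_mean_count exon pre-filter threshold.
#' @return data.frame: `gene_id`, `n_exons`, `p` (Simes), `q`; excluded
#'   single-exon genes in the `"excluded"` attribute.
#' @export
splicing_trajectory_lrt <- function(exon_counts, annotation, meta,
                                    min_mean_count = 1, normalize = TRUE) {
  meta <- .align_meta(exon_counts, meta)
  days <- sort(unique(meta$day))
  if (!all(table(meta$group, meta$day) > 0)) {
    stop("both groups must be observed at every day")
  }
  if (normalize) {
    exon_counts <- suppressWarnings(normalize_library_sizes(exon_counts))
  }
  flt <- .filter_counts(exon_counts, min_mean_count)
  des <- .interaction_designs(meta, days)
  we <- logcpm_transform(flt$cm, design = des$full)
  fit <- moderate(fit_weighted_lm(we, des$full))
  int_cols <- grep(":", colnames(des$full), fixed = TRUE)

  gene_of <- annotation$gene_id[match(fit$feature_ids, annotation$exon_id)]
  if (any(is.na(gene_of))) stop("exon(s) missing from the annotation")
  tab <- table(gene_of)
  testable <- names(tab)[tab >= 2]
  excluded <- setdiff(names(tab), testable)
  keep <- gene_of %in% testable
  genes <- factor(gene_of[keep])

  r <- length(int_cols)
  fsum <- 0
  for (jc in int_cols) {
    beta <- fit$coefficients[keep, jc]
    se2 <- (fit$stdev_unscaled[keep, jc]^2) * fit$var_post[keep]
    dv <- .exon_deviations(beta, se2, genes)
    fsum <- fsum + dv$t^2
  }
  f_exon <- fsum / r
  df2 <- fit$df_total[keep]
  p_exon <- stats::pf(f_exon, r, df2, lower.tail = FALSE)
  p_gene <- tapply(p_exon, genes, simes_combine)
  res <- data.frame(gene_id = names(p_gene),
                    n_exons = as.integer(tab[names(p_gene)]),
                    p = as.numeric(p_gene), stringsAsFactors = FALSE)
  res <- res[order(res$gene_id), ]
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  ct_log(sprintf("splicing trajectory test: %d genes, %d single-exon excluded",
                 nrow(res), length(excluded)))
  res
}
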