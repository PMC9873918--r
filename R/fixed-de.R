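# Timepoint-specific disease-vs-control differential expression and
# signature extraction.

.subset_cm <- function(cm, sample_ids) {
  count_matrix(cm$counts[, sample_ids, drop = FALSE],
               library_sizes = cm$library_sizes[sample_ids])
}

.align_meta <- function(cm, meta) {
  meta <- meta[match(colnames(cm$counts), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) {
    stop("every sample in the count matrix needs exactly one metadata row")
  }
  meta
}

# Pre-filter genes: all-zero rows are excluded outright, rows below the mean
# count threshold filtered; both recorded for the filter log.
.filter_counts <- function(cm, min_mean_count) {
  means <- rowMeans(cm$counts)
  zero <- means == 0
  low <- !zero & means < min_mean_count
  filtered <- data.frame(
    feature_id = rownames(cm$counts)[zero | low],
    reason = c(rep("all-zero", sum(zero)), rep("low-count", sum(low))),
    stringsAsFactors = FALSE
  )
  keep <- !(zero | low)
  if (!any(keep)) stop("no features pass the count filter")
  list(cm = count_matrix(cm$counts[keep, , drop = FALSE],
                         library_sizes = cm$library_sizes),
       filtered = filtered)
}

# NB Wald engine for one timepoint: per-gene dispersion by Pearson moments,
# shrunk 50% (log scale) toward a lowess mean-dispersion trend, then a Wald
# test on the disease coefficient at the final dispersion.
.nbglm_de <- function(cm, group) {
  y_all <- cm$counts
  lib <- cm$library_sizes
  X <- cbind(intercept = 1, disease = as.numeric(group == "disease"))
  off <- log(lib)
  n_g <- nrow(y_all)
  phi_raw <- numeric(n_g)
  mus <- vector("list", n_g)
  for (g in seq_len(n_g)) {
    f0 <- nb_irls(X, y_all[g, ], off, phi = 0.1)
    phi_raw[g] <- estimate_dispersion(y_all[g, ], f0$mu, ncol(X))
    mus[[g]] <- f0$mu
  }
  mean_cpm <- rowMeans(t(t(y_all) / lib) * 1e6)
  lx <- log(mean_cpm)
  ly <- log(pmax(phi_raw, 1e-8))
  lo <- stats::lowess(lx, ly, f = 0.5)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  phi <- pmax(exp(0.5 * ly + 0.5 * trend(lx)), 1e-8)

  out <- matrix(NA_real_, n_g, 3,
                dimnames = list(rownames(y_all), c("logFC", "se", "stat")))
  for (g in seq_len(n_g)) {
    fit <- nb_irls(X, y_all[g, ], off, phi = phi[g])
    se <- sqrt(fit$cov[2, 2])
    if (!fit$converged || !is.finite(se)) next
    out[g, ] <- c(fit$coefficients[2] / log(2), se / log(2),
                  fit$coefficients[2] / se)
  }
  # t reference with the residual df: better calibrated than the normal at
  # the cohort sizes used here
  df_res <- ncol(y_all) - ncol(X)
  data.frame(gene_id = rownames(y_all),
             logFC = out[, "logFC"], se = out[, "se"], stat = out[, "stat"],
             p = 2 * stats::pt(abs(out[, "stat"]), df = df_res,
                               lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Timepoint-specific differential expression
#'
#' Tests disease vs control at a single sacrifice day. Engine `"nbglm"` fits
#' a per-gene negative-binomial log-linear model (intercept + group, library
#' size offset) with trend-shrunk Pearson dispersion and a Wald test on the
#' group coefficient. Engine `"wlm"` runs the log-CPM / precision-weight /
#' moderated-t route of the core machinery. Both report BH q-values within
#' the day.
#'
#' @param gene_counts a [count_matrix].
#' @param meta sample metadata (see [read_sample_meta()]).
#' @param day the day to test (>= 2 samples per group required).
#' @param engine `"nbglm"` or `"wlm"`.
#' @param min_mean_count pre-filter threshold on mean count (all-zero genes
#'   are always excluded; filtered genes recorded in the `"filtered"`
#'   attribute).
#' @param normalize use median-of-ratios effective library sizes (default
#'   TRUE; see [normalize_library_sizes()]).
#' @return data.frame (one row per tested gene): `gene_id`, `logFC` (log2,
#'   disease vs control), `se`, `stat`, `p`, `q`, `day`, `engine`.
#' @export
timepoint_de <- function(gene_counts, meta, day,
                         engine = c("nbglm", "wlm"), min_mean_count = 1,
                         normalize = TRUE) {
  engine <- match.arg(engine)
  meta <- .align_meta(gene_counts, meta)
  sel <- meta$day == day
  if (!any(sel)) stop("no samples at day ", day)
  meta_d <- meta[sel, , drop = FALSE]
  if (min(table(factor(meta_d$group, c("control", "disease")))) < 2) {
    stop("need >= 2 samples per group at day ", day)
  }
  cm <- .subset_cm(gene_counts, meta_d$sample_id)
  if (normalize) cm <- suppressWarnings(normalize_library_sizes(cm))
  meta_d <- .align_meta(cm, meta_d)
  flt <- .filter_counts(cm, min_mean_count)
  ct_log(sprintf("day %s DE (%s): %d genes tested, %d filtered",
                 day, engine, nrow(flt$cm$counts), nrow(flt$filtered)))

  if (engine == "nbglm") {
    res <- .nbglm_de(flt$cm, meta_d$group)
  } else {
    design <- cbind(intercept = 1,
                    disease = as.numeric(meta_d$group == "disease"))
    we <- logcpm_transform(flt$cm, design = design)
    fit <- moderate(fit_weighted_lm(we, design))
    res <- data.frame(
      gene_id = fit$feature_ids,
      logFC = fit$coefficients[, "disease"],
      se = fit$stdev_unscaled[, "disease"] * sqrt(fit$var_post),
      stat = fit$t[, "disease"],
      p = fit$p_value[, "disease"],
      stringsAsFactors = FALSE
    )
  }
  res <- res[order(res$gene_id), ]
  res$q <- bh_adjust(res$p)
  res$day <- day
  res$engine <- engine
  rownames(res) <- NULL
  attr(res, "filtered") <- flt$filtered
  res
}

#' Extract a signature from a DE table
#'
#' Genes passing the direction-appropriate log-fold-change bound and the
#' FDR threshold, labeled `fixed-day-<d>`.
#'
#' @param de a [timepoint_de()] result.
#' @param lfc_min minimum |log2FC| beyond 0 (strict inequality).
#' @param q_max FDR threshold (inclusive).
#' @param direction `"up"` (logFC > lfc_min, the headline signature rule),
#'   `"down"`, or `"both"`.
#' @param label signature label; defaults to `fixed-day-<day>`.
#' @return object of class `signature`: list with `label`, `genes`, and
#'   per-gene `direction` signs.
#' @export
extract_signature <- function(de, lfc_min = 0, q_max = 0.05,
                              direction = c("up", "down", "both"),
                              label = NULL) {
  direction <- match.arg(direction)
  pass_q <- !is.na(de$q) & de$q <= q_max
  pass_lfc <- switch(direction,
    up = de$logFC > lfc_min,
    down = de$logFC < -lfc_min,
    both = abs(de$logFC) > lfc_min
  )
  keep <- pass_q & pass_lfc & !is.na(de$logFC)
  if (is.null(label)) {
    label <- sprintf("fixed-day-%s", if (length(unique(de$day)) == 1)
      de$day[1] else "multi")
  }
  if (!any(keep)) {
    warning("empty signature at the stated thresholds (", label, ")")
  }
  genes <- de$gene_id[keep]
  structure(list(label = label, genes = genes,
                 direction = stats::setNames(sign(de$logFC[keep]), genes)),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature '%s': %d genes\n", x$label, length(x$genes)))
  invisible(x)
}

#' Fraction of signature genes specific to a single timepoint
#'
#' @param signatures list of per-day `signature` objects (>= 2).
#' @return fraction of the union present in exactly one day's signature.
#' @export
timepoint_specificity <- function(signatures) {
  stopifnot(length(signatures) >= 2)
  genes <- unlist(lapply(signatures, function(s) unique(s$genes)))
  if (length(genes) == 0L) stop("all signatures are empty")
  tab <- table(genes)
  sum(tab == 1) / length(tab)
}
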