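# Differential exon usage: per-exon deviations from the gene-average fold
# change, moderated t per exon, Simes and moderated-F gene aggregation, plus
# isoform-specific expression and co-correlation lists.

# Inverse-variance gene-average of exon coefficients and the deviation of
# each exon from it. var(dev) = se^2 - 1/sum(w) accounts for subtracting the
# weighted mean (cov(beta_e, mean) = 1/sum w under independence).
.exon_deviations <- function(beta, se2, genes) {
  w <- 1 / se2
  idx <- as.integer(genes)
  sum_w <- rowsum(w, idx)[, 1]
  wmean <- rowsum(w * beta, idx)[, 1] / sum_w
  pos <- match(idx, sort(unique(idx)))
  dev <- beta - wmean[pos]
  var_dev <- pmax(se2 - 1 / sum_w[pos], 1e-12)
  list(dev = dev, var_dev = var_dev, t = dev / sqrt(var_dev),
       weights = w, sum_w = sum_w)
}

#' Differential exon usage from a moderated exon-level fit
#'
#' For each gene with >= 2 exons, the tested coefficient is averaged across
#' exons with inverse-variance weights; each exon's deviation from that
#' average is tested with a moderated t (two-sided). Gene-level evidence is
#' aggregated two ways: Simes over the exon p-values, and a moderated
#' F-statistic (mean squared deviation t over `n_exons - 1`). Each route is
#' BH-adjusted; a gene is flagged differentially spliced when the smaller of
#' the two q-values is below `q_max`.
#'
#' @param fit a `moderated_fit` on exon-level data (see [moderate()]).
#' @param annotation exon-to-gene map.
#' @param coefficient name or index of the tested design column.
#' @param q_max flagging threshold on min(q_simes, q_F) (default 0.10).
#' @return list of class `splice_result`: `exon` (per-exon deviation table)
#'   and `gene` (per-gene `p_simes`, `q_simes`, `p_f`, `q_f`, `q_min`,
#'   `flagged`); single-exon genes in the `"excluded"` attribute.
#' @export
diff_splice <- function(fit, annotation, coefficient, q_max = 0.10) {
  stopifnot(inherits(fit, "moderated_fit"))
  if (is.character(coefficient)) {
    coefficient <- match(coefficient, colnames(fit$coefficients))
  }
  stopifnot(!is.na(coefficient))
  gene_of <- annotation$gene_id[match(fit$feature_ids, annotation$exon_id)]
  if (any(is.na(gene_of))) stop("exon(s) missing from the annotation")
  tab <- table(gene_of)
  testable <- names(tab)[tab >= 2]
  excluded <- setdiff(names(tab), testable)
  if (length(excluded)) {
    ct_log(sprintf("diff_splice: %d single-exon gene(s) excluded",
                   length(excluded)))
  }
  keep <- gene_of %in% testable
  genes <- factor(gene_of[keep])
  beta <- fit$coefficients[keep, coefficient]
  se2 <- (fit$stdev_unscaled[keep, coefficient]^2) * fit$var_post[keep]
  dv <- .exon_deviations(beta, se2, genes)
  df2 <- fit$df_total[keep]
  p_exon <- 2 * stats::pt(abs(dv$t), df = df2, lower.tail = FALSE)

  exon_tab <- data.frame(
    exon_id = fit$feature_ids[keep], gene_id = as.character(genes),
    logFC_dev = dv$dev, t = dv$t, p = p_exon, stringsAsFactors = FALSE
  )
  gene_ids <- levels(genes)
  n_exons <- as.integer(tab[gene_ids])
  p_simes <- as.numeric(tapply(p_exon, genes, simes_combine))
  f_stat <- as.numeric(tapply(dv$t^2, genes, sum)) / (n_exons - 1)
  df2_gene <- as.numeric(tapply(df2, genes, function(x) x[1]))
  p_f <- stats::pf(f_stat, n_exons - 1, df2_gene, lower.tail = FALSE)
  gene_tab <- data.frame(
    gene_id = gene_ids, n_exons = n_exons,
    p_simes = p_simes, q_simes = bh_adjust(p_simes),
    f = f_stat, p_f = p_f, q_f = bh_adjust(p_f),
    stringsAsFactors = FALSE
  )
  gene_tab$q_min <- pmin(gene_tab$q_simes, gene_tab$q_f)
  gene_tab$flagged <- gene_tab$q_min < q_max
  gene_tab <- gene_tab[order(gene_tab$gene_id), ]
  rownames(gene_tab) <- NULL
  out <- structure(list(exon = exon_tab, gene = gene_tab),
                   class = "splice_result")
  attr(out, "excluded") <- excluded
  out
}

#' Differential exon usage at a single day
#'
#' Convenience wrapper: subsets to one day, runs the log-CPM / weighted LM /
#' moderation route on exon counts with an intercept + disease design, and
#' aggregates with [diff_splice()].
#'
#' @param exon_counts exon-level [count_matrix].
#' @param annotation exon-to-gene map.
#' @param meta sample metadata.
#' @param day day to test.
#' @param q_max flagging threshold (default 0.10, the fixed-day rule).
#' @param min_mean_count exon pre-filter.
#' @param normalize use median-of-ratios effective library sizes.
#' @return a `splice_result` (see [diff_splice()]); the tested day is stored
#'   in the `"day"` attribute.
#' @export
splice_at_day <- function(exon_counts, annotation, meta, day, q_max = 0.10,
                          min_mean_count = 1, normalize = TRUE) {
  meta <- .align_meta(exon_counts, meta)
  sel <- meta$day == day
  if (!any(sel)) stop("no samples at day ", day)
  meta_d <- meta[sel, , drop = FALSE]
  if (min(table(factor(meta_d$group, c("control", "disease")))) < 2) {
    stop("need >= 2 samples per group at day ", day)
  }
  cm <- .subset_cm(exon_counts, meta_d$sample_id)
  if (normalize) cm <- suppressWarnings(normalize_library_sizes(cm))
  meta_d <- .align_meta(cm, meta_d)
  flt <- .filter_counts(cm, min_mean_count)
  design <- cbind(intercept = 1,
                  disease = as.numeric(meta_d$group == "disease"))
  we <- logcpm_transform(flt$cm, design = design)
  fit <- moderate(fit_weighted_lm(we, design))
  out <- diff_splice(fit, annotation, "disease", q_max = q_max)
  attr(out, "day") <- day
  out
}

#' Expression/splicing orthogonality report
#'
#' Quantifies how disjoint differential expression (DE) and differential
#' splicing (DS) calls are: Jaccard overlap of the pooled gene sets,
#' directional overlap fractions, per-day overlap fractions, and (when DE
#' tables are supplied) the Spearman correlation between |log2FC| and DS
#' evidence (-log10 p) among DS genes.
#'
#' @param de_sigs list (by day) of DE `signature` objects or gene vectors.
#' @param ds_sigs list (by day) of DS gene vectors (flagged genes).
#' @param de_tables optional list (by day) of [timepoint_de()] tables.
#' @param ds_tables optional list (by day) of `splice_result$gene` tables.
#' @return list: `jaccard`, `frac_ds_also_de`, `frac_de_also_ds`, `per_day`
#'   (data.frame of per-day overlap fractions), `cor_lfc_ds` (Spearman rho or
#'   NA when not computable).
#' @export
orthogonality_report <- function(de_sigs, ds_sigs, de_tables = NULL,
                                 ds_tables = NULL) {
  as_genes <- function(x) if (inherits(x, "signature")) x$genes else x
  de_by_day <- lapply(de_sigs, as_genes)
  ds_by_day <- lapply(ds_sigs, as_genes)
  de_all <- unique(unlist(de_by_day))
  ds_all <- unique(unlist(ds_by_day))
  if (length(de_all) == 0L && length(ds_all) == 0L) {
    stop("both DE and DS sets are empty")
  }
  inter <- length(intersect(de_all, ds_all))
  uni <- length(union(de_all, ds_all))
  days <- union(names(de_by_day), names(ds_by_day))
  per_day <- data.frame(
    day = days,
    n_de = vapply(days, function(d) length(de_by_day[[d]]), integer(1)),
    n_ds = vapply(days, function(d) length(ds_by_day[[d]]), integer(1)),
    overlap = vapply(days, function(d) {
      length(intersect(de_by_day[[d]], ds_by_day[[d]]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  cor_lfc_ds <- NA_real_
  if (!is.null(de_tables) && !is.null(ds_tables) && length(ds_all) >= 3) {
    pairs <- do.call(rbind, lapply(days, function(d) {
      det <- de_tables[[d]]
      dst <- ds_tables[[d]]
      if (is.null(det) || is.null(dst)) return(NULL)
      dst <- dst[dst$flagged, , drop = FALSE]
      m <- match(dst$gene_id, det$gene_id)
      ok <- !is.na(m)
      data.frame(lfc = abs(det$logFC[m[ok]]),
                 ev = -log10(pmax(dst$p_simes[ok], 1e-300)))
    }))
    if (!is.null(pairs) && nrow(pairs) >= 3 &&
        stats::sd(pairs$lfc) > 0 && stats::sd(pairs$ev) > 0) {
      cor_lfc_ds <- spearman_cor(pairs$lfc, pairs$ev)$rho
    }
  }
  list(
    jaccard = if (uni > 0) inter / uni else NA_real_,
    frac_ds_also_de = if (length(ds_all)) inter / length(ds_all) else NA_real_,
    frac_de_also_ds = if (length(de_all)) inter / length(de_all) else NA_real_,
    per_day = per_day,
    cor_lfc_ds = cor_lfc_ds
  )
}

#' Relative exon usage
#'
#' Converts exon-level log2-CPM to usage scores by subtracting, per sample,
#' the mean log2-CPM of the exon's gene across its bins. The result isolates
#' exon usage from overall gene expression and is the exon-side input to the
#' signature feature builder ("relative isoform expression").
#'
#' @param we_exon exon-level `weighted_expression`.
#' @param annotation exon-to-gene map.
#' @return a `weighted_expression` whose `E` holds usage scores (weights
#'   carried over).
#' @export
relative_exon_usage <- function(we_exon, annotation) {
  gene_of <- annotation$gene_id[match(rownames(we_exon$E),
                                      annotation$exon_id)]
  if (any(is.na(gene_of))) stop("exon(s) missing from the annotation")
  idx <- match(gene_of, sort(unique(gene_of)))
  gene_mean <- rowsum(we_exon$E, idx) / as.vector(table(idx))
  out <- we_exon
  out$E <- we_exon$E - gene_mean[idx, , drop = FALSE]
  out
}

#' Isoform-specific expression scores
#'
#' Per sample, the mean log2-CPM over the exons designated as specific to
#' each isoform (user-supplied map; exon sets of the two isoforms of a gene
#' must be disjoint).
#'
#' @param exon_counts exon-level [count_matrix].
#' @param isoform_map data.frame with columns `gene_id`, `isoform`,
#'   `exon_id`.
#' @return matrix isoforms x samples, rownames `gene_id:isoform`.
#' @export
isoform_specific_expression <- function(exon_counts, isoform_map) {
  need <- c("gene_id", "isoform", "exon_id")
  stopifnot(all(need %in% colnames(isoform_map)))
  E <- t(log2(t(exon_counts$counts + 0.5) /
                (exon_counts$library_sizes + 1) * 1e6))
  keys <- unique(isoform_map[, c("gene_id", "isoform")])
  for (g in unique(keys$gene_id)) {
    sets <- split(isoform_map$exon_id[isoform_map$gene_id == g],
                  isoform_map$isoform[isoform_map$gene_id == g])
    if (length(sets) >= 2 &&
        length(Reduce(intersect, sets)) > 0) {
      stop("designated exon sets overlap for gene ", g)
    }
  }
  scores <- t(apply(keys, 1, function(k) {
    exons <- isoform_map$exon_id[isoform_map$gene_id == k[["gene_id"]] &
                                   isoform_map$isoform == k[["isoform"]]]
    exons <- intersect(exons, rownames(E))
    if (length(exons) == 0L) {
      stop("no designated exons present for ", k[["gene_id"]], ":",
           k[["isoform"]])
    }
    colMeans(E[exons, , drop = FALSE])
  }))
  rownames(scores) <- paste(keys$gene_id, keys$isoform, sep = ":")
  colnames(scores) <- colnames(E)
  scores
}

#' Genes co-correlated with isoform scores
#'
#' For each isoform score, the genes whose expression correlates with it
#' above `r_min` (Pearson). Zero-variance gene rows are skipped.
#'
#' @param iso matrix of isoform scores (rows = isoforms) from
#'   [isoform_specific_expression()].
#' @param we gene-level `weighted_expression` over the same samples.
#' @param r_min correlation threshold (strict; the headline analyses use 0.8
#'   and 0.7).
#' @return named list of gene vectors, one per isoform.
#' @export
correlated_gene_lists <- function(iso, we, r_min = 0.8) {
  stopifnot(ncol(iso) == ncol(we$E))
  if (ncol(iso) < 3) stop("need >= 3 samples")
  gene_sd <- apply(we$E, 1, stats::sd)
  usable <- we$E[gene_sd > 0, , drop = FALSE]
  out <- lapply(seq_len(nrow(iso)), function(i) {
    sc <- iso[i, ]
    if (stats::sd(sc) == 0) return(character(0))
    r <- as.vector(stats::cor(t(usable), sc))
    sort(rownames(usable)[r > r_min])
  })
  names(out) <- rownames(iso)
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each set's overlap with the query,
#' within a stated gene universe; BH across sets. Sets with empty universe
#' intersection are skipped.
#'
#' @param query gene vector (must lie within the universe).
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param universe background gene vector (default: union of query and all
#'   sets).
#' @return data.frame: `set`, `n_set` (within universe), `overlap`, `p`,
#'   `q`.
#' @export
geneset_enrichment <- function(query, collection, universe = NULL) {
  query <- unique(query)
  if (is.null(universe)) universe <- union(query, unlist(collection))
  universe <- unique(universe)
  if (length(setdiff(query, universe))) {
    stop("query genes outside the universe")
  }
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(collection[[nm]], universe)
    if (length(set_u) == 0L) return(NULL)
    k <- length(intersect(query, set_u))
    data.frame(set = nm, n_set = length(set_u), overlap = k,
               p = hypergeom_overlap_p(k, length(query), length(set_u),
                                       length(universe)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(set = character(0), n_set = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}
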