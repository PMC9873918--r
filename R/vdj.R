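# Adaptive immune burden and clonality per sample from VDJ clone abundance
# tables. NOTE: the clonality definition is the standard repertoire metric
# 1 - Pielou evenness (normalized Shannon entropy of clone frequencies); a
# single-clone sample has clonality 1 by convention.

#' VDJ read burden per million library reads
#'
#' `1e6 * sum(clone reads) / library_size` per sample. Samples present in
#' `library_sizes` but absent from the clone table get burden 0; a clone-table
#' sample missing from `library_sizes` is an error.
#'
#' @param clone_table data.frame `sample_id`, `clone_id`, `reads`.
#' @param library_sizes named positive vector of total library reads.
#' @return named numeric vector over the samples of `library_sizes`.
#' @export
vdj_read_cpm <- function(clone_table, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  missing <- setdiff(unique(clone_table$sample_id), names(library_sizes))
  if (length(missing)) {
    stop("sample(s) absent from the library-size table: ",
         paste(missing, collapse = ", "))
  }
  tot <- tapply(clone_table$reads, clone_table$sample_id, sum)
  out <- stats::setNames(rep(0, length(library_sizes)), names(library_sizes))
  out[names(tot)] <- tot
  1e6 * out / library_sizes
}

#' Clonality of a clone abundance vector
#'
#' `1 - H / ln(K)` where `H` is the Shannon entropy (nats) of the clone
#' frequency vector and `K` the number of clones with positive count.
#' `K = 1` returns 1 by convention; equal abundances return 0. Invariant
#' under rescaling of abundances.
#'
#' @param abundances non-negative clone read counts, at least one positive.
#' @return clonality in `[0, 1]`.
#' @export
clonality <- function(abundances) {
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0L) stop("all clone abundances are zero")
  k <- length(abundances)
  if (k == 1L) return(1)
  f <- abundances / sum(abundances)
  h <- -sum(f * log(f))
  max(0, min(1, 1 - h / log(k)))
}

#' Per-sample VDJ profile
#'
#' @param clone_table data.frame `sample_id`, `clone_id`, `reads`.
#' @param library_sizes named positive vector of total library reads.
#' @return data.frame: `sample_id`, `vdj_read_cpm`, `clone_count`,
#'   `clonality` (NA for samples with no detected clones).
#' @export
vdj_profile <- function(clone_table, library_sizes) {
  cpm <- vdj_read_cpm(clone_table, library_sizes)
  by_sample <- split(clone_table$reads, clone_table$sample_id)
  ids <- names(library_sizes)
  data.frame(
    sample_id = ids,
    vdj_read_cpm = unname(cpm[ids]),
    clone_count = vapply(ids, function(s) {
      if (is.null(by_sample[[s]])) 0L else sum(by_sample[[s]] > 0)
    }, integer(1)),
    clonality = vapply(ids, function(s) {
      if (is.null(by_sample[[s]]) || sum(by_sample[[s]]) == 0) NA_real_
      else clonality(by_sample[[s]])
    }, numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Correlation of VDJ measurements with severity
#'
#' Spearman rank correlation between a VDJ measurement (burden, clonality)
#' and a paired severity proxy (histology score, lymphocyte aggregate
#' count). Exact p for n <= 9, t approximation otherwise; constant vectors
#' yield NA.
#'
#' @param vdj_values named or plain numeric vector.
#' @param severity paired numeric vector (matched by name when both are
#'   named).
#' @return list with `rho` and `p`.
#' @export
vdj_severity_correlation <- function(vdj_values, severity) {
  if (!is.null(names(vdj_values)) && !is.null(names(severity))) {
    common <- intersect(names(vdj_values), names(severity))
    if (length(common) < 3) stop("need >= 3 paired samples")
    vdj_values <- vdj_values[common]
    severity <- severity[common]
  }
  spearman_cor(as.numeric(vdj_values), as.numeric(severity))
}
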