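# Readers and writers for the plain-text formats the pipeline touches.
# TSV is the canonical dialect: tab-separated, '#' comment lines allowed,
# feature/sample ids case-sensitive. Feature and sample order is
# canonicalized by sorted id on construction so that loading order can never
# change a downstream number.

#' Construct a count matrix container
#'
#' Bundles an integer feature-by-sample count matrix with per-sample library
#' sizes. Rows and columns are sorted by id; library sizes default to column
#' sums but may be overridden (e.g. to use total library reads for blood or
#' VDJ consistency).
#'
#' @param counts integer matrix with unique rownames (features) and colnames
#'   (samples); all cells non-negative integers.
#' @param library_sizes optional named positive numeric vector, one entry per
#'   sample; defaults to column sums.
#' @return object of class `count_matrix` with elements `counts` and
#'   `library_sizes`.
#' @export
count_matrix <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at feature '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  storage.mode(counts) <- "double"
  counts <- counts[order(rownames(counts)), order(colnames(counts)), drop = FALSE]
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
  } else {
    if (is.null(names(library_sizes))) stop("library_sizes must be named")
    missing <- setdiff(colnames(counts), names(library_sizes))
    if (length(missing)) {
      stop("library_sizes missing for sample(s): ", paste(missing, collapse = ", "))
    }
    library_sizes <- library_sizes[colnames(counts)]
  }
  if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  structure(
    list(counts = counts, library_sizes = library_sizes),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d features x %d samples (median library size %.3g)\n",
    nrow(x$counts), ncol(x$counts), stats::median(x$library_sizes)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Median-of-ratios effective library sizes
#'
#' Replaces column-sum library sizes with composition-robust effective sizes:
#' per sample, the median ratio of counts to the per-feature geometric mean
#' (features observed in every sample), rescaled to preserve the overall
#' library-size scale. This guards fold-change estimates against composition
#' bias when many features change in one direction.
#'
#' @param cm a [count_matrix].
#' @return the same matrix with normalized `library_sizes`.
#' @export
normalize_library_sizes <- function(cm) {
  counts <- cm$counts
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 10) {
    warning("fewer than 10 all-positive features; library sizes unchanged")
    return(cm)
  }
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc - geo, 2, function(r) exp(stats::median(r)))
  sf <- sf / exp(mean(log(sf)))
  scale_keep <- exp(mean(log(cm$library_sizes)))
  cm$library_sizes <- sf * scale_keep
  cm
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a count matrix from TSV
#'
#' First column holds feature ids, the header the sample ids. Exon-kind
#' matrices are identical in layout; their feature ids are exon (counting
#' bin) ids that a companion annotation maps to genes.
#'
#' @param path TSV file path.
#' @param kind `"gene"` or `"exon"` (layout identical; recorded as an
#'   attribute).
#' @param library_sizes optional named override of the per-sample library
#'   sizes.
#' @return a [count_matrix].
#' @export
read_counts <- function(path, kind = c("gene", "exon"), library_sizes = NULL) {
  kind <- match.arg(kind)
  tab <- .read_tsv(path)
  if (ncol(tab) < 2) stop("count table needs a feature-id column and >= 1 sample")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in count table")
  rownames(mat) <- ids
  cm <- count_matrix(mat, library_sizes = library_sizes)
  attr(cm, "kind") <- kind
  ct_log(sprintf("read %s counts: %d x %d from %s",
                 kind, nrow(cm$counts), ncol(cm$counts), path))
  cm
}

#' Write a count matrix to TSV
#'
#' @param cm a [count_matrix].
#' @param path output file.
#' @param feature_col header name of the feature-id column.
#' @export
write_counts <- function(cm, path, feature_col = "feature_id") {
  df <- data.frame(rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read exon counting-bin annotation
#'
#' @param path TSV with columns `exon_id`, `gene_id`, `bin_index`.
#' @return data.frame sorted by exon id; every exon maps to exactly one gene.
#' @export
read_exon_annotation <- function(path) {
  tab <- .read_tsv(path)
  need <- c("exon_id", "gene_id", "bin_index")
  if (!all(need %in% colnames(tab))) {
    stop("exon annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$exon_id)) stop("duplicate exon ids in annotation")
  if (any(tab$bin_index < 1 | tab$bin_index != round(tab$bin_index))) {
    stop("bin_index must be a positive integer")
  }
  tab <- tab[order(tab$exon_id), need]
  rownames(tab) <- NULL
  tab
}

#' Read and validate per-sample metadata
#'
#' Columns `sample_id`, `group`, `day`, `cohort`, `tissue`. Group labels are
#' normalized case-insensitively to `disease` / `control`; days must belong
#' to the declared timepoint set.
#'
#' @param path TSV file path.
#' @param allowed_days integer set of valid sacrifice days.
#' @return validated data.frame sorted by sample id.
#' @export
read_sample_meta <- function(path, allowed_days = c(5, 12, 17, 36)) {
  tab <- .read_tsv(path)
  need <- c("sample_id", "group", "day", "cohort", "tissue")
  if (!all(need %in% colnames(tab))) {
    stop("sample metadata needs columns: ", paste(need, collapse = ", "))
  }
  validate_sample_meta(tab[, need], allowed_days = allowed_days)
}

#' Validate a sample-metadata table
#'
#' @param meta data.frame with the columns of [read_sample_meta()].
#' @param allowed_days integer set of valid days.
#' @return normalized data.frame sorted by sample id.
#' @export
validate_sample_meta <- function(meta, allowed_days = c(5, 12, 17, 36)) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  grp <- tolower(trimws(as.character(meta$group)))
  bad <- setdiff(unique(grp), c("disease", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  meta$group <- grp
  meta$day <- as.numeric(meta$day)
  off <- setdiff(unique(meta$day), allowed_days)
  if (length(off)) {
    stop("day(s) outside the declared timepoint set: ",
         paste(off, collapse = ", "))
  }
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: per line a set name, a description, then members.
#' @return named list of unique member character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    nm <- parts[[1]]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop(sprintf("GMT line %d has an empty set", i))
    sets[[nm]] <- members
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors (a description attribute per
#'   element is honoured, else the set name is reused).
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected network edge list
#'
#' Accepts SIF (`node relation node`) or two-column TSV. Direction is
#' discarded, duplicate edges (ignoring order) collapsed, self-loops dropped
#' with a warning.
#'
#' @param path file path.
#' @param dialect `"sif"`, `"tsv"`, or `"auto"` (sniff from the first data
#'   line's field count).
#' @return object of class `gene_network`: list with `edges` (two-column
#'   character matrix, lexicographically ordered within edge) and `nodes`.
#' @export
read_network <- function(path, dialect = c("auto", "sif", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(structure(list(edges = matrix(character(0), ncol = 2),
                          nodes = character(0)), class = "gene_network"))
  }
  split_fields <- function(l) strsplit(trimws(l), "[\t ]+")[[1]]
  if (dialect == "auto") {
    dialect <- if (length(split_fields(lines[[1]])) >= 3) "sif" else "tsv"
  }
  pairs <- lapply(seq_along(lines), function(i) {
    f <- split_fields(lines[[i]])
    if (dialect == "sif") {
      if (length(f) < 3) stop(sprintf("malformed SIF line %d", i))
      cbind(f[1], f[3:length(f)])
    } else {
      if (length(f) != 2) stop(sprintf("malformed edge-list line %d", i))
      cbind(f[1], f[2])
    }
  })
  edges <- do.call(rbind, pairs)
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges)) {
    ordered <- t(apply(edges, 1, sort))
    edges <- ordered[!duplicated(paste(ordered[, 1], ordered[, 2], sep = "\r")),
                     , drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(edges = edges, nodes = sort(unique(as.vector(edges)))),
            class = "gene_network")
}

#' Read a two-column mouse-to-human ortholog map
#'
#' @param path TSV with columns mouse id, human id (header optional but the
#'   first row is treated as a header when it repeats no ids).
#' @return data.frame with columns `mouse`, `human`, unique pairs.
#' @export
read_ortholog_map <- function(path) {
  tab <- .read_tsv(path, header = TRUE)
  if (ncol(tab) < 2) stop("ortholog map needs two columns (mouse, human)")
  out <- data.frame(mouse = as.character(tab[[1]]),
                    human = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$mouse, out$human), ]
}

#' Read a VDJ clone abundance table
#'
#' @param path TSV with columns `sample_id`, `clone_id`, `reads`.
#' @return data.frame with non-negative integer read counts.
#' @export
read_clone_table <- function(path) {
  tab <- .read_tsv(path)
  need <- c("sample_id", "clone_id", "reads")
  if (!all(need %in% colnames(tab))) {
    stop("clone table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$reads < 0 | tab$reads != round(tab$reads))) {
    stop("clone read counts must be non-negative integers")
  }
  tab[, need]
}

#' Read per-sample histology scores
#'
#' @param path TSV with columns `sample_id`, `histology` (and optionally
#'   `status`).
#' @return data.frame with non-negative scores.
#' @export
read_histology <- function(path) {
  tab <- .read_tsv(path)
  need <- c("sample_id", "histology")
  if (!all(need %in% colnames(tab))) {
    stop("histology table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$histology < 0)) stop("histology scores must be >= 0")
  tab
}
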