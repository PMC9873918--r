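#' @keywords internal
"_PACKAGE"

# Stage-boundary logging. Level threshold taken from
# options(colitraj.log_level), one of "debug", "info", "warn", "none".
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, none = 4L)

ct_log <- function(msg, level = "info") {
  threshold <- getOption("colitraj.log_level", "warn")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[colitraj %s] %s", level, msg))
  }
  invisible(NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: `q_i` is the smallest over
#' `j >= rank(i)` of `p_(j) * m / j`, capped at 1. NaN inputs propagate with
#' a warning.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) warning("NaN p-values propagated through BH adjustment")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Simes combination of p-values
#'
#' Combined p-value `min_i p_(i) * m / i` for a global null over `m` tests.
#'
#' @param p non-empty numeric vector of p-values.
#' @return a single combined p-value in `[0, 1]`.
#' @export
simes_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("simes_combine() requires at least one p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  min(1, min(sort(p) * m / seq_len(m)))
}

#' Spearman rank correlation with p-value
#'
#' Rank correlation between two paired vectors. The p-value is exact for
#' n <= 9 without ties and uses the t approximation otherwise.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `rho` and `p` (both NA when either vector is constant).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  exact <- length(x) <= 9L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Cohen's kappa for two categorical vectors
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)`. Perfect agreement with
#' `pe = 1` (both raters constant and equal) returns 1.
#'
#' @param observed,predicted vectors of equal length, coercible to factor
#'   over their common level set.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  lev <- sort(unique(c(as.character(observed), as.character(predicted))))
  o <- factor(as.character(observed), levels = lev)
  p <- factor(as.character(predicted), levels = lev)
  tab <- table(o, p)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least `overlap` members of a `k_b`-element set
#' when sampling `k_a` elements without replacement from a universe of size
#' `n_universe`.
#'
#' @param overlap observed intersection size.
#' @param k_a,k_b sizes of the two sets within the universe.
#' @param n_universe universe size.
#' @return upper-tail p-value in `(0, 1]`.
#' @export
hypergeom_overlap_p <- function(overlap, k_a, k_b, n_universe) {
  stopifnot(overlap <= min(k_a, k_b), k_a <= n_universe, k_b <= n_universe)
  stats::phyper(overlap - 1, k_b, n_universe - k_b, k_a, lower.tail = FALSE)
}

# Newton inversion of the trigamma function, used when estimating the prior
# degrees of freedom of the variance distribution.
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
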