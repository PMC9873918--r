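# Shared statistical machinery: log-CPM with mean-variance precision
# weights, per-feature weighted least squares, empirical-Bayes variance
# moderation, and an NB GLM fitter used by the count-based engines.

#' Log-CPM transform with mean-variance precision weights
#'
#' Computes `E = log2((count + 0.5) / (library_size + 1) * 1e6)` and
#' observation-level weights from a fitted mean-variance trend: per-feature
#' residual standard deviations (on the `sqrt(sd)` scale) are lowess-smoothed
#' against average log2 count, the trend is evaluated at each observation's
#' fitted log2 count, and the weight is the predicted standard deviation to
#' the power -4. With fewer than 50 features the trend is not estimable and
#' unit weights are used with a warning.
#'
#' @param cm a [count_matrix].
#' @param design model matrix used to compute residual standard deviations for
#'   the trend (default: per-feature intercept only).
#' @param span lowess span of the trend fit.
#' @return object of class `weighted_expression`: list with `E` (log2-CPM),
#'   `weights`, `design` used for the trend, and `lib_sizes`.
#' @export
logcpm_transform <- function(cm, design = NULL, span = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  lib <- cm$library_sizes
  E <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
  n_f <- nrow(E)
  n_s <- ncol(E)
  if (is.null(design)) design <- matrix(1, n_s, 1)
  design <- as.matrix(design)

  unit_weights <- function(reason) {
    warning("mean-variance trend not estimable (", reason,
            "); using unit weights")
    structure(list(E = E, weights = matrix(1, n_f, n_s,
                                           dimnames = dimnames(E)),
                   design = design, lib_sizes = lib),
              class = "weighted_expression")
  }
  if (n_f < 50) return(unit_weights("fewer than 50 features"))
  if (n_s <= ncol(design)) return(unit_weights("no residual df"))

  qrX <- qr(design)
  fitted <- t(qr.fitted(qrX, t(E)))
  res <- E - fitted
  df_res <- n_s - qrX$rank
  sigma <- sqrt(rowSums(res^2) / df_res)

  # mean log2 count scale for the trend
  avg_logcount <- rowMeans(E) + mean(log2(lib + 1)) - log2(1e6)
  sqrt_sd <- sqrt(sigma)
  ok <- is.finite(avg_logcount) & is.finite(sqrt_sd) & sigma > 0
  if (sum(ok) < 50) return(unit_weights("too few positive-variance features"))
  lo <- stats::lowess(avg_logcount[ok], sqrt_sd[ok], f = span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)

  fitted_logcount <- t(t(fitted) + log2(lib + 1) - log2(1e6))
  pred_sqrt_sd <- pmax(trend(fitted_logcount), 1e-4)
  w <- matrix(pred_sqrt_sd^-4, n_f, n_s, dimnames = dimnames(E))
  structure(list(E = E, weights = w, design = design, lib_sizes = lib),
            class = "weighted_expression")
}

#' @export
print.weighted_expression <- function(x, ...) {
  cat(sprintf("weighted_expression: %d features x %d samples\n",
              nrow(x$E), ncol(x$E)))
  invisible(x)
}

#' Per-feature weighted least squares
#'
#' Fits `E_g ~ design` by weighted least squares for every feature, carrying
#' the observation weights of the log-CPM transform. Residual df equals
#' `n - rank(design)`; features with zero residual df are flagged untestable
#' (residual sd NA).
#'
#' @param we a `weighted_expression`.
#' @param design full-rank model matrix (rows = samples, in `we` column
#'   order).
#' @return object of class `linear_fit`: `coefficients` and
#'   `stdev_unscaled` (features x design columns), `sigma`, `df_residual`,
#'   `design`.
#' @export
fit_weighted_lm <- function(we, design) {
  stopifnot(inherits(we, "weighted_expression"))
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  n_s <- ncol(we$E)
  stopifnot(nrow(design) == n_s)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    aliased <- colnames(design)[setdiff(seq_len(ncol(design)),
                                        qrX$pivot[seq_len(qrX$rank)])]
    stop("design is rank-deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  p <- ncol(design)
  n_f <- nrow(we$E)
  coefs <- matrix(NA_real_, n_f, p,
                  dimnames = list(rownames(we$E), colnames(design)))
  stdev <- coefs
  sigma <- rep(NA_real_, n_f)
  df_res <- n_s - p
  for (g in seq_len(n_f)) {
    w <- we$weights[g, ]
    sw <- sqrt(w)
    fit <- stats::lm.fit(design * sw, we$E[g, ] * sw)
    coefs[g, ] <- fit$coefficients
    R <- qr.R(fit$qr)
    xtxinv <- chol2inv(R)
    stdev[g, ] <- sqrt(diag(xtxinv))[order(fit$qr$pivot)][seq_len(p)]
    if (df_res > 0) sigma[g] <- sqrt(sum(fit$residuals^2) / df_res)
  }
  structure(list(coefficients = coefs, stdev_unscaled = stdev, sigma = sigma,
                 df_residual = rep(df_res, n_f), design = design,
                 feature_ids = rownames(we$E)),
            class = "linear_fit")
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-feature residual variances toward a common prior by fitting a
#' scaled-F model to the observed variances: the prior degrees of freedom
#' `d0` and prior variance `s0^2` are estimated by method of moments on
#' `log s_g^2` with the digamma/trigamma corrections of the classic
#' moderated-t derivation. Posterior variances are
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and moderated t-statistics are
#' referred to `d0 + d_g` df.
#'
#' @param fit a `linear_fit` with >= 2 features with positive residual df.
#' @param df_prior optional fixed prior df overriding the estimate (0 gives
#'   ordinary t-statistics, Inf full shrinkage to the prior variance).
#' @return the fit, extended with `df_prior`, `var_prior`, `var_post`, `t`
#'   and `p_value` matrices (class `moderated_fit`).
#' @export
moderate <- function(fit, df_prior = NULL) {
  stopifnot(inherits(fit, "linear_fit"))
  ok <- !is.na(fit$sigma) & fit$df_residual >= 1
  if (sum(ok) < 2) stop("need >= 2 features with residual df >= 1")
  s2 <- fit$sigma[ok]^2
  df <- fit$df_residual[ok]
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- max(0, stats::var(e) * (sum(ok) - 1) / sum(ok) -
                mean(trigamma(df / 2)))
  if (evar > 1e-12) {
    est_df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(mean(e) + digamma(est_df_prior / 2) -
                       log(est_df_prior / 2))
  } else {
    est_df_prior <- Inf
    # identical observed variances are a fixed point: the prior equals them
    var_prior <- if (stats::var(z) < 1e-12) exp(mean(z)) else exp(mean(e))
  }
  if (is.null(df_prior)) df_prior <- est_df_prior
  var_post <- rep(NA_real_, length(fit$sigma))
  var_post[ok] <- if (is.infinite(df_prior)) var_prior else {
    (df_prior * var_prior + df * s2) / (df_prior + df)
  }
  df_total <- ifelse(ok, pmin(df_prior + fit$df_residual, 1e7), NA_real_)
  tval <- fit$coefficients / (fit$stdev_unscaled * sqrt(var_post))
  pval <- 2 * stats::pt(abs(tval), df = df_total, lower.tail = FALSE)
  fit$df_prior <- df_prior
  fit$var_prior <- var_prior
  fit$var_post <- var_post
  fit$df_total <- df_total
  fit$t <- tval
  fit$p_value <- pval
  class(fit) <- c("moderated_fit", "linear_fit")
  fit
}

# ---- negative-binomial GLM machinery ---------------------------------------

# Log-link NB IRLS with fixed dispersion phi (var = mu + phi mu^2).
# Returns coefficients, fitted mu, covariance of coefficients, convergence.
nb_irls <- function(X, y, offset = 0, phi, max_iter = 50, tol = 1e-8) {
  p <- ncol(X)
  mu <- pmax(y, 0.5)
  eta <- log(mu) - offset
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    zz <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, zz, w)
    new_beta <- fit$coefficients
    if (any(!is.finite(new_beta))) break
    eta_new <- drop(X %*% new_beta)
    eta_new <- pmin(pmax(eta_new, -50), 50)
    if (max(abs(eta_new - eta)) < tol) converged <- TRUE
    eta <- eta_new
    mu <- exp(eta + offset)
    beta <- new_beta
    if (converged) break
  }
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  list(coefficients = beta, mu = mu, cov = cov, converged = converged)
}

nb_loglik <- function(y, mu, phi) {
  sum(stats::dnbinom(y, size = 1 / phi, mu = pmax(mu, 1e-12), log = TRUE))
}

# Dispersion of one gene by solving the Pearson moment equation under given
# fitted means (residual df n - p); falls back to the simple moment estimator.
estimate_dispersion <- function(y, mu, p) {
  n <- length(y)
  if (n <= p) return(1e-8)
  pearson <- function(phi) sum((y - mu)^2 / (mu + phi * mu^2)) - (n - p)
  lo <- 1e-8
  if (pearson(lo) <= 0) return(lo)
  hi <- 10
  while (pearson(hi) > 0 && hi < 1e4) hi <- hi * 10
  if (pearson(hi) > 0) return(hi)
  stats::uniroot(pearson, c(lo, hi), tol = 1e-8)$root
}
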