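#' Phylogenetic generalized least squares at a fixed Pagel's lambda
#'
#' Fits y = X beta + e with e ~ N(0, sigma^2 * V_lambda), where V_lambda is
#' the Brownian covariance matrix with off-diagonals scaled by `lambda`
#' (see [apply_lambda()]). Estimation is by Cholesky whitening: with
#' V_lambda = L'L, the model is ordinary least squares on L'^-1 y and
#' L'^-1 X.
#'
#' Conventions (held fixed so AIC is comparable across fits):
#' * sigma^2 is the maximum-likelihood estimate RSS/n, and the reported
#'   log-likelihood is the full multivariate-normal ML log-likelihood;
#' * coefficient standard errors and t-tests use the unbiased residual
#'   variance RSS/(n - k) on n - k degrees of freedom, so that at
#'   `lambda = 0` on an ultrametric tree the fit reproduces ordinary least
#'   squares exactly;
#' * the model P value is the F test of all non-intercept coefficients;
#' * r^2 = 1 - RSS/TSS in the whitened space, with TSS taken from the
#'   intercept-only GLS fit at the same lambda, so r^2 lies in \[0, 1\];
#' * AIC = 2k' - 2 logL with k' = #coefficients + 1 (sigma^2) + 1 more when
#'   lambda was estimated by ML.
#'
#' @param y named numeric response vector.
#' @param X design matrix with an intercept column first; rownames must
#'   match `names(y)`.
#' @param C raw phylogenetic covariance matrix from [vcv_matrix()], with
#'   dimnames matching `names(y)` in the same order.
#' @param lambda fixed value of Pagel's lambda in \[0, 1\].
#' @param lambda_estimated internal flag: counts lambda as a free parameter
#'   in the AIC penalty (set by [profile_lambda_ml()]).
#' @return an object of class `pgls_fit`: list with `coefficients` (data
#'   frame: term, estimate, se, t, p), `lambda`, `lambda_mode`, `sigma2`
#'   (ML), `logLik`, `r_squared`, `model_p`, `aic`, `n`, `k`, `k_aic`,
#'   `rss`, `tss`, `taxa`, `fitted`, `residuals` (response scale).
#' @export
gls_fit_fixed_lambda <- function(y, X, C, lambda, lambda_estimated = FALSE) {
  if (is.null(names(y)) || is.null(rownames(X)) || is.null(rownames(C)))
    stop("y, X and C must carry taxon names (names/rownames)")
  if (!identical(names(y), rownames(X)) || !identical(names(y), rownames(C)))
    stop("taxa of y, X and C must be identical and in the same order; ",
         "mismatch: ",
         paste(utils::head(c(setdiff(names(y), rownames(C)),
                             setdiff(rownames(C), names(y))), 5),
               collapse = ", "))
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("need more taxa (", n, ") than coefficients (", k, ")")
  V <- apply_lambda(C, lambda)
  ch <- tryCatch(chol(V), error = function(e)
    stop("lambda-transformed covariance is not positive definite: ",
         conditionMessage(e)))
  wy <- backsolve(ch, y, transpose = TRUE)
  wX <- backsolve(ch, X, transpose = TRUE)
  XtX <- crossprod(wX)
  qr_ <- qr(wX)
  if (qr_$rank < k) {
    dep <- colnames(X)[qr_$pivot[seq.int(qr_$rank + 1L, k)]]
    stop("singular design matrix; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- drop(solve(XtX, crossprod(wX, wy)))
  res_w <- wy - drop(wX %*% beta)
  rss <- sum(res_w^2)
  logdet <- 2 * sum(log(diag(ch)))
  sigma2_ml <- rss / n
  logL <- if (sigma2_ml > 0)
    -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdet + n)
  else Inf
  # intercept-only GLS at the same lambda defines the whitened TSS
  w1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  b0 <- sum(w1 * wy) / sum(w1^2)
  tss <- sum((wy - w1 * b0)^2)
  s2 <- rss / (n - k)
  XtXinv <- chol2inv(chol(XtX))
  se <- sqrt(s2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  q <- k - 1L  # non-intercept terms
  if (q >= 1L && rss > 0) {
    Fstat <- ((tss - rss) / q) / (rss / (n - k))
    model_p <- stats::pf(Fstat, q, n - k, lower.tail = FALSE)
  } else {
    Fstat <- NA_real_
    model_p <- NA_real_
  }
  r2 <- if (tss > sqrt(.Machine$double.eps) * n) {
    max(0, min(1, 1 - rss / tss))
  } else 0  # constant (whitened) response carries no explainable variance
  k_aic <- k + 1L + as.integer(lambda_estimated)
  fitted_resp <- drop(X %*% beta)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta, se = se,
                              t = tval, p = pval, row.names = NULL,
                              stringsAsFactors = FALSE),
    lambda = lambda,
    lambda_mode = if (lambda_estimated) "ML" else "fixed",
    sigma2 = sigma2_ml,
    logLik = logL,
    r_squared = r2,
    F_stat = Fstat,
    model_p = model_p,
    aic = 2 * k_aic - 2 * logL,
    n = n, k = k, k_aic = k_aic,
    rss = rss, tss = tss,
    taxa = names(y),
    fitted = stats::setNames(fitted_resp, names(y)),
    residuals = stats::setNames(y - fitted_resp, names(y))
  ), class = "pgls_fit")
}

# Profile log-likelihood of lambda: only RSS and log|V| are needed.
gls_profile_loglik <- function(y, X, C, lambda) {
  n <- length(y)
  V <- apply_lambda(C, lambda)
  ch <- chol(V)
  wy <- backsolve(ch, y, transpose = TRUE)
  wX <- backsolve(ch, X, transpose = TRUE)
  beta <- qr.coef(qr(wX), wy)
  rss <- sum((wy - drop(wX %*% beta))^2)
  if (rss <= 0) return(Inf)
  -0.5 * (n * log(2 * pi) + n * log(rss / n) + 2 * sum(log(diag(ch))) + n)
}

#' Maximum-likelihood estimation of Pagel's lambda in a PGLS fit
#'
#' Maximizes the profile log-likelihood of lambda over \[0, 1\] by bounded
#' scalar optimization (tolerance 1e-8), evaluates both endpoints as well,
#' and keeps the maximum. Near-ties (within 1e-7 relative log-likelihood)
#' are broken toward lambda = 1; on a star phylogeny the likelihood is
#' constant in lambda and the fit returns lambda = 1.
#'
#' @inheritParams gls_fit_fixed_lambda
#' @param tol optimizer tolerance on lambda.
#' @return a `pgls_fit` (see [gls_fit_fixed_lambda()]) with
#'   `lambda_mode = "ML"`; lambda counts as a parameter in its AIC.
#' @export
profile_lambda_ml <- function(y, X, C, tol = 1e-8) {
  ll <- function(l) gls_profile_loglik(y, X, C, l)
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, 1)
  lv <- vapply(cand, ll, numeric(1))
  if (any(!is.finite(lv) & !is.infinite(lv)) || all(lv == -Inf))
    stop("non-finite log-likelihood while profiling lambda")
  best <- max(lv)
  tie_tol <- 1e-7 * (1 + abs(best))
  lambda_hat <- max(cand[lv >= best - tie_tol])
  gls_fit_fixed_lambda(y, X, C, lambda_hat, lambda_estimated = TRUE)
}

#' Fit a PGLS regression from a formula, data frame and tree
#'
#' Convenience wrapper: aligns the data to the tree's tip order, builds the
#' design matrix with an intercept, computes the Brownian covariance and
#' fits by [profile_lambda_ml()] (`lambda = "ML"`, the default) or
#' [gls_fit_fixed_lambda()].
#'
#' @param formula model formula; variables must be columns of `data`.
#' @param data data frame with a `clade_id` column matching the tree's tip
#'   labels (or rownames matching them).
#' @param tree rooted binary `phylo` whose tips are the analysis units.
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @return a `pgls_fit` with the call's `formula` attached.
#' @examples
#' set.seed(1)
#' tr <- ape::rphylo(20, 0.1, 0)
#' d <- data.frame(clade_id = tr$tip.label, x = rnorm(20))
#' d$y <- 1 + 2 * d$x + rnorm(20, sd = 0.1)
#' pgls(y ~ x, d, tr, lambda = 0)
#' @export
pgls <- function(formula, data, tree, lambda = "ML") {
  ids <- if ("clade_id" %in% names(data)) as.character(data$clade_id)
         else rownames(data)
  miss <- c(setdiff(tree$tip.label, ids), setdiff(ids, tree$tip.label))
  if (length(miss))
    stop("clade/tip mismatch between data and tree: ",
         paste(unique(miss), collapse = ", "))
  data <- data[match(tree$tip.label, ids), , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::setNames(stats::model.response(mf), tree$tip.label)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  rownames(X) <- tree$tip.label
  C <- vcv_matrix(tree)
  fit <- if (identical(lambda, "ML")) profile_lambda_ml(y, X, C)
         else gls_fit_fixed_lambda(y, X, C, lambda)
  fit$formula <- formula
  fit
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS fit")
  if (!is.null(x$formula)) cat(": ", deparse(x$formula), sep = "")
  cat("\n  n =", x$n,
      " lambda =", format(x$lambda, digits = digits),
      paste0("(", x$lambda_mode, ")"),
      " sigma2 =", format(x$sigma2, digits = digits), "\n")
  cat("  logLik =", format(x$logLik, digits = digits + 2),
      " AIC =", format(x$aic, digits = digits + 2),
      " r2 =", format(x$r_squared, digits = digits),
      " model P =", format.pval(x$model_p, digits = digits), "\n")
  co <- x$coefficients
  co[-1] <- lapply(co[-1], signif, digits = digits)
  print(co, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...)
  stats::setNames(object$coefficients$estimate, object$coefficients$term)

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$k_aic, nobs = object$n,
            class = "logLik")
}

#' Coefficient of determination of a PGLS fit
#'
#' 1 - RSS/TSS in the lambda-whitened space, with TSS from the
#' intercept-only GLS fit at the same lambda. For single-predictor models
#' this equals the squared Pearson correlation of whitened fitted versus
#' whitened observed values.
#'
#' @param fit a `pgls_fit`.
#' @return value in \[0, 1\].
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$r_squared
}

#' AIC of a PGLS fit
#'
#' AIC = 2k - 2 logL, with k counting the regression coefficients, the ML
#' residual variance, and Pagel's lambda when it was estimated.
#'
#' @param fit a `pgls_fit`.
#' @return the AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$aic
}

#' Rank PGLS fits by AIC
#'
#' @param fits named list of `pgls_fit` objects for the same response and
#'   taxa (taxa sets are checked).
#' @return data frame sorted by AIC ascending with a `delta_aic` column.
#' @export
model_compare <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "pgls_fit")))
  taxa0 <- sort(fits[[1L]]$taxa)
  for (f in fits)
    if (!identical(sort(f$taxa), taxa0))
      stop("fits were made on different taxa sets")
  labels <- names(fits)
  if (is.null(labels))
    labels <- vapply(fits, function(f)
      if (is.null(f$formula)) "<unnamed>" else deparse(f$formula), character(1))
  out <- data.frame(
    model = labels,
    k = vapply(fits, function(f) f$k_aic, numeric(1)),
    lambda = vapply(fits, function(f) f$lambda, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    model_p = vapply(fits, function(f) f$model_p, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1L]
  rownames(out) <- NULL
  out
}
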