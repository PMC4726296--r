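# Restricted log likelihood of y* ~ N(X* beta, sigma2 (lambda D + I)),
# with beta and sigma2 profiled out.  w = 1/(lambda d + 1) are the GLS
# weights; q = rank(X).  Constants are kept so the value matches a dense
# REML evaluation exactly.
.null_restricted_loglik <- function(lambda, ystar, Xstar, D, q) {
  n <- length(ystar)
  w <- 1 / (lambda * D + 1)
  XtWX <- crossprod(Xstar * w, Xstar)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  XtWy <- crossprod(Xstar, ystar * w)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ystar - Xstar %*% beta
  rss <- sum(w * r^2)
  sigma2 <- rss / (n - q)
  if (!is.finite(sigma2) || sigma2 <= 0) return(-Inf)
  -0.5 * ((n - q) * log(2 * pi * sigma2) + (n - q) +
            sum(log(lambda * D + 1)) + 2 * sum(log(diag(ch))))
}

#' Fit the polygenic null model by restricted maximum likelihood
#'
#' Estimates the polygenic-to-residual variance ratio
#' `lambda = sigma_g^2 / sigma^2` once, under the pure polygenic model
#' without any marker term. The ratio is then held fixed for every
#' single-marker fit in the scans (population parameters previously
#' defined, P3D). The 1-D profiled restricted likelihood is maximised by
#' Brent's method on `log10(lambda)` over `[-5, 5]`; estimates at a search
#' boundary are flagged with a warning, and a near-constant eigenvalue
#' spectrum (e.g. `K = I`), under which `lambda` is not identifiable, yields
#' `lambda_hat = 0` with a degeneracy warning.
#'
#' @param td a [transform_data()] result.
#' @param D kinship eigenvalues (or a `kinship_spectrum`).
#' @param interval search interval for `log10(lambda)`.
#' @return object of class `null_fit`: `lambda_hat`, `sigma_g2`, `sigma2`,
#'   `beta`, `restricted_loglik`, `boundary`, `degenerate`.
#' @export
fit_null_reml <- function(td, D, interval = c(-5, 5)) {
  stopifnot(inherits(td, "transformed_data"))
  if (inherits(D, "kinship_spectrum")) D <- D$D
  ystar <- td$y_star; Xstar <- td$X_star; q <- td$q; n <- td$n
  if (n <= q) stop("need n > rank(X) to fit the null model")
  degenerate <- (max(D) - min(D)) < 1e-10 * max(abs(D), 1)
  if (degenerate) {
    warning("kinship eigenvalues are constant; lambda is not identifiable, returning 0")
    lam <- 0
  } else {
    f <- function(l10) .null_restricted_loglik(10^l10, ystar, Xstar, D, q)
    probe <- vapply(seq(interval[1], interval[2], length.out = 21), f, 0)
    if (any(!is.finite(probe)) && all(!is.finite(probe)))
      stop("restricted likelihood non-finite across the search interval")
    opt <- stats::optimize(f, interval, maximum = TRUE, tol = 1e-8)
    # accept the boundary lambda = 0 when it dominates the interior optimum
    ll0 <- .null_restricted_loglik(0, ystar, Xstar, D, q)
    lam <- if (ll0 >= opt$objective) 0 else 10^opt$maximum
  }
  ll <- .null_restricted_loglik(lam, ystar, Xstar, D, q)
  if (!is.finite(ll)) stop("restricted likelihood non-finite at the optimum")
  w <- 1 / (lam * D + 1)
  XtWX <- crossprod(Xstar * w, Xstar)
  beta <- solve(XtWX, crossprod(Xstar, ystar * w))
  r <- drop(ystar - Xstar %*% beta)
  sigma2 <- sum(w * r^2) / (n - q)
  boundary <- !degenerate && lam > 0 &&
    (abs(log10(lam) - interval[1]) < 1e-6 || abs(log10(lam) - interval[2]) < 1e-6)
  if (boundary) warning("lambda estimate at the search boundary")
  structure(list(lambda_hat = lam, sigma_g2 = lam * sigma2, sigma2 = sigma2,
                 beta = drop(beta), restricted_loglik = ll,
                 boundary = boundary, degenerate = degenerate,
                 n = n, q = q),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat("Polygenic null model (REML)\n")
  cat(sprintf("  lambda = sigma_g2/sigma2 = %.6g\n", x$lambda_hat))
  cat(sprintf("  sigma_g2 = %.6g, sigma2 = %.6g\n", x$sigma_g2, x$sigma2))
  cat(sprintf("  restricted log-likelihood = %.6g\n", x$restricted_loglik))
  if (x$degenerate) cat("  (degenerate spectrum: lambda not identifiable)\n")
  if (x$boundary) cat("  (estimate at search boundary)\n")
  invisible(x)
}

#' Serialize / restore a null-model fit
#'
#' The fit is written as JSON so the (expensive) null estimation can be
#' reused across scans of the same phenotype.
#'
#' @param fit a `null_fit`.
#' @param path file path.
#' @return `read_null_fit` returns a `null_fit`.
#' @export
write_null_fit <- function(fit, path) {
  stopifnot(inherits(fit, "null_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_null_fit
#' @export
read_null_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$beta <- as.numeric(x$beta)
  structure(x, class = "null_fit")
}
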