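# ---- rank-one covariance algebra -------------------------------------------
#
# Per-marker covariance (up to sigma2): Sigma = lambda_k z* z*' + R with R the
# positive diagonal lambda_hat * D + 1 fixed from the null model.  All scan
# quantities reduce to three scalars computed once per marker under R alone:
#   c  = z' R^-1 z
#   a  = z' P z,   t0 = z' P y,   r0 = y' P y
# with P the REML projection under R.  Under Sigma(lambda) they update in
# closed form: s = a/(1+lambda a), t = t0/(1+lambda a),
# r = r0 - lambda t0^2/(1+lambda a).

#' Woodbury rank-one solver for the per-marker covariance
#'
#' For `Sigma = lambda_k * z z' + diag(R)` returns the action of
#' `Sigma^{-1}` on vectors and `log det Sigma` in O(n), via
#' `Sigma^{-1} v = R^{-1}v - lambda_k (R^{-1}z)(z'R^{-1}v) / (1 + lambda_k z'R^{-1}z)`
#' and `log det Sigma = sum(log R) + log(1 + lambda_k z'R^{-1}z)`.
#'
#' @param R positive diagonal of the base covariance (numeric vector).
#' @param z_star transformed marker vector.
#' @param lambda_k marker variance ratio, `>= 0`.
#' @return list with `solve(v)` (matrix- or vector-valued) and `logdet`.
#' @export
woodbury_solve <- function(R, z_star, lambda_k) {
  if (lambda_k < 0) stop("lambda_k must be nonnegative")
  if (any(R <= 0)) stop("R must be a positive diagonal")
  Riz <- z_star / R
  cc <- sum(z_star * Riz)
  denom <- 1 + lambda_k * cc
  if (denom <= 0) stop("1 + lambda_k z'R^-1 z <= 0: corrupted input")
  list(
    solve = function(v) {
      v <- as.matrix(v)
      v / R - (lambda_k / denom) * Riz %*% crossprod(Riz, v)
    },
    logdet = sum(log(R)) + log(denom)
  )
}

# scalar building blocks (a, t0, r0, c) for one marker under the base R
.marker_base <- function(td, z_star, R) {
  y <- td$y_star; X <- td$X_star
  Rin <- 1 / R
  RiX <- X * Rin
  XtRX <- crossprod(X, RiX)
  ch <- tryCatch(chol(XtRX), error = function(e)
    stop("singular X*' Sigma^-1 X*: collinear covariates"))
  solveX <- function(v) backsolve(ch, forwardsolve(t(ch), v))
  Py <- Rin * y - RiX %*% solveX(crossprod(RiX, y))
  Pz <- Rin * z_star - RiX %*% solveX(crossprod(RiX, z_star))
  list(cc = sum(z_star^2 * Rin),
       a = drop(crossprod(z_star, Pz)),
       t0 = drop(crossprod(z_star, Py)),
       r0 = drop(crossprod(y, Py)),
       ldR = sum(log(R)),
       ldX = 2 * sum(log(diag(ch))))
}

#' Profiled restricted log likelihood in the marker variance ratio
#'
#' REML log likelihood of the transformed data under
#' `Var(y*) = sigma2 (lambda_k z* z*' + R)` with the fixed effects and
#' `sigma2` profiled out analytically, leaving a function of the single
#' ratio `lambda_k`. Evaluated through the Woodbury rank-one identities;
#' equals the dense-matrix evaluation.
#'
#' @param lambda_k marker variance ratio `>= 0`.
#' @param td a [transform_data()] result.
#' @param z_star transformed marker genotype vector.
#' @param R positive diagonal `lambda_hat * D + 1`.
#' @return restricted log likelihood (including constants).
#' @export
profiled_restricted_loglik <- function(lambda_k, td, z_star, R) {
  if (lambda_k < 0) stop("lambda_k must be nonnegative")
  b <- .marker_base(td, z_star, R)
  nq <- td$n - td$q
  .profile_ll(lambda_k, b$a, b$t0, b$r0, b$cc, b$ldR, b$ldX, nq)
}

.profile_ll <- function(lambda, a, t0, r0, cc, ldR, ldX, nq) {
  one <- 1 + lambda * a
  r <- r0 - lambda * t0^2 / one
  if (r <= 0) return(-Inf)
  sigma2 <- r / nq
  ldSig <- ldR + log1p(lambda * cc)
  ldXSX <- ldX + log(one) - log1p(lambda * cc)
  -0.5 * (nq * log(2 * pi * sigma2) + nq + ldSig + ldXSX)
}

# first and second derivatives of the profiled restricted loglik in lambda
.profile_dll <- function(lambda, a, t0, r0, nq) {
  one <- 1 + lambda * a
  s <- a / one
  t <- t0 / one
  r <- r0 - lambda * t0^2 / one
  d1 <- -0.5 * (s - nq * t^2 / r)
  d2 <- -0.5 * (-s^2 + nq * (2 * s * t^2 / r - t^4 / r^2))
  c(d1, d2, r)
}

#' Newton estimate of a marker variance ratio
#'
#' Maximises the profiled restricted log likelihood in `lambda_k` by
#' Newton iteration on the analytic first and second derivatives, with
#' step-halving, projection to the boundary `lambda_k = 0` when the score
#' at zero is non-positive, and a grid-plus-Brent fallback if the iteration
#' fails to converge (the record is then flagged via
#' `attr(, "fallback")`).
#'
#' @inheritParams profiled_restricted_loglik
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the step.
#' @return estimated `lambda_k` (>= 0).
#' @export
newton_optimize_lambda_k <- function(td, z_star, R, max_iter = 50, tol = 1e-8) {
  b <- .marker_base(td, z_star, R)
  nq <- td$n - td$q
  if (b$a <= 0) return(0)
  lam <- .lambda_hat_closed(b$a, b$t0, b$r0, nq)
  if (lam == 0) return(0)
  ll <- function(l) .profile_ll(l, b$a, b$t0, b$r0, b$cc, b$ldR, b$ldX, nq)
  cur <- ll(lam)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    d <- .profile_dll(lam, b$a, b$t0, b$r0, nq)
    if (!is.finite(d[1]) || !is.finite(d[2]) || d[2] >= 0) break
    step <- -d[1] / d[2]
    new <- max(lam + step, 0)
    # halve the step until the likelihood does not decrease
    for (h in 1:30) {
      if (ll(new) >= cur - 1e-12) break
      step <- step / 2
      new <- max(lam + step, 0)
    }
    moved <- abs(new - lam) / (1 + abs(lam))
    lam <- new
    cur <- ll(lam)
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged && !isTRUE(abs(.profile_dll(lam, b$a, b$t0, b$r0, nq)[1]) < 1e-6)) {
    grid <- 10^seq(-6, 4, length.out = 2001)
    lls <- vapply(grid, ll, 0)
    i <- which.max(lls)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
    lam <- if (ll(0) >= opt$objective) 0 else opt$maximum
    attr(lam, "fallback") <- TRUE
  }
  if (ll(0) >= ll(lam)) lam <- 0
  lam
}

# closed-form stationary point of the profiled restricted loglik: with
# b = t0^2/a, the score vanishes at u = ((n-q)b - r0)/((n-q-1)b) where
# u = lambda a/(1 + lambda a); the boundary 0 applies when the score at 0
# is non-positive, i.e. (n-q) b <= r0.
.lambda_hat_closed <- function(a, t0, r0, nq) {
  if (a <= 0 || t0 == 0) return(0)
  b <- t0^2 / a
  if (nq * b <= r0) return(0)
  u <- (nq * b - r0) / ((nq - 1) * b)
  u / (a * (1 - u))
}

#' GLS estimates of fixed effects and residual variance
#'
#' Given the estimated marker ratio, computes
#' `beta = (X*' Sigma^-1 X*)^-1 X*' Sigma^-1 y*` and the REML residual
#' variance `sigma2 = y*' P y* / (n - q)`.
#'
#' @inheritParams profiled_restricted_loglik
#' @param lambda_k_hat estimated marker variance ratio.
#' @return list with `beta_hat`, `sigma2_hat`.
#' @export
estimate_beta_sigma2 <- function(lambda_k_hat, td, z_star, R) {
  ws <- woodbury_solve(R, z_star, lambda_k_hat)
  X <- td$X_star; y <- td$y_star
  SiX <- ws$solve(X)
  XtSX <- crossprod(X, SiX)
  if (rcond(XtSX) < 1e-12) stop("rank-deficient design")
  beta <- solve(XtSX, crossprod(SiX, y))
  resid <- y - X %*% beta
  sigma2 <- drop(crossprod(resid, ws$solve(resid))) / (td$n - td$q)
  list(beta_hat = drop(beta), sigma2_hat = sigma2)
}

#' BLUP of a random marker effect and its conditional variance
#'
#' `gamma_hat = lambda_k z*' Sigma^-1 (y* - X* beta)`, the conditional
#' expectation of the marker effect; the conditional variance is
#' `sigma2 (lambda_k - lambda_k^2 z*' P z*)` with `P` the REML projection
#' at `lambda_k`. At `lambda_k = 0` both are exactly zero (full
#' shrinkage); as `lambda_k` grows the BLUP approaches the fixed-effect
#' GLS estimate.
#'
#' @inheritParams estimate_beta_sigma2
#' @param beta_hat,sigma2_hat output of [estimate_beta_sigma2()].
#' @return list with `gamma_hat`, `var_gamma`.
#' @export
blup_gamma <- function(lambda_k_hat, td, z_star, R, beta_hat, sigma2_hat) {
  if (lambda_k_hat == 0) return(list(gamma_hat = 0, var_gamma = 0))
  ws <- woodbury_solve(R, z_star, lambda_k_hat)
  X <- td$X_star; y <- td$y_star
  resid <- y - X %*% beta_hat
  gamma <- lambda_k_hat * drop(crossprod(z_star, ws$solve(resid)))
  # z*' P z* at lambda_k via the projection under Sigma(lambda_k)
  SiX <- ws$solve(X)
  Siz <- ws$solve(z_star)
  XtSX <- crossprod(X, SiX)
  zPz <- drop(crossprod(z_star, Siz)) -
    drop(crossprod(crossprod(SiX, z_star), solve(XtSX, crossprod(SiX, z_star))))
  var_gamma <- sigma2_hat * (lambda_k_hat - lambda_k_hat^2 * zPz)
  list(gamma_hat = gamma, var_gamma = max(var_gamma, 0))
}

#' Wald test of a marker effect
#'
#' `W = gamma_hat^2 / var_gamma`, referred to the upper tail of a
#' chi-square distribution with one degree of freedom;
#' `LOD = W / (2 ln 10)`. A zero conditional variance with a zero effect
#' (full shrinkage at the boundary) gives `W = 0`, `p = 1`.
#'
#' @param gamma_hat effect estimate.
#' @param var_gamma conditional variance, `>= 0`.
#' @return list with `wald`, `p_value`, `lod`.
#' @export
wald_test <- function(gamma_hat, var_gamma) {
  if (var_gamma < 0) stop("var_gamma must be nonnegative")
  if (var_gamma == 0) {
    if (gamma_hat != 0) stop("inconsistent record: zero variance, nonzero effect")
    return(list(wald = 0, p_value = 1, lod = 0))
  }
  w <- gamma_hat^2 / var_gamma
  list(wald = w,
       p_value = stats::pchisq(w, df = 1, lower.tail = FALSE),
       lod = w / (2 * log(10)))
}

#' Effective number of independent markers
#'
#' Estimates the number of effectively independent tests from the
#' eigenvalues of the marker correlation matrix, summing
#' `I(eigenvalue >= 1) + (eigenvalue - floor(eigenvalue))` over
#' eigenvalues (Li-Ji style). For tractability on long genomes the
#' correlation matrix is evaluated in consecutive blocks (default 133
#' markers, within chromosome) and the block contributions are added; linkage
#' disequilibrium is local, so distant-pair correlations contribute little.
#' The strategy is pluggable via `method`, a function taking a coded marker
#' matrix block and returning its effective test count.
#'
#' @param G a [geno_matrix()] or coded numeric matrix.
#' @param block_size markers per correlation block.
#' @param method optional function overriding the Li-Ji block estimator.
#' @return `m_e`, with `1 <= m_e <=` number of polymorphic markers.
#' @export
effective_marker_number <- function(G, block_size = 133, method = NULL) {
  if (inherits(G, "geno_matrix")) {
    Z <- G$values
    chrom <- G$snp_map$chrom
  } else {
    Z <- as.matrix(G)
    chrom <- rep(1L, ncol(Z))
  }
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2L]]
  }
  poly <- !.monomorphic_cols(Z)
  if (!any(poly)) stop("no polymorphic marker")
  Z <- Z[, poly, drop = FALSE]
  chrom <- chrom[poly]
  liji <- function(block) {
    if (ncol(block) == 1L) return(1)
    ev <- eigen(stats::cor(block), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    sum((ev >= 1) + (ev - floor(ev)))
  }
  f <- if (is.null(method)) liji else method
  me <- 0
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    starts <- seq(1L, length(idx), by = block_size)
    for (s in starts) {
      cols <- idx[s:min(s + block_size - 1L, length(idx))]
      me <- me + f(Z[, cols, drop = FALSE])
    }
  }
  min(max(me, 1), ncol(Z))
}

# ---- vectorized scan engine ------------------------------------------------

# Base projection quantities for all markers at once.
.scan_base <- function(ystar, Xstar, Zstar, R) {
  Rin <- 1 / R
  RiX <- Xstar * Rin
  XtRX <- crossprod(Xstar, RiX)
  ch <- chol(XtRX)
  solveX <- function(v) backsolve(ch, forwardsolve(t(ch), v))
  Py <- drop(Rin * ystar - RiX %*% solveX(crossprod(RiX, ystar)))
  r0 <- sum(ystar * Py)
  B <- crossprod(RiX, Zstar)                      # q x m
  a <- colSums(Zstar * (Rin * Zstar)) - colSums(B * solveX(B))
  t0 <- drop(crossprod(Zstar, Py))
  list(a = a, t0 = t0, r0 = r0)
}

#' Single-locus random-SNP-effect genome scan
#'
#' Scans every polymorphic marker with the random-effect mixed linear
#' model: the polygenic-to-residual ratio is fixed at its null-model REML
#' estimate (P3D), and for each marker the profiled restricted likelihood
#' in the single ratio `lambda_k` is maximised (Newton step on the analytic
#' score; the stationary point has a closed form in the rank-one algebra).
#' Each record carries the BLUP effect, its conditional variance, the Wald
#' statistic, the chi-square(1) p-value and the LOD score. Significance uses
#' the modified Bonferroni threshold `alpha / m_e` with `m_e` the effective
#' number of markers.
#'
#' Markers that are monomorphic, or with minor allele frequency below
#' `1/(2n)` after imputation, are reported with `NA` statistics.
#'
#' @param y numeric phenotype vector (length n).
#' @param geno a [geno_matrix()].
#' @param X optional fixed-effect design (intercept added if absent).
#' @param K optional kinship matrix (computed with [kinship()] if `NULL`).
#' @param null_fit optional precomputed [fit_null_reml()] result.
#' @param alpha genome-wide significance level.
#' @param me_block block size for [effective_marker_number()].
#' @return object of class `rmlm` with elements `records` (one row per
#'   marker), `thresholds`, `null_fit`, `spectrum`, `call`.
#' @seealso [emma_scan()] for the fixed-effect baseline, [mrmlm()] for the
#'   multi-locus second stage.
#' @export
rmlm <- function(y, geno, X = NULL, K = NULL, null_fit = NULL,
                 alpha = 0.05, me_block = 133) {
  eng <- .scan_setup(y, geno, X, K, null_fit)
  nq <- eng$td$n - eng$td$q
  a <- eng$base$a; t0 <- eng$base$t0; r0 <- eng$base$r0
  # closed-form stationary point of the profiled restricted likelihood
  b <- ifelse(a > 0, t0^2 / a, 0)
  pos <- a > 0 & (nq * b > r0)
  u <- ifelse(pos, (nq * b - r0) / ((nq - 1) * b), 0)
  lambda_k <- ifelse(pos, u / (a * (1 - u)), 0)
  sigma2 <- ifelse(pos, (r0 - u * b) / nq, r0 / nq)
  gamma <- ifelse(a > 0, u * t0 / a, 0)
  varg <- ifelse(a > 0, sigma2 * u / a, 0)
  wald <- ifelse(varg > 0, gamma^2 / varg, 0)
  p <- stats::pchisq(wald, 1, lower.tail = FALSE)
  lod <- wald / (2 * log(10))
  rec <- .scan_records(eng, lambda_k = lambda_k, effect = gamma,
                       se = sqrt(varg), wald = wald, p = p, lod = lod)
  me <- effective_marker_number(eng$geno, block_size = me_block)
  thr <- list(m = sum(eng$tested), m_e = me, alpha = alpha,
              p_threshold = alpha / me)
  rec$significant <- !is.na(rec$p) & rec$p <= thr$p_threshold
  structure(list(records = rec, thresholds = thr, null_fit = eng$null_fit,
                 spectrum = eng$ks, effect_model = "random",
                 call = match.call()),
            class = "rmlm")
}

#' Fixed-effect (EMMA-style) baseline genome scan
#'
#' The fixed-SNP-effect version of the mixed linear model: the same
#' eigen-rotated covariance with the polygenic ratio fixed from the null
#' model, but each marker enters as a fixed effect tested by the exact GLS
#' F test (equivalently the squared t statistic). Significance uses the
#' plain Bonferroni threshold `alpha / m` over all tested markers — at one
#' million markers and `alpha = 0.05` the per-test threshold is 5e-8.
#'
#' @inheritParams rmlm
#' @return object of class `rmlm` (with `effect_model = "fixed"`).
#' @export
emma_scan <- function(y, geno, X = NULL, K = NULL, null_fit = NULL,
                      alpha = 0.05) {
  eng <- .scan_setup(y, geno, X, K, null_fit)
  nq <- eng$td$n - eng$td$q
  a <- eng$base$a; t0 <- eng$base$t0; r0 <- eng$base$r0
  gamma <- ifelse(a > 0, t0 / a, 0)
  rss <- r0 - ifelse(a > 0, t0^2 / a, 0)
  sigma2 <- rss / (nq - 1)
  varg <- ifelse(a > 0, sigma2 / a, 0)
  wald <- ifelse(varg > 0, gamma^2 / varg, 0)
  p <- stats::pf(wald, 1, nq - 1, lower.tail = FALSE)
  lod <- wald / (2 * log(10))
  rec <- .scan_records(eng, lambda_k = NA_real_, effect = gamma,
                       se = sqrt(varg), wald = wald, p = p, lod = lod)
  thr <- list(m = sum(eng$tested), m_e = sum(eng$tested), alpha = alpha,
              p_threshold = alpha / sum(eng$tested))
  rec$significant <- !is.na(rec$p) & rec$p <= thr$p_threshold
  structure(list(records = rec, thresholds = thr, null_fit = eng$null_fit,
                 spectrum = eng$ks, effect_model = "fixed",
                 call = match.call()),
            class = "rmlm")
}

# shared preparation: kinship, spectrum, transform, null fit, projections
.scan_setup <- function(y, geno, X, K, null_fit) {
  stopifnot(inherits(geno, "geno_matrix"))
  y <- as.numeric(y)
  if (length(y) != nrow(geno$values))
    stop("phenotype and genotype sample sizes differ")
  Z <- geno$values
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2L]]
  }
  n <- length(y)
  maf <- marker_maf(Z)
  tested <- !geno$monomorphic & maf >= 1 / (2 * n)
  if (is.null(K)) K <- kinship(geno)
  ks <- kinship_spectrum(K)
  td <- transform_data(y, X, ks$U)
  if (is.null(null_fit)) null_fit <- fit_null_reml(td, ks$D)
  R <- null_fit$lambda_hat * ks$D + 1
  Zstar <- crossprod(ks$U, Z[, tested, drop = FALSE])
  base <- .scan_base(td$y_star, td$X_star, Zstar, R)
  list(geno = geno, td = td, ks = ks, null_fit = null_fit, R = R,
       tested = tested, base = base, maf = maf)
}

# assemble the full record table, NA rows for untested markers
.scan_records <- function(eng, lambda_k, effect, se, wald, p, lod) {
  map <- eng$geno$snp_map
  m <- nrow(map)
  rec <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    maf = eng$maf,
                    lambda_k = NA_real_, effect = NA_real_, se = NA_real_,
                    wald = NA_real_, p = NA_real_, lod = NA_real_,
                    stringsAsFactors = FALSE)
  i <- which(eng$tested)
  rec$lambda_k[i] <- lambda_k
  rec$effect[i] <- effect
  rec$se[i] <- se
  rec$wald[i] <- wald
  rec$p[i] <- p
  rec$lod[i] <- lod
  rec
}
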