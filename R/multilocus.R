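#' Preselect markers from a single-locus scan
#'
#' Keeps markers with scan p-value below `p_select` (default 0.01), then
#' prunes positionally: walking the survivors in ascending p order (ties
#' broken by position, then marker id), any not-yet-selected marker within
#' `window_bp` of an already selected marker on the same chromosome is
#' eliminated, reducing collinearity among the selected set. The windows
#' are closed intervals `[pos - w, pos + w]`.
#'
#' @param records scan record table (from [rmlm()]`$records`).
#' @param p_select selection threshold on the per-marker p-value.
#' @param window_bp pruning half-window in base pairs (1 kb for simulated
#'   data, 20 kb for real data).
#' @return data.frame of selected records (possibly empty), ordered by
#'   ascending p, with the provenance columns of the scan.
#' @export
preselect_markers <- function(records, p_select = 0.01, window_bp = 1000) {
  cand <- records[!is.na(records$p) & records$p < p_select, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$p, cand$pos, cand$marker), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sel <- which(keep)
    clash <- any(cand$chrom[sel] == cand$chrom[i] &
                   abs(cand$pos[sel] - cand$pos[i]) <= window_bp)
    keep[i] <- !clash
  }
  cand[keep, , drop = FALSE]
}

#' Classify preselected markers as fixed or random
#'
#' Markers whose scan p-value passes the modified Bonferroni threshold
#' `alpha / m_e` undergo a single-marker likelihood ratio test (maximum
#' likelihood, marker as a fixed effect against the no-marker model, both
#' under the whitened polygenic covariance). A LOD score above 1.50 makes
#' the marker fixed in the multi-locus model; otherwise — and for all
#' markers that did not pass the gate — it is random.
#'
#' @param selected output of [preselect_markers()].
#' @param p_gate the modified Bonferroni threshold `alpha / m_e`.
#' @param td a [transform_data()] result.
#' @param Zstar_sel transformed genotype columns of the selected markers
#'   (n x s, in the order of `selected`).
#' @param R diagonal `lambda_hat * D + 1`.
#' @param lod_fixed LOD cutoff for fixed treatment (default 1.5).
#' @return `selected` with columns `gate_passed`, `lrt_lod`, `treated_as`.
#' @export
classify_fixed_random <- function(selected, p_gate, td, Zstar_sel, R,
                                  lod_fixed = 1.5) {
  s <- nrow(selected)
  selected$gate_passed <- !is.na(selected$p) & selected$p <= p_gate
  selected$lrt_lod <- NA_real_
  selected$treated_as <- "random"
  if (s == 0L) return(selected)
  ll0 <- .ml_loglik(td$y_star, td$X_star, R)
  for (i in which(selected$gate_passed)) {
    ll1 <- .ml_loglik(td$y_star, cbind(td$X_star, Zstar_sel[, i]), R)
    lrt <- max(2 * (ll1 - ll0), 0)
    selected$lrt_lod[i] <- lrt / (2 * log(10))
  }
  selected$treated_as[which(selected$lrt_lod > lod_fixed)] <- "fixed"
  selected
}

# ML log likelihood of y* ~ N(X b, sigma2 diag(R)) profiled in b, sigma2
.ml_loglik <- function(ystar, X, R) {
  n <- length(ystar)
  w <- 1 / R
  fit <- stats::lm.wfit(as.matrix(X), ystar, w)
  rss <- sum(w * fit$residuals^2)
  sigma2 <- rss / n
  -0.5 * (n * log(2 * pi * sigma2) + n + sum(log(R)))
}

#' EM empirical Bayes fit of the multi-locus model
#'
#' Jointly fits all surviving markers: fixed-classified markers augment the
#' design matrix, each random-classified marker `k` carries its own effect
#' variance `sigma_k^2` estimated by expectation-maximisation under a
#' scaled-inverse-chi-square prior `(tau, omega)`. With the default
#' `(tau, omega) = (-2, 0)` the prior is flat and the M-step is
#' `sigma_k^2 = E(gamma_k^2 | y)`. The E-step computes each effect's
#' posterior mean and variance given the current variances; fixed effects
#' are re-estimated by GLS and the residual variance is updated every
#' cycle. The polygenic background is retained through the whitening
#' weights `R = lambda_hat D + 1`. The marginal likelihood is
#' non-decreasing across iterations up to numerical tolerance.
#'
#' @param y response (already transformed; length n).
#' @param X fixed-effect design including any fixed-classified markers.
#' @param Z matrix of random-marker columns (n x t; may have 0 columns).
#' @param R whitening weights (diagonal covariance of the background), or
#'   `NULL` for i.i.d. residuals.
#' @param tau,omega prior hyperparameters of the effect variances.
#' @param max_iter,tol EM controls: stop when the largest parameter change
#'   is below `tol` or the marginal log likelihood gain falls below
#'   `1e-9 * (1 + |loglik|)`.
#' @param init optional warm start: list with any of `sigma_k2`, `sigma2`.
#' @return object of class `emeb_fit`: `beta` (fixed effects), `gamma`
#'   (posterior means), `gamma_var` (posterior variances), `sigma_k2`,
#'   `sigma2`, `loglik` (marginal), `iterations`, `converged`.
#' @export
emeb_fit <- function(y, X, Z, R = NULL, tau = -2, omega = 0,
                     max_iter = 1000, tol = 1e-6, init = NULL) {
  y <- as.numeric(y); X <- as.matrix(X)
  n <- length(y)
  if (is.null(Z)) Z <- matrix(0, n, 0)
  Z <- as.matrix(Z)
  if (!is.null(R)) {            # whiten the heteroscedastic background
    s <- 1 / sqrt(R)
    y <- y * s; X <- X * s
    if (ncol(Z)) Z <- Z * s
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design rank deficient")
  t <- ncol(Z)
  ZtZ <- if (t) crossprod(Z) else matrix(0, 0, 0)
  sigma_k2 <- rep(stats::var(y) / max(t, 1) / 2, t)
  fit0 <- stats::lm.fit(X, y)
  beta <- fit0$coefficients
  sigma2 <- max(sum(fit0$residuals^2) / n, 1e-10)
  if (!is.null(init)) {
    if (!is.null(init$sigma_k2)) {
      stopifnot(length(init$sigma_k2) == t)
      sigma_k2 <- pmax(init$sigma_k2, 0)
    }
    if (!is.null(init$sigma2) && init$sigma2 > 0) sigma2 <- init$sigma2
  }
  gamma <- rep(0, t); gvar <- rep(0, t)
  iter <- 0L; converged <- FALSE
  ll_prev <- -Inf
  marg_ll <- function(beta, sigma_k2, sigma2) {
    act <- which(sigma_k2 > 0)
    resb <- y - drop(X %*% beta)
    if (!length(act)) {
      ld <- n * log(sigma2)
      quad <- sum(resb^2) / sigma2
    } else {
      M <- diag(sigma2 / sigma_k2[act], length(act)) +
        ZtZ[act, act, drop = FALSE]
      ld <- n * log(sigma2) + determinant(M, logarithm = TRUE)$modulus +
        sum(log(sigma_k2[act])) - length(act) * log(sigma2)
      Za <- Z[, act, drop = FALSE]
      quad <- (sum(resb^2) -
                 sum(resb * (Za %*% solve(M, crossprod(Za, resb))))) / sigma2
    }
    -0.5 * (n * log(2 * pi) + as.numeric(ld) + quad)
  }
  polish_every <- 25L
  repeat {                       # EM, restarted after each boundary zeroing
  inner <- 0L
  repeat {
    iter <- iter + 1L
    inner <- inner + 1L
    old <- c(beta, sigma_k2, sigma2)
    act <- which(sigma_k2 > 0)
    # V^-1 through the t x t Woodbury form on the active set
    Vinv <- function(v) {
      v <- as.matrix(v)
      if (!length(act)) return(v / sigma2)
      M <- diag(sigma2 / sigma_k2[act], length(act)) +
        ZtZ[act, act, drop = FALSE]
      (v - Z[, act, drop = FALSE] %*%
         solve(M, crossprod(Z[, act, drop = FALSE], v))) / sigma2
    }
    ViX <- Vinv(X)
    beta <- drop(solve(crossprod(X, ViX), crossprod(ViX, y)))
    res <- y - drop(X %*% beta)
    Vir <- drop(Vinv(res))
    # E-step: posterior mean and full posterior covariance of the effects
    trace_term <- 0
    if (t) {
      gamma <- rep(0, t); gvar <- rep(0, t)
      if (length(act)) {
        Za <- Z[, act, drop = FALSE]
        sa <- sigma_k2[act]
        ga <- sa * drop(crossprod(Za, Vir))
        ZtViZ <- crossprod(Za, Vinv(Za))
        Ca <- diag(sa, length(act)) -
          (sa %o% sa) * ZtViZ          # S - S Z'V^-1 Z S
        Ca <- (Ca + t(Ca)) / 2
        gamma[act] <- ga
        gvar[act] <- pmax(diag(Ca), 0)
        trace_term <- sum(ZtZ[act, act] * Ca)
      }
      # M-step for the effect variances under the (tau, omega) prior
      sigma_k2 <- pmax((gamma^2 + gvar + omega) / (3 + tau), 0)
    }
    e <- res - if (t) drop(Z %*% gamma) else 0
    sigma2 <- max((sum(e^2) + trace_term) / n, 1e-12)
    # effect variances vanishing relative to the residual variance are
    # truncated to exactly zero (their likelihood contribution is below
    # numerical resolution and the raw EM tail decays only like 1/iter)
    if (t) sigma_k2[sigma_k2 < 1e-8 * sigma2] <- 0
    ll <- marg_ll(beta, sigma_k2, sigma2)
    if (max(abs(c(beta, sigma_k2, sigma2) - old)) < tol ||
        abs(ll - ll_prev) < 1e-9 * (1 + abs(ll))) { converged <- TRUE; break }
    ll_prev <- ll
    if (iter >= max_iter || inner >= polish_every) break
  }
  # boundary polish: the EM tail of a vanishing effect variance decays only
  # like 1/iteration; any active variance whose zeroing does not lower the
  # marginal likelihood is set exactly to zero and the EM continues
  act <- which(sigma_k2 > 0)
  if (length(act)) {
    ll_cur <- marg_ll(beta, sigma_k2, sigma2)
    gain <- vapply(act, function(k) {
      s2 <- sigma_k2; s2[k] <- 0
      marg_ll(beta, s2, sigma2) - ll_cur
    }, 0)
    j <- which.max(gain)
    if (gain[j] >= -1e-9) {      # one zeroing per round keeps ll monotone
      sigma_k2[act[j]] <- 0
      ll_prev <- -Inf; converged <- FALSE
    }
  }
  if (converged || iter >= max_iter) break
  }
  if (t) {
    gamma[sigma_k2 == 0] <- 0
    gvar[sigma_k2 == 0] <- 0
  }
  ll <- marg_ll(beta, sigma_k2, sigma2)
  if (!converged) warning("EM empirical Bayes did not converge in ",
                          max_iter, " iterations")
  structure(list(beta = beta, gamma = gamma, gamma_var = gvar,
                 sigma_k2 = sigma_k2, sigma2 = sigma2, loglik = ll,
                 iterations = iter, converged = converged,
                 tau = tau, omega = omega),
            class = "emeb_fit")
}

# marginal ML loglik of the EMEB model at given variance states (helper for
# monotonicity checks in tests)
#' @export
logLik.emeb_fit <- function(object, ...) {
  structure(object$loglik, df = NA_real_, class = "logLik")
}

#' Per-marker likelihood ratio tests in the multi-locus model
#'
#' Each marker is tested by removing it from the converged multi-locus
#' model (a random marker's variance forced to zero, a fixed marker
#' dropped from the design), re-converging all remaining parameters, and
#' comparing marginal likelihoods: `LRT = 2 (ll_full - ll_reduced)`,
#' `p` from chi-square(1), `LOD = LRT / (2 ln 10)`. Small negative LRT
#' values (within numerical tolerance of the EM) are clipped to zero.
#'
#' @param fit converged [emeb_fit()].
#' @param y,X,Z,R as passed to [emeb_fit()].
#' @param fixed_cols indices of `X` columns that are tested fixed markers
#'   (other columns — intercept, covariates — are not tested).
#' @param ... EM controls forwarded to the refits.
#' @return data.frame with one row per tested effect: `which` ("fixed" or
#'   "random"), `index`, `lrt`, `lod`, `p`.
#' @export
lrt_per_marker <- function(fit, y, X, Z, R = NULL, fixed_cols = integer(0), ...) {
  t <- if (is.null(Z)) 0L else ncol(as.matrix(Z))
  out <- data.frame(which = character(0), index = integer(0),
                    lrt = numeric(0), lod = numeric(0), p = numeric(0))
  ll_full <- fit$loglik
  test1 <- function(Xr, Zr, init, full_init) {
    red <- emeb_fit(y, Xr, Zr, R = R, tau = fit$tau, omega = fit$omega,
                    init = init, ...)
    if (red$loglik > ll_full) {
      # the reduced optimum dominates the achieved full fit: the full model
      # nests it, so re-converge the full fit from the reduced solution
      upg <- emeb_fit(y, X, Z, R = R, tau = fit$tau, omega = fit$omega,
                      init = full_init(red), ...)
      ll_full <<- max(ll_full, upg$loglik)
    }
    lrt <- 2 * (ll_full - red$loglik)
    if (lrt < -1e-6) stop("negative likelihood ratio beyond tolerance: refit inconsistency")
    max(lrt, 0)
  }
  for (j in fixed_cols) {
    lrt <- test1(as.matrix(X)[, -j, drop = FALSE], Z,
                 init = list(sigma_k2 = fit$sigma_k2, sigma2 = fit$sigma2),
                 full_init = function(red)
                   list(sigma_k2 = red$sigma_k2, sigma2 = red$sigma2))
    out <- rbind(out, data.frame(which = "fixed", index = j, lrt = lrt,
                                 lod = lrt / (2 * log(10)),
                                 p = stats::pchisq(lrt, 1, lower.tail = FALSE)))
  }
  for (k in seq_len(t)) {
    lrt <- if (fit$sigma_k2[k] <= 1e-12) 0 else
      test1(X, as.matrix(Z)[, -k, drop = FALSE],
            init = list(sigma_k2 = fit$sigma_k2[-k], sigma2 = fit$sigma2),
            full_init = function(red)
              list(sigma_k2 = append(red$sigma_k2, 0, after = k - 1),
                   sigma2 = red$sigma2))
    out <- rbind(out, data.frame(which = "random", index = k, lrt = lrt,
                                 lod = lrt / (2 * log(10)),
                                 p = stats::pchisq(lrt, 1, lower.tail = FALSE)))
  }
  out
}

#' Declare quantitative trait nucleotides from a multi-locus fit
#'
#' Markers with `LOD >= lod_threshold` (default 3.0, equivalent to a
#' per-marker p-value of about 0.0002 under chi-square(1)) are declared
#' QTNs. The comparison is inclusive at the threshold. Each call reports
#' the effect and the proportion of phenotypic variance explained,
#' `r2 = var(z_k * gamma_k) / var(y)` on the original genotype coding.
#'
#' @param fit_table per-marker table with columns `marker`, `chrom`, `pos`,
#'   `treated_as`, `effect`, `lrt`, `lod`, `p`.
#' @param y original phenotype vector.
#' @param Z_orig original coded genotype columns of the markers in
#'   `fit_table` (same order).
#' @param lod_threshold LOD cutoff.
#' @return data.frame of declared QTNs with an `r2` column.
#' @export
final_calls <- function(fit_table, y, Z_orig, lod_threshold = 3) {
  if (nrow(fit_table) == 0L) {
    fit_table$r2 <- numeric(0)
    return(fit_table)
  }
  keep <- !is.na(fit_table$lod) & fit_table$lod >= lod_threshold
  calls <- fit_table[keep, , drop = FALSE]
  Z_orig <- as.matrix(Z_orig)
  vy <- stats::var(as.numeric(y))
  calls$r2 <- vapply(seq_len(nrow(calls)), function(i) {
    j <- which(keep)[i]
    stats::var(Z_orig[, j]) * calls$effect[i]^2 / vy
  }, 0)
  calls
}

#' Goodness of fit of the declared QTN set
#'
#' Ordinary multiple linear regression of the phenotype on the called
#' marker columns (intercept-only when no QTN is called), reporting the
#' negative log likelihood and `BIC = -2 loglik + k log n` with `k`
#' counting the regression coefficients plus the residual variance.
#' Collinear columns are dropped with a warning; a residual variance below
#' `1e-8 * var(y)` (perfect fit) is floored there.
#'
#' @param y phenotype vector.
#' @param Z_called coded genotype columns of the called markers (or `NULL`).
#' @return list with `neg_loglik`, `bic`, `k`, `dropped` (names of dropped
#'   columns).
#' @export
bic_goodness_of_fit <- function(y, Z_called = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(Z_called) || NCOL(Z_called) == 0L) {
    fit <- stats::lm(y ~ 1)
  } else {
    Z_called <- as.matrix(Z_called)
    fit <- stats::lm(y ~ Z_called)
  }
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped))
    warning("dropping collinear called markers: ", paste(dropped, collapse = ", "))
  p <- sum(!is.na(cf))
  rss <- sum(stats::residuals(fit)^2)
  floor_v <- 1e-8 * max(stats::var(y), 1e-300)
  sigma2 <- max(rss / n, floor_v)
  ll <- -0.5 * n * (log(2 * pi * sigma2) + rss / (n * sigma2))
  k <- p + 1                               # coefficients + residual variance
  list(neg_loglik = -ll, bic = -2 * ll + k * log(n), k = k, dropped = dropped)
}

#' Two-stage multi-locus random-SNP-effect GWAS
#'
#' Runs the full pipeline: (1) single-locus random-effect scan ([rmlm()]);
#' (2) preselection of markers with scan `p < p_select` and positional
#' pruning within `window_bp`; (3) classification of survivors as fixed
#' (single-marker LRT LOD > 1.5 among those passing `alpha / m_e`) or
#' random; (4) joint EM empirical Bayes fit of all survivors with the
#' polygenic background retained at the null-model ratio; (5) per-marker
#' likelihood ratio tests with full refits; (6) QTN declaration at
#' `LOD >= lod_threshold` and a BIC goodness-of-fit of the called set.
#' Being multi-locus and shrinkage-based, the final test needs no multiple
#' test correction; the LOD 3 criterion corresponds to p = 0.0002.
#'
#' @inheritParams rmlm
#' @param p_select stage-1 selection threshold (default 0.01).
#' @param window_bp pruning half-window in bp (1 kb simulated, 20 kb real).
#' @param lod_threshold final QTN declaration cutoff (default 3).
#' @param keep_polygenic retain the polygenic covariance (at the null-model
#'   ratio) in the second stage; `FALSE` fits i.i.d. residuals.
#' @param scan optional precomputed [rmlm()] object to reuse.
#' @param ... EM controls passed to [emeb_fit()].
#' @return object of class `mrmlm`: `scan`, `selected`, `fit_table` (all
#'   surviving markers with effects and tests), `calls` (declared QTNs),
#'   `bic`, `emeb`, `thresholds`, `call`.
#' @export
mrmlm <- function(y, geno, X = NULL, K = NULL, null_fit = NULL,
                  p_select = 0.01, window_bp = 1000, lod_threshold = 3,
                  alpha = 0.05, me_block = 133, keep_polygenic = TRUE,
                  scan = NULL, ...) {
  if (is.null(scan))
    scan <- rmlm(y, geno, X = X, K = K, null_fit = null_fit, alpha = alpha,
                 me_block = me_block)
  sel <- preselect_markers(scan$records, p_select = p_select,
                           window_bp = window_bp)
  thr <- c(scan$thresholds,
           list(p_select = p_select, window_bp = window_bp,
                lod_threshold = lod_threshold, lod_fixed = 1.5))
  empty_fit <- data.frame(marker = character(0), chrom = character(0),
                          pos = numeric(0), treated_as = character(0),
                          effect = numeric(0), lrt = numeric(0),
                          lod = numeric(0), p = numeric(0))
  if (nrow(sel) == 0L) {
    calls <- cbind(empty_fit, r2 = numeric(0))
    return(structure(list(scan = scan, selected = sel, fit_table = empty_fit,
                          calls = calls,
                          bic = bic_goodness_of_fit(y, NULL), emeb = NULL,
                          thresholds = thr, y = as.numeric(y),
                          call = match.call()),
                     class = "mrmlm"))
  }
  ks <- scan$spectrum
  td <- transform_data(y, X, ks$U)
  R <- if (keep_polygenic) scan$null_fit$lambda_hat * ks$D + 1 else
    rep(1, td$n)
  Zo <- geno$values[, match(sel$marker, geno$snp_map$marker), drop = FALSE]
  if (anyNA(Zo)) {
    mu <- colMeans(Zo, na.rm = TRUE)
    idx <- which(is.na(Zo), arr.ind = TRUE)
    Zo[idx] <- mu[idx[, 2L]]
  }
  Zstar <- crossprod(ks$U, Zo)
  sel <- classify_fixed_random(sel, p_gate = scan$thresholds$p_threshold,
                               td = td, Zstar_sel = Zstar, R = R)
  fx <- which(sel$treated_as == "fixed")
  rd <- which(sel$treated_as == "random")
  Xaug <- cbind(td$X_star, Zstar[, fx, drop = FALSE])
  Zr <- Zstar[, rd, drop = FALSE]
  fit <- emeb_fit(td$y_star, Xaug, Zr, R = R, ...)
  q0 <- ncol(td$X_star)
  lrt <- lrt_per_marker(fit, td$y_star, Xaug, Zr, R = R,
                        fixed_cols = q0 + seq_along(fx), ...)
  effects <- numeric(nrow(sel))
  effects[fx] <- fit$beta[q0 + seq_along(fx)]
  effects[rd] <- fit$gamma
  tests <- matrix(NA_real_, nrow(sel), 3)
  lf <- lrt[lrt$which == "fixed", , drop = FALSE]
  tests[fx[lf$index - q0], ] <- as.matrix(lf[, c("lrt", "lod", "p")])
  lr <- lrt[lrt$which == "random", , drop = FALSE]
  tests[rd[lr$index], ] <- as.matrix(lr[, c("lrt", "lod", "p")])
  fit_table <- data.frame(marker = sel$marker, chrom = sel$chrom,
                          pos = sel$pos, treated_as = sel$treated_as,
                          effect = effects, lrt = tests[, 1],
                          lod = tests[, 2], p = tests[, 3],
                          stringsAsFactors = FALSE)
  calls <- final_calls(fit_table, y, Zo, lod_threshold = lod_threshold)
  Zcalled <- if (nrow(calls)) Zo[, match(calls$marker, sel$marker), drop = FALSE] else NULL
  bic <- bic_goodness_of_fit(y, Zcalled)
  structure(list(scan = scan, selected = sel, fit_table = fit_table,
                 calls = calls, bic = bic, emeb = fit, thresholds = thr,
                 y = as.numeric(y), call = match.call()),
            class = "mrmlm")
}
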