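test_that("the Woodbury solver reproduces dense inverses and determinants", {
  set.seed(20)
  for (s in 1:4) {
    R <- rexp(4) + 0.5
    z <- rnorm(4)
    lam <- c(0, 0.3, 2, 10)[s]
    ws <- woodbury_solve(R, z, lam)
    Sigma <- dense_sigma(lam, z, R)
    V <- matrix(rnorm(8), 4)
    expect_lt(max(abs(ws$solve(V) - solve(Sigma, V))), 1e-10)
    expect_equal(ws$logdet, as.numeric(determinant(Sigma)$modulus),
                 tolerance = 1e-10)
  }
  # lambda 0 and a null marker both reduce to the diagonal case
  R <- c(1, 2, 3); z0 <- rep(0, 3)
  ws <- woodbury_solve(R, z0, 5)
  expect_equal(ws$logdet, sum(log(R)))
  expect_equal(drop(ws$solve(c(1, 1, 1))), 1 / R)
  expect_error(woodbury_solve(c(1, -1), c(1, 1), 1), "positive")
  expect_error(woodbury_solve(c(1, 1), c(1, 1), -1), "nonnegative")
})

test_that("the profiled restricted likelihood matches brute-force dense REML", {
  ti <- toy_instance(6, 1, seed = 21, q_covar = 1)
  td <- transform_data(ti$y, ti$X, diag(6))
  z <- ti$Z[, 1]
  for (lam in c(0, 0.2, 1, 7)) {
    expect_equal(profiled_restricted_loglik(lam, td, z, ti$R),
                 dense_reml_loglik(lam, ti$y, ti$X, z, ti$R),
                 tolerance = 1e-8)
  }
  # at lambda_k = 0 the value equals the null-model restricted likelihood
  ll0 <- rmlmgwas:::.null_restricted_loglik(0.5, td$y_star, td$X_star, ti$D,
                                            td$q)
  expect_equal(profiled_restricted_loglik(0, td, z, 0.5 * ti$D + 1), ll0,
               tolerance = 1e-10)
})

test_that("a strong marker effect lifts the likelihood away from lambda_k = 0", {
  set.seed(22)
  n <- 80
  z <- sample(c(-1, 0, 1), n, TRUE, prob = c(0.49, 0.42, 0.09))
  y <- 10 + 2.5 * z + rnorm(n, sd = 2)
  td <- transform_data(y, NULL, diag(n))
  R <- rep(1, n)
  expect_gt(profiled_restricted_loglik(1, td, z, R),
            profiled_restricted_loglik(0, td, z, R))
})

test_that("the Newton estimate agrees with a dense grid search", {
  for (s in 1:6) {
    ti <- toy_instance(12, 1, seed = 30 + s)
    td <- transform_data(ti$y + ti$Z[, 1] * (s / 3), ti$X, diag(12))
    lam <- newton_optimize_lambda_k(td, ti$Z[, 1], ti$R)
    grid <- 10^seq(-6, 4, length.out = 2001)
    ll <- vapply(grid, function(l)
      profiled_restricted_loglik(l, td, ti$Z[, 1], ti$R), 0)
    best <- grid[which.max(ll)]
    ll_at <- function(l) profiled_restricted_loglik(l, td, ti$Z[, 1], ti$R)
    if (lam == 0) {
      expect_lte(max(ll) - ll_at(0), 1e-6)
    } else {
      expect_lt(abs(log10(lam) - log10(best)), 1e-2)
      expect_gte(ll_at(lam), max(ll) - 1e-8)
    }
  }
})

test_that("the marker ratio lands on the boundary for null markers and off it for strong ones", {
  set.seed(40)
  n <- 199
  null_zero <- replicate(200, {
    z <- stats::rbinom(n, 1, 0.3) + stats::rbinom(n, 1, 0.3) - 1
    y <- rnorm(n)
    td <- transform_data(y, NULL, diag(n))
    newton_optimize_lambda_k(td, z, rep(1, n)) == 0
  })
  expect_gt(mean(null_zero), 0.5)

  # h2 = 0.15 at n = 199: effect sqrt(0.15/0.85 * 10 / 0.42) on resid sd sqrt(10)
  a <- sqrt(0.15 / 0.85 * 10 / 0.42)
  strong_pos <- replicate(200, {
    z <- stats::rbinom(n, 1, 0.3) + stats::rbinom(n, 1, 0.3) - 1
    y <- a * z + rnorm(n, sd = sqrt(10))
    td <- transform_data(y, NULL, diag(n))
    newton_optimize_lambda_k(td, z, rep(1, n)) > 0
  })
  expect_gte(mean(strong_pos), 0.95)
})

test_that("GLS estimates and the BLUP match dense oracles and their limits", {
  ti <- toy_instance(6, 1, seed = 50)
  z <- ti$Z[, 1]
  # lambda 0 with identity weights is ordinary least squares
  td <- transform_data(ti$y, ti$X, diag(6))
  est <- estimate_beta_sigma2(0, td, z, rep(1, 6))
  ols <- lm.fit(ti$X, ti$y)
  expect_equal(est$beta_hat, unname(ols$coefficients), tolerance = 1e-10)

  # intercept-only toy against the dense GLS oracle
  tdi <- transform_data(ti$y, cbind(rep(1, 6)), diag(6))
  for (lam in c(0.4, 3)) {
    est <- estimate_beta_sigma2(lam, tdi, z, ti$R)
    dg <- dense_gls(ti$y, cbind(rep(1, 6)), dense_sigma(lam, z, ti$R))
    expect_equal(est$beta_hat, dg$beta, tolerance = 1e-8)
    expect_equal(est$sigma2_hat, dg$sigma2, tolerance = 1e-8)
    # scale equivariance
    td2 <- transform_data(2 * ti$y, cbind(rep(1, 6)), diag(6))
    est2 <- estimate_beta_sigma2(lam, td2, z, ti$R)
    expect_equal(est2$beta_hat, 2 * est$beta_hat, tolerance = 1e-10)
    expect_equal(est2$sigma2_hat, 4 * est$sigma2_hat, tolerance = 1e-10)

    bl <- blup_gamma(lam, tdi, z, ti$R, est$beta_hat, est$sigma2_hat)
    or <- dense_blup(lam, ti$y, cbind(rep(1, 6)), z, ti$R)
    expect_equal(bl$gamma_hat, or$gamma, tolerance = 1e-8)
    expect_equal(bl$var_gamma, or$var_gamma, tolerance = 1e-8)
  }

  # full shrinkage at the boundary; fixed-effect GLS in the diffuse limit
  expect_equal(blup_gamma(0, tdi, z, ti$R, 0, 1),
               list(gamma_hat = 0, var_gamma = 0))
  est <- estimate_beta_sigma2(1e6, tdi, z, ti$R)
  bl <- blup_gamma(1e6, tdi, z, ti$R, est$beta_hat, est$sigma2_hat)
  base <- rmlmgwas:::.marker_base(tdi, z, ti$R)
  expect_equal(bl$gamma_hat, base$t0 / base$a, tolerance = 1e-4)
})

test_that("the Wald test maps effects to chi-square(1) p-values and LOD", {
  expect_equal(wald_test(0, 0), list(wald = 0, p_value = 1, lod = 0))
  w <- wald_test(sqrt(6 * log(10) * 2), 2)     # LOD exactly 3
  expect_equal(w$lod, 3, tolerance = 1e-12)
  expect_equal(w$p_value, 2e-4, tolerance = 0.05)   # printed as 0.0002
  w <- wald_test(sqrt(3.841459), 1)
  expect_equal(w$p_value, 0.05, tolerance = 1e-6)
  expect_error(wald_test(1, 0), "inconsistent")
  expect_error(wald_test(1, -1), "nonnegative")
})

test_that("the effective marker number tracks independence and redundancy", {
  set.seed(60)
  n <- 600; m <- 40
  Z <- matrix(rbinom(n * m, 1, 0.4) + rbinom(n * m, 1, 0.4) - 1, n, m)
  me <- effective_marker_number(Z)
  expect_gt(me / m, 0.9)
  expect_lte(me, m)

  # a duplicated block collapses to about one effective test
  Zd <- cbind(Z, Z[, 1], Z[, 1], Z[, 1])
  me_d <- effective_marker_number(Zd)
  expect_lt(abs(me_d - me), 1.5)

  expect_equal(effective_marker_number(Z[, 1, drop = FALSE]), 1)

  # order and orientation invariance (single block)
  perm <- sample(m)
  expect_equal(effective_marker_number(Z[, perm]), me, tolerance = 1e-8)
  Zf <- Z; Zf[, 5] <- -Zf[, 5]
  expect_equal(effective_marker_number(Zf), me, tolerance = 1e-8)
})

test_that("the genome scan ranks a strong QTN first and obeys threshold nesting", {
  set.seed(61)
  cfg <- sim_config(n = 150, m = 300, rho = 0,
                    qtn_h2 = c(0, 0, 0, 0.3, 0, 0))
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  sc <- rmlm(ph$y, sim$geno)
  expect_equal(nrow(sc$records), 300)
  expect_true(all(sc$records$lambda_k >= 0, na.rm = TRUE))
  expect_true(all(sc$records$p > 0 & sc$records$p <= 1, na.rm = TRUE))
  # the single strong simulated QTN carries the smallest p-value
  expect_equal(sc$records$marker[which.min(sc$records$p)],
               ph$truth$qtn_marker[4])
  # deterministic given inputs
  sc2 <- rmlm(ph$y, sim$geno)
  expect_identical(sc$records, sc2$records)

  em <- emma_scan(ph$y, sim$geno, null_fit = sc$null_fit)
  expect_lte(em$thresholds$p_threshold, sc$thresholds$p_threshold)
  # markers significant under 0.05/m are a subset of those under 0.05/m_e
  sig_m <- !is.na(sc$records$p) & sc$records$p <= em$thresholds$p_threshold
  sig_me <- !is.na(sc$records$p) & sc$records$p <= sc$thresholds$p_threshold
  expect_true(all(!sig_m | sig_me))

  expect_error(rmlm(ph$y[-1], sim$geno), "sample sizes differ")
})

test_that("monomorphic and ultra-rare markers are reported untested", {
  set.seed(62)
  Z <- cbind(matrix(sample(c(-1, 0, 1), 40 * 5, TRUE), 40, 5), 1)
  map <- data.frame(marker = paste0("m", 1:6), chrom = 1, pos = 1:6 * 1000)
  g <- geno_matrix(Z, map)
  y <- rnorm(40)
  sc <- rmlm(y, g)
  expect_true(is.na(sc$records$p[6]))
  expect_equal(sc$thresholds$m, 5)
})

test_that("permuted phenotypes stay below the modified Bonferroni threshold", {
  set.seed(63)
  cfg <- sim_config(n = 120, m = 250, rho = 0.5)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  K <- kinship(sim$geno)
  hits <- replicate(20, {
    sc <- rmlm(sample(ph$y), sim$geno, K = K)
    any(sc$records$significant, na.rm = TRUE)
  })
  expect_gte(mean(!hits), 0.95)
})

test_that("the fixed-effect scan matches a dense GLS oracle and plain Bonferroni", {
  ti <- toy_instance(20, 4, seed = 64)
  y <- ti$y + ti$Z[, 2]
  g <- ti$geno
  K <- kinship(g)
  sc <- emma_scan(y, g, K = K)
  ks <- kinship_spectrum(K)
  nf <- sc$null_fit
  Sigma0 <- nf$lambda_hat * ks$K + diag(20)
  for (j in 1:4) {
    Xj <- cbind(1, ti$Z[, j])
    dg <- dense_gls(y, Xj, Sigma0)
    expect_equal(sc$records$effect[j], dg$beta[2], tolerance = 1e-8)
  }
  expect_equal(sc$thresholds$p_threshold, 0.05 / 4)
  # with lambda = 0 the scan reduces to ordinary regression
  nf0 <- nf; nf0$lambda_hat <- 0
  sc0 <- emma_scan(y, g, K = K, null_fit = nf0)
  for (j in 1:2) {
    f <- summary(lm(y ~ ti$Z[, j]))
    expect_equal(sc0$records$wald[j], f$coefficients[2, "t value"]^2,
                 tolerance = 1e-8)
  }
})

test_that("random-effect BLUPs never exceed the fixed-effect estimates in magnitude", {
  for (s in 1:4) {
    set.seed(70 + s)
    cfg <- sim_config(n = 80, m = 120, rho = 0.4)
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(sim, cfg)
    K <- kinship(sim$geno)
    sc <- rmlm(ph$y, sim$geno, K = K)
    em <- emma_scan(ph$y, sim$geno, K = K, null_fit = sc$null_fit)
    ok <- !is.na(sc$records$effect) & !is.na(em$records$effect)
    expect_true(all(abs(sc$records$effect[ok]) <=
                      abs(em$records$effect[ok]) + 1e-10))
  }
})

test_that("the vectorised scan agrees with the scalar Woodbury path", {
  set.seed(80)
  cfg <- sim_config(n = 40, m = 30, rho = 0.2)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  K <- kinship(sim$geno)
  ks <- kinship_spectrum(K)
  td <- transform_data(ph$y, NULL, ks$U)
  nf <- fit_null_reml(td, ks$D)
  R <- nf$lambda_hat * ks$D + 1
  sc <- rmlm(ph$y, sim$geno, K = K, null_fit = nf)
  for (j in c(1, 7, 19)) {
    if (is.na(sc$records$p[j])) next
    z <- drop(crossprod(ks$U, sim$geno$values[, j]))
    lam <- newton_optimize_lambda_k(td, z, R)
    expect_equal(sc$records$lambda_k[j], as.numeric(lam), tolerance = 1e-6)
    est <- estimate_beta_sigma2(lam, td, z, R)
    bl <- blup_gamma(lam, td, z, R, est$beta_hat, est$sigma2_hat)
    expect_equal(sc$records$effect[j], bl$gamma_hat, tolerance = 1e-6)
    wt <- wald_test(bl$gamma_hat, bl$var_gamma)
    expect_equal(sc$records$p[j], wt$p_value, tolerance = 1e-6)
  }
})

test_that("fixed-scan p-values are calibrated and random-scan p-values conservative", {
  set.seed(81)
  n <- 100; m <- 200; reps <- 100
  cfg <- sim_config(n = n, m = m, rho = 0)
  p_r <- c(); p_f <- c()
  for (r in seq_len(reps)) {
    sim <- simulate_genotypes(cfg)
    y <- rnorm(n, 10, sqrt(10))       # no genetic signal at all
    K <- kinship(sim$geno)
    ks <- kinship_spectrum(K)
    td <- transform_data(y, NULL, ks$U)
    nf <- fit_null_reml(td, ks$D)
    p_r <- c(p_r, rmlm(y, sim$geno, K = K, null_fit = nf)$records$p)
    p_f <- c(p_f, emma_scan(y, sim$geno, K = K, null_fit = nf)$records$p)
  }
  for (alpha in c(0.01, 0.05)) {
    N <- sum(!is.na(p_f))
    cnt_f <- sum(p_f <= alpha, na.rm = TRUE)
    # the marker-estimated kinship absorbs a sliver of each tested marker
    # (proximal contamination), so allow mild conservatism below the
    # binomial band but no inflation above it
    expect_gte(cnt_f, 0.85 * N * alpha)
    expect_lte(cnt_f, qbinom(0.995, N, alpha))
    # shrinkage makes the random-effect test conservative, never inflated
    cnt_r <- sum(p_r <= alpha, na.rm = TRUE)
    expect_lte(cnt_r, qbinom(0.995, N, alpha))
  }
})
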