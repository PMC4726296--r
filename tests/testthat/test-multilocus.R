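mk_records <- function(p, pos, chrom = 1) {
  data.frame(marker = paste0("m", seq_along(p)), chrom = chrom, pos = pos,
             maf = 0.3, lambda_k = 0.1, effect = 0.1, se = 0.1, wald = 1,
             p = p, lod = 1, stringsAsFactors = FALSE)
}

test_that("preselection keeps sub-threshold markers and prunes within the window", {
  rec <- mk_records(c(1e-5, 1e-3), pos = c(100, 500))
  sel <- preselect_markers(rec, p_select = 0.01, window_bp = 1000)
  expect_equal(sel$marker, "m1")                 # 500 bp apart: pruned

  rec <- mk_records(c(1e-3, 1e-4), pos = c(1000, 4000))
  sel <- preselect_markers(rec, window_bp = 1000)
  expect_setequal(sel$marker, c("m1", "m2"))     # 3 kb apart: both kept

  rec <- mk_records(c(0.02, 0.5), pos = c(100, 500))
  expect_equal(nrow(preselect_markers(rec)), 0L)

  # same positions on different chromosomes never clash
  rec <- mk_records(c(1e-5, 1e-4), pos = c(100, 200), chrom = c(1, 2))
  expect_equal(nrow(preselect_markers(rec, window_bp = 1000)), 2L)
})

test_that("fixed-vs-random classification follows the gate and the LOD 1.5 rule", {
  set.seed(90)
  n <- 120
  z1 <- rbinom(n, 2, 0.4) - 1        # strong marker
  z2 <- rbinom(n, 2, 0.4) - 1        # pure noise marker
  y <- 10 + 1.5 * z1 + rnorm(n)
  U <- diag(n); td <- transform_data(y, NULL, U)
  R <- rep(1, n)
  Zsel <- cbind(z1, z2)
  sel <- mk_records(c(1e-8, 1e-9), pos = c(1000, 50000))

  out <- classify_fixed_random(sel, p_gate = 1e-4, td, Zsel, R)
  expect_equal(out$treated_as, c("fixed", "random"))  # z2 LRT is ~0
  expect_gt(out$lrt_lod[1], 1.5)
  expect_lt(out$lrt_lod[2], 1.5)

  # a marker that misses the gate stays random no matter how strong
  sel$p <- c(0.009, 1e-9)
  out <- classify_fixed_random(sel, p_gate = 1e-4, td, Zsel, R)
  expect_equal(out$treated_as[1], "random")
  expect_false(out$gate_passed[1])
})

test_that("the EM empirical Bayes fit shrinks noise and keeps strong signals", {
  set.seed(91)
  n <- 100
  z <- rbinom(n, 2, 0.3) - 1
  y <- 3 * z + rnorm(n)
  X <- cbind(rep(1, n))
  fit <- emeb_fit(y, X, cbind(z))
  ols <- coef(lm(y ~ z))[2]
  expect_lt(abs(fit$gamma - ols) / abs(ols), 0.1)   # low-shrinkage limit

  # a null marker among 20 is shrunk to (near) zero
  eff <- replicate(100, {
    Z <- matrix(rbinom(n * 20, 2, 0.3) - 1, n, 20)
    yy <- 10 + 2 * Z[, 1] + rnorm(n)
    f <- emeb_fit(yy, X, Z)
    f$gamma[2]
  })
  expect_lt(median(abs(eff)), 0.05)

  # zero random markers with one fixed reduces to GLS
  fitg <- emeb_fit(y, cbind(1, z), matrix(0, n, 0))
  expect_equal(unname(fitg$beta), unname(coef(lm(y ~ z))), tolerance = 1e-8)
})

test_that("the EM iterations never decrease the marginal likelihood", {
  set.seed(92)
  n <- 80
  Z <- matrix(rbinom(n * 8, 2, 0.3) - 1, n, 8)
  y <- 10 + 1.2 * Z[, 1] + 0.8 * Z[, 4] + rnorm(n)
  X <- cbind(rep(1, n))
  lls <- vapply(1:25, function(k)
    suppressWarnings(emeb_fit(y, X, Z, max_iter = k)$loglik), 0)
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("per-marker likelihood ratio tests isolate the causal marker", {
  set.seed(93)
  n <- 150
  Z <- matrix(rbinom(n * 5, 2, 0.3) - 1, n, 5)
  y <- 10 + 2 * Z[, 3] + rnorm(n, sd = 2)
  X <- cbind(rep(1, n))
  fit <- emeb_fit(y, X, Z)
  lrt <- lrt_per_marker(fit, y, X, Z)
  expect_equal(nrow(lrt), 5)
  expect_equal(which.max(lrt$lod), 3)
  expect_gt(lrt$lod[3], 3)
  shrunk <- which(fit$sigma_k2 <= 1e-12)
  expect_true(all(lrt$lrt[shrunk] == 0))
  expect_true(all(lrt$p[shrunk] == 1))
  expect_true(all(abs(lrt$lod - lrt$lrt / (2 * log(10))) < 1e-12))
})

test_that("a 0.15-heritability QTN at n = 199 is usually declared", {
  set.seed(94)
  n <- 199
  a <- sqrt(0.15 / 0.85 * 10 / 0.42)
  hit <- replicate(100, {
    Z <- matrix(rbinom(n * 6, 2, 0.3) - 1, n, 6)
    y <- 10 + a * Z[, 2] + rnorm(n, sd = sqrt(10))
    fit <- emeb_fit(y, cbind(rep(1, n)), Z)
    lrt <- lrt_per_marker(fit, y, cbind(rep(1, n)), Z)
    lrt$lod[2] >= 3
  })
  expect_gte(mean(hit), 0.6)
})

test_that("final calls honour the inclusive LOD boundary and report r2", {
  ft <- data.frame(marker = c("a", "b", "c"), chrom = 1,
                   pos = c(1000, 2000, 3000),
                   treated_as = "random", effect = c(1, 2, 0.5),
                   lrt = c(2.99, 3.01, 3) * 2 * log(10),
                   lod = c(2.99, 3.01, 3),
                   p = 0.001, stringsAsFactors = FALSE)
  set.seed(95)
  Z <- matrix(rbinom(30 * 3, 2, 0.4) - 1, 30, 3)
  y <- rnorm(30, 10, 2)
  calls <- final_calls(ft, y, Z)
  expect_setequal(calls$marker, c("b", "c"))     # >= 3 is inclusive
  i <- which(calls$marker == "b")
  expect_equal(calls$r2[i], var(Z[, 2]) * 4 / var(y), tolerance = 1e-12)

  empty <- final_calls(ft[0, ], y, Z[, 0])
  expect_equal(nrow(empty), 0L)
})

test_that("the BIC goodness of fit matches the Gaussian closed form", {
  set.seed(96)
  y <- rnorm(50, 10, 3)
  g0 <- bic_goodness_of_fit(y)
  s2 <- mean((y - mean(y))^2)
  ll <- -0.5 * 50 * (log(2 * pi * s2) + 1)
  expect_equal(g0$neg_loglik, -ll, tolerance = 1e-8)
  expect_equal(g0$bic, -2 * ll + 2 * log(50), tolerance = 1e-8)

  # an uninformative extra column raises the BIC almost always
  worse <- replicate(100, {
    yy <- rnorm(40)
    z <- rnorm(40)
    bic_goodness_of_fit(yy, cbind(z))$bic > bic_goodness_of_fit(yy)$bic
  })
  expect_gte(mean(worse), 0.9)

  # a perfect fit hits the variance floor instead of erroring
  Z <- matrix(rbinom(40 * 2, 2, 0.4) - 1, 40, 2)
  yy <- 1 + 2 * Z[, 1] - Z[, 2]
  g <- bic_goodness_of_fit(yy, Z)
  expect_true(is.finite(g$bic))

  expect_warning(bic_goodness_of_fit(yy, cbind(Z, Z[, 1])), "collinear")
})

test_that("the two-stage pipeline is deterministic and safe on null phenotypes", {
  set.seed(97)
  cfg <- sim_config(n = 120, m = 300, rho = 0.5)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  K <- kinship(sim$geno)
  f1 <- mrmlm(ph$y, sim$geno, K = K)
  f2 <- mrmlm(ph$y, sim$geno, K = K)
  expect_identical(f1$calls, f2$calls)
  expect_identical(f1$fit_table, f2$fit_table)

  # no-signal safety: false QTN calls at LOD >= 3 are very rare
  set.seed(98)
  n <- 199; m <- 500; reps <- 60
  cfg0 <- sim_config(n = n, m = m, rho = 0)
  false_calls <- 0; tests <- 0
  for (r in seq_len(reps)) {
    s <- simulate_genotypes(cfg0)
    y0 <- rnorm(n, 10, sqrt(10))
    f <- mrmlm(y0, s$geno)
    false_calls <- false_calls + nrow(f$calls)
    tests <- tests + m
  }
  expect_lte(false_calls / tests, 0.001)
})

test_that("the multi-locus stage estimates effects at least as accurately as the scan", {
  set.seed(99)
  reps <- 200
  cfg <- sim_experiment(1, n = 199, m = 1000)
  est_m <- matrix(NA_real_, reps, 6)
  est_r <- matrix(NA_real_, reps, 6)
  truth0 <- NULL
  for (r in seq_len(reps)) {
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(sim, cfg)
    truth0 <- ph$truth
    K <- kinship(sim$geno)
    fit <- mrmlm(ph$y, sim$geno, K = K)
    sc <- fit$scan
    for (i in 1:6) {
      # nearest declared call within 1 kb
      if (nrow(fit$calls)) {
        d <- ifelse(fit$calls$chrom == ph$truth$qtn_chrom[i],
                    abs(fit$calls$pos - ph$truth$qtn_pos[i]), Inf)
        if (min(d) <= 1000) est_m[r, i] <- fit$calls$effect[which.min(d)]
      }
      sig <- sc$records[which(sc$records$significant), , drop = FALSE]
      if (nrow(sig)) {
        d <- ifelse(sig$chrom == ph$truth$qtn_chrom[i],
                    abs(sig$pos - ph$truth$qtn_pos[i]), Inf)
        if (min(d) <= 1000) est_r[r, i] <- sig$effect[which.min(d)]
      }
    }
  }
  mse_m <- evaluate_mse(est_m, truth0$qtn_effects)
  mse_r <- evaluate_mse(est_r, truth0$qtn_effects)
  expect_gte(sum(mse_m <= mse_r), 4)
})
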