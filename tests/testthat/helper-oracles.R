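# Dense-matrix oracles: explicit n x n inverses and determinants, kept
# independent of the Woodbury / closed-form paths they check.

dense_sigma <- function(lambda_k, z, Rdiag) {
  lambda_k * tcrossprod(z) + diag(Rdiag, length(Rdiag))
}

# REML log likelihood with beta and sigma2 profiled out, dense algebra
dense_reml_loglik <- function(lambda_k, y, X, z, Rdiag) {
  n <- length(y); q <- qr(X)$rank
  Sigma <- dense_sigma(lambda_k, z, Rdiag)
  Si <- solve(Sigma)
  XtSX <- t(X) %*% Si %*% X
  P <- Si - Si %*% X %*% solve(XtSX) %*% t(X) %*% Si
  sigma2 <- drop(t(y) %*% P %*% y) / (n - q)
  -0.5 * ((n - q) * log(2 * pi * sigma2) + (n - q) +
            as.numeric(determinant(Sigma)$modulus) +
            as.numeric(determinant(XtSX)$modulus))
}

dense_gls <- function(y, X, Sigma) {
  Si <- solve(Sigma)
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  n <- length(y); q <- qr(X)$rank
  P <- Si - Si %*% X %*% solve(t(X) %*% Si %*% X) %*% t(X) %*% Si
  sigma2 <- drop(t(y) %*% P %*% y) / (n - q)
  list(beta = drop(beta), sigma2 = sigma2, P = P, Si = Si)
}

dense_blup <- function(lambda_k, y, X, z, Rdiag) {
  Sigma <- dense_sigma(lambda_k, z, Rdiag)
  g <- dense_gls(y, X, Sigma)
  gamma <- lambda_k * drop(t(z) %*% g$Si %*% (y - X %*% g$beta))
  var_g <- g$sigma2 * (lambda_k - lambda_k^2 * drop(t(z) %*% g$P %*% z))
  list(gamma = gamma, var_gamma = var_g)
}

# small random test instance: coded genotypes, phenotype, weights
toy_instance <- function(n, m, seed, q_covar = 0, lambda_bg = 0.5) {
  set.seed(seed)
  Z <- matrix(sample(c(-1, 0, 1), n * m, replace = TRUE), n, m)
  map <- data.frame(marker = paste0("m", seq_len(m)), chrom = 1,
                    pos = seq_len(m) * 1000)
  X <- matrix(1, n, 1)
  if (q_covar) X <- cbind(X, matrix(rnorm(n * q_covar), n))
  D <- sort(rexp(n, 1), decreasing = TRUE)
  R <- lambda_bg * D + 1
  y <- rnorm(n, sd = 2)
  list(geno = geno_matrix(Z, map), Z = Z, X = X, D = D, R = R, y = y)
}
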