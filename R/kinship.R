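#' Marker-inferred kinship matrix
#'
#' VanRaden-type kinship from the column-centered coded genotype matrix:
#' `K = c * Zc %*% t(Zc)` with the constant `c` chosen so that
#' `mean(diag(K)) = 1`. The normalisation keeps the polygenic-to-residual
#' variance ratio on the usual scale. Missing genotypes are mean-imputed
#' per marker before centering; monomorphic markers contribute nothing.
#'
#' The formula is pluggable: pass a function `method(Zc)` taking the
#' centered matrix and returning an n x n matrix to substitute another
#' estimator; the choice is recorded in `attr(K, "method")`.
#'
#' @param G a [geno_matrix()] or coded numeric matrix.
#' @param method `"vanraden"` (default) or a function of the centered matrix.
#' @return symmetric positive semi-definite n x n matrix with sample ids as
#'   dimnames.
#' @export
kinship <- function(G, method = "vanraden") {
  Z <- if (inherits(G, "geno_matrix")) G$values else as.matrix(G)
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2L]]
  }
  poly <- !.monomorphic_cols(Z)
  if (!any(poly)) stop("kinship needs at least one polymorphic marker")
  Zc <- scale(Z[, poly, drop = FALSE], center = TRUE, scale = FALSE)
  if (is.function(method)) {
    K <- method(Zc)
    attr(K, "method") <- "custom"
  } else {
    method <- match.arg(method, "vanraden")
    K <- tcrossprod(Zc)
    K <- K / mean(diag(K))
    attr(K, "method") <- "vanraden"
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(Z), rownames(Z))
  K
}

#' Eigen-decomposition of a kinship matrix
#'
#' Returns the spectrum used by the whitening transform. Tiny negative
#' eigenvalues (numerical PSD repair) are clipped to zero; eigenvalues below
#' `-tol * max(|eigenvalue|)` signal a genuinely indefinite input and raise
#' an error.
#'
#' @param K symmetric n x n matrix.
#' @param tol relative tolerance for symmetry and negative-eigenvalue repair.
#' @return object of class `kinship_spectrum`: list with `K`, orthonormal
#'   eigenvectors `U` and eigenvalues `D` in descending order.
#' @export
kinship_spectrum <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  nrm <- max(abs(K), 1e-300)
  if (max(abs(K - t(K))) > tol * nrm) stop("kinship matrix is not symmetric")
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("kinship matrix has a substantially negative eigenvalue: ",
         format(min(e$values)))
  D <- pmax(e$values, 0)
  structure(list(K = K, U = e$vectors, D = D), class = "kinship_spectrum")
}

#' @export
print.kinship_spectrum <- function(x, ...) {
  cat(sprintf("Kinship spectrum: n = %d, eigenvalues in [%.4g, %.4g]\n",
              length(x$D), min(x$D), max(x$D)))
  invisible(x)
}

#' Whitening transform of phenotype and design
#'
#' Rotates `y` and `X` by the transposed eigenvectors of the kinship matrix
#' so that the polygenic covariance becomes diagonal,
#' `Var(U'u) = sigma_g^2 * diag(D)`. The rotation is orthogonal, so norms
#' are preserved and the transform is exactly invertible.
#'
#' @param y numeric phenotype vector of length n.
#' @param X n x q fixed-effect design matrix (intercept included). `NULL`
#'   gives an intercept-only design.
#' @param U orthonormal eigenvector matrix (or a `kinship_spectrum`).
#' @return object of class `transformed_data`: `y_star`, `X_star`, `U`, `n`,
#'   `q` (rank of X).
#' @export
transform_data <- function(y, X, U) {
  if (inherits(U, "kinship_spectrum")) U <- U$U
  y <- as.numeric(y)
  n <- length(y)
  if (!all(is.finite(y))) stop("phenotype must be finite")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n || nrow(U) != n || ncol(U) != n)
    stop("dimension mismatch between y, X and U")
  q <- qr(X)$rank
  if (q > ncol(X)) stop("invalid design matrix")
  structure(list(y_star = drop(crossprod(U, y)),
                 X_star = crossprod(U, X),
                 U = U, n = n, q = q),
            class = "transformed_data")
}
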