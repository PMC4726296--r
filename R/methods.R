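#' @export
print.rmlm <- function(x, ...) {
  cat(sprintf("%s-effect mixed linear model scan\n",
              if (x$effect_model == "random") "Random-SNP" else "Fixed-SNP (EMMA-style)"))
  cat(sprintf("  markers tested: %d of %d; lambda (polygenic) = %.4g\n",
              x$thresholds$m, nrow(x$records), x$null_fit$lambda_hat))
  cat(sprintf("  effective markers m_e = %.2f; threshold p = %.3g (alpha = %g)\n",
              x$thresholds$m_e, x$thresholds$p_threshold, x$thresholds$alpha))
  cat(sprintf("  significant markers: %d\n", sum(x$records$significant, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.rmlm <- function(object, n_top = 10, ...) {
  rec <- object$records[!is.na(object$records$p), , drop = FALSE]
  rec <- rec[order(rec$p), , drop = FALSE]
  out <- list(thresholds = object$thresholds,
              null_fit = object$null_fit,
              top = utils::head(rec, n_top),
              n_significant = sum(rec$significant))
  class(out) <- "summary.rmlm"
  out
}

#' @export
print.summary.rmlm <- function(x, ...) {
  cat(sprintf("Scan: %d tested markers, m_e = %.2f, threshold p = %.3g\n",
              x$thresholds$m, x$thresholds$m_e, x$thresholds$p_threshold))
  cat(sprintf("Significant markers: %d\nTop associations:\n", x$n_significant))
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.rmlm <- function(object, ...) {
  stats::setNames(object$records$effect, object$records$marker)
}

#' Manhattan-style plot of a genome scan
#'
#' Plots `-log10(p)` against genome position, colouring chromosomes
#' alternately and drawing the significance threshold.
#'
#' @param x an `rmlm` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rmlm <- function(x, ...) {
  rec <- x$records
  chr <- factor(rec$chrom, levels = unique(rec$chrom))
  offset <- c(0, cumsum(tapply(rec$pos, chr, max)))[as.integer(chr)]
  gx <- rec$pos + offset
  graphics::plot(gx, -log10(rec$p), pch = 20, cex = 0.6,
                 col = c("grey30", "steelblue")[1 + as.integer(chr) %% 2],
                 xlab = "genome position (bp, concatenated)",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(x$thresholds$p_threshold), lty = 2, col = "red")
  invisible(x)
}

#' @export
print.mrmlm <- function(x, ...) {
  cat("Multi-locus random-SNP-effect mixed linear model\n")
  cat(sprintf("  stage 1: %d markers preselected at p < %g (window %g bp)\n",
              nrow(x$selected), x$thresholds$p_select, x$thresholds$window_bp))
  if (nrow(x$selected))
    cat(sprintf("  treated as fixed: %d, random: %d\n",
                sum(x$selected$treated_as == "fixed"),
                sum(x$selected$treated_as == "random")))
  cat(sprintf("  declared QTNs (LOD >= %g): %d\n",
              x$thresholds$lod_threshold, nrow(x$calls)))
  cat(sprintf("  goodness of fit: -loglik = %.2f, BIC = %.2f\n",
              x$bic$neg_loglik, x$bic$bic))
  invisible(x)
}

#' @export
summary.mrmlm <- function(object, ...) {
  out <- list(thresholds = object$thresholds, calls = object$calls,
              n_selected = nrow(object$selected), bic = object$bic,
              emeb = if (!is.null(object$emeb))
                list(iterations = object$emeb$iterations,
                     converged = object$emeb$converged,
                     sigma2 = object$emeb$sigma2))
  class(out) <- "summary.mrmlm"
  out
}

#' @export
print.summary.mrmlm <- function(x, ...) {
  cat(sprintf("Multi-locus fit: %d selected markers, %d declared QTNs\n",
              x$n_selected, nrow(x$calls)))
  if (nrow(x$calls)) {
    cat("Declared QTNs:\n")
    print(x$calls, row.names = FALSE, digits = 4)
  }
  cat(sprintf("BIC of the called set: %.2f\n", x$bic$bic))
  invisible(x)
}

#' @export
coef.mrmlm <- function(object, ...) {
  stats::setNames(object$calls$effect, object$calls$marker)
}

#' Fitted genetic values from the declared QTNs
#'
#' Returns `intercept + sum_k z_k * effect_k` over the declared QTN set
#' (intercept-only when no QTN was called).
#'
#' @param object an `mrmlm` fit.
#' @param geno the [geno_matrix()] the model was fitted on.
#' @param ... unused.
#' @export
fitted.mrmlm <- function(object, geno = NULL, ...) {
  if (is.null(geno)) stop("supply the geno_matrix used in the fit")
  mu <- mean(object$y)
  if (!nrow(object$calls)) return(rep(mu, length(object$y)))
  Z <- geno$values[, match(object$calls$marker, geno$snp_map$marker),
                   drop = FALSE]
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  drop(mu + Zc %*% object$calls$effect)
}

#' @export
residuals.mrmlm <- function(object, geno = NULL, ...) {
  object$y - fitted.mrmlm(object, geno = geno, ...)
}
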