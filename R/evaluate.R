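#' Per-QTN empirical power
#'
#' A QTN counts as detected in a replicate when at least one declared call
#' lies within `window_bp` of its position on the same chromosome; each
#' call is credited to at most one QTN (the nearest). Power is the
#' fraction of replicates with a detection.
#'
#' @param calls_list list (one element per replicate) of data.frames with
#'   columns `chrom`, `pos`.
#' @param truth list with `qtn_chrom`, `qtn_pos` (as from
#'   [simulate_genotypes()]).
#' @param window_bp detection half-window (default 1000).
#' @return numeric vector of per-QTN power.
#' @export
evaluate_power <- function(calls_list, truth, window_bp = 1000) {
  nq <- length(truth$qtn_pos)
  hits <- matrix(FALSE, length(calls_list), nq)
  for (r in seq_along(calls_list)) {
    hits[r, ] <- .credit_calls(calls_list[[r]], truth, window_bp) > 0
  }
  colMeans(hits)
}

# number of calls credited to each QTN (nearest in-window QTN wins a call)
.credit_calls <- function(calls, truth, window_bp) {
  nq <- length(truth$qtn_pos)
  cnt <- integer(nq)
  if (is.null(calls) || nrow(calls) == 0L) return(cnt)
  for (i in seq_len(nrow(calls))) {
    d <- ifelse(calls$chrom[i] == truth$qtn_chrom,
                abs(calls$pos[i] - truth$qtn_pos), Inf)
    j <- which.min(d)
    if (d[j] <= window_bp) cnt[j] <- cnt[j] + 1L
  }
  cnt
}

#' Pooled empirical Type 1 error
#'
#' The proportion of significant null markers over all null-marker tests,
#' pooled across replicates; markers overlapping the simulated QTNs are
#' excluded from both numerator and denominator.
#'
#' @param flags_list list (per replicate) of logical significance flags per
#'   marker; `NA` flags (untested markers) are excluded.
#' @param qtn_index marker indices of the simulated QTNs.
#' @return scalar rate in [0, 1].
#' @export
evaluate_type1 <- function(flags_list, qtn_index = integer(0)) {
  sig <- 0; tot <- 0
  for (fl in flags_list) {
    if (length(qtn_index)) fl <- fl[-qtn_index]
    fl <- fl[!is.na(fl)]
    sig <- sig + sum(fl)
    tot <- tot + length(fl)
  }
  if (tot == 0L) return(0)
  sig / tot
}

#' Per-QTN mean squared error of effect estimates
#'
#' `MSE_i = mean_j (gamma_hat_ij - gamma_i)^2` over replicates. By
#' default an undetected QTN contributes an estimate of zero (the
#' shrinkage-consistent convention); `skip_undetected = TRUE` instead
#' averages over detecting replicates only.
#'
#' @param estimates replicates x QTN matrix of estimated effects, `NA`
#'   where undetected.
#' @param true_effects length-#QTN vector of true effects.
#' @param skip_undetected drop NA estimates instead of scoring them as 0.
#' @return numeric vector of per-QTN MSE.
#' @export
evaluate_mse <- function(estimates, true_effects, skip_undetected = FALSE) {
  estimates <- as.matrix(estimates)
  stopifnot(ncol(estimates) == length(true_effects))
  vapply(seq_along(true_effects), function(i) {
    est <- estimates[, i]
    if (skip_undetected) est <- est[!is.na(est)] else est[is.na(est)] <- 0
    if (!length(est)) return(NA_real_)
    mean((est - true_effects[i])^2)
  }, 0)
}

#' ROC coordinates over a grid of significance levels
#'
#' Inserts 61 log-spaced probability levels between 1e-8 and 1e-2 and, at
#' each, computes the empirical Type 1 error (over null markers) and the
#' per-QTN power (a marker with `p <= alpha` within the detection window
#' counts). Both coordinates are non-decreasing in the level.
#'
#' @param p_list list (per replicate) of per-marker p-value vectors.
#' @param sim output of [simulate_genotypes()] (for the map and truth).
#' @param window_bp detection half-window.
#' @param levels significance levels (default `10^seq(-8, -2, by = 0.1)`).
#' @return list with `alpha` (levels), `power` (levels x QTN matrix),
#'   `type1` (vector).
#' @export
roc_curves <- function(p_list, sim, window_bp = 1000,
                       levels = 10^seq(-8, -2, by = 0.1)) {
  truth <- sim$truth
  map <- sim$geno$snp_map
  nq <- length(truth$qtn_pos)
  in_window <- lapply(seq_len(nq), function(i)
    which(map$chrom == truth$qtn_chrom[i] &
            abs(map$pos - truth$qtn_pos[i]) <= window_bp))
  null_idx <- setdiff(seq_len(nrow(map)), truth$qtn_index)
  power <- matrix(0, length(levels), nq)
  sig_null <- numeric(length(levels)); tot_null <- 0
  for (p in p_list) {
    pn <- p[null_idx]
    pn <- pn[!is.na(pn)]
    tot_null <- tot_null + length(pn)
    for (l in seq_along(levels)) {
      sig_null[l] <- sig_null[l] + sum(pn <= levels[l])
      for (i in seq_len(nq)) {
        pw <- p[in_window[[i]]]
        if (any(!is.na(pw) & pw <= levels[l]))
          power[l, i] <- power[l, i] + 1
      }
    }
  }
  list(alpha = levels, power = power / length(p_list),
       type1 = sig_null / max(tot_null, 1))
}
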