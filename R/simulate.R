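#' Simulation configuration for the Monte Carlo designs
#'
#' Captures the four simulation designs used to evaluate the methods:
#' six additive QTNs at minor allele frequency 0.30 with heritabilities
#' (0.10, 0.05, 0.05, 0.15, 0.05, 0.05), phenotypic mean 10.0 and residual
#' variance 10.0; optionally an additive polygenic component (fraction
#' 0.092 of phenotypic variance in the second design) and three epistatic
#' QTN pairs each explaining 0.05 (third design); the fourth design varies
#' the sample size (199, 149, 99). Markers are spread over `n_chr`
#' chromosomes at 500 bp spacing with local AR(1) linkage disequilibrium.
#'
#' @param n individuals (default 199).
#' @param m markers (default 2000).
#' @param maf allele frequency of the QTN markers (default 0.30).
#' @param qtn_h2 per-QTN heritabilities.
#' @param mean phenotypic mean.
#' @param resid_var residual variance.
#' @param polygenic_h2 fraction of phenotypic variance from the polygenic
#'   term (0 disables it).
#' @param epistasis_h2 vector of per-pair epistatic heritabilities (length 0
#'   disables epistasis).
#' @param rho AR(1) allele-copy correlation between adjacent markers.
#' @param n_chr chromosomes; markers are split evenly.
#' @param spacing_bp base-pair spacing between adjacent markers.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 199, m = 2000, maf = 0.30,
                       qtn_h2 = c(0.10, 0.05, 0.05, 0.15, 0.05, 0.05),
                       mean = 10, resid_var = 10,
                       polygenic_h2 = 0, epistasis_h2 = numeric(0),
                       rho = 0.7, n_chr = 5, spacing_bp = 500) {
  stopifnot(n >= 2, m >= 1, maf > 0, maf <= 0.5, resid_var > 0,
            all(qtn_h2 >= 0), polygenic_h2 >= 0, all(epistasis_h2 >= 0),
            rho >= 0, rho < 1)
  total <- sum(qtn_h2) + polygenic_h2 + sum(epistasis_h2)
  if (total >= 1) stop("variance fractions must sum below 1")
  structure(list(n = n, m = m, maf = maf, qtn_h2 = qtn_h2, mean = mean,
                 resid_var = resid_var, polygenic_h2 = polygenic_h2,
                 epistasis_h2 = epistasis_h2, rho = rho, n_chr = n_chr,
                 spacing_bp = spacing_bp),
            class = "sim_config")
}

#' Preset configurations of the four simulation designs
#'
#' @param experiment 1 (additive QTNs only), 2 (plus polygenic fraction
#'   0.092), 3 (plus three epistatic pairs, 0.05 each), 4 (design 2 at a
#'   chosen sample size).
#' @param n sample size (used by experiment 4; default 199).
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_experiment <- function(experiment = 1, n = 199, ...) {
  switch(as.character(experiment),
         "1" = sim_config(n = n, ...),
         "2" = sim_config(n = n, polygenic_h2 = 0.092, ...),
         "3" = sim_config(n = n, epistasis_h2 = c(0.05, 0.05, 0.05), ...),
         "4" = sim_config(n = n, polygenic_h2 = 0.092, ...),
         stop("experiment must be 1, 2, 3 or 4"))
}

# QTN marker indices: one per chromosome plus a second on chromosome 1,
# kept away from block edges; epistatic loci on the chromosome pairs
# (4,2), (2,3), (3,1), away from the QTNs.
.design_positions <- function(cfg) {
  per <- floor(cfg$m / cfg$n_chr)
  chr_start <- (seq_len(cfg$n_chr) - 1L) * per + 1L
  at <- function(chr, frac) chr_start[chr] + max(1L, round(per * frac)) - 1L
  qtn <- c(at(1, 0.25), at(2, 0.50), at(3, 0.50), at(4, 0.50), at(5, 0.50),
           at(1, 0.75))[seq_along(cfg$qtn_h2)]
  epi <- NULL
  if (length(cfg$epistasis_h2)) {
    pairs <- list(c(4, 2), c(2, 3), c(3, 1))
    fr <- list(c(0.20, 0.22), c(0.80, 0.20), c(0.80, 0.45))
    epi <- t(vapply(seq_along(cfg$epistasis_h2), function(j) {
      pr <- pairs[[((j - 1) %% 3) + 1]]
      c(at(pr[1], fr[[((j - 1) %% 3) + 1]][1]),
        at(pr[2], fr[[((j - 1) %% 3) + 1]][2]))
    }, c(0, 0)))
  }
  list(qtn = qtn, epi = epi)
}

#' Simulate coded genotypes with local linkage disequilibrium
#'
#' Draws `2n` haplotypes per chromosome from a Gaussian-copula AR(1)
#' process (latent correlation `rho` between adjacent markers) and codes
#' the genotypes {1, 0, -1} under Hardy-Weinberg proportions. Non-QTN
#' marker allele frequencies are uniform on [0.05, 0.5]; QTN (and
#' epistatic) marker columns are drawn at exactly the design frequency
#' `maf` and redrawn if monomorphic. Positions are spaced `spacing_bp`
#' apart within each chromosome.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (a [geno_matrix()]) and `truth` scaffold:
#'   `qtn_index`, `qtn_chrom`, `qtn_pos`, `epi_index` (pairs), frequencies.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n; m <- cfg$m
  des <- .design_positions(cfg)
  freq <- stats::runif(m, 0.05, 0.5)
  special <- c(des$qtn, as.integer(des$epi))
  freq[special] <- cfg$maf
  per <- floor(m / cfg$n_chr)
  chrom <- rep(seq_len(cfg$n_chr), times = c(rep(per, cfg$n_chr - 1), m - per * (cfg$n_chr - 1)))
  pos <- unlist(lapply(table(chrom), function(k) seq_len(k) * cfg$spacing_bp))
  thresh <- stats::qnorm(freq)
  Z <- matrix(0, n, m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    mj <- length(idx)
    for (h in 1:2) {
      lat <- matrix(stats::rnorm(n * mj), n, mj)
      if (cfg$rho > 0 && mj > 1) {
        # stationary AR(1) along the marker axis
        sr <- sqrt(1 - cfg$rho^2)
        for (j in 2:mj)
          lat[, j] <- cfg$rho * lat[, j - 1] + sr * lat[, j]
      }
      Z[, idx] <- Z[, idx] + (lat < rep(thresh[idx], each = n))
    }
  }
  Z <- Z - 1
  # redraw monomorphic QTN columns (exceedingly rare at n = 199)
  for (j in special) {
    tries <- 0
    while (max(Z[, j]) - min(Z[, j]) < 1e-12 && tries < 100) {
      hap <- stats::rbinom(2 * n, 1, freq[j])
      Z[, j] <- hap[1:n] + hap[(n + 1):(2 * n)] - 1
      tries <- tries + 1
    }
  }
  map <- data.frame(marker = sprintf("snp_%d_%d", chrom, pos),
                    chrom = chrom, pos = pos)
  g <- geno_matrix(Z, map)
  truth <- list(qtn_index = des$qtn, qtn_marker = map$marker[des$qtn],
                qtn_chrom = chrom[des$qtn], qtn_pos = pos[des$qtn],
                epi_index = des$epi, freq = freq)
  list(geno = g, truth = truth)
}

#' Back-solve true effect sizes from the design heritabilities
#'
#' The total phenotypic variance implied by the design is
#' `V_p = resid_var / (1 - sum(all fractions))`. Under the {1, 0, -1}
#' coding a marker at allele frequency p has variance `2 p q`, so the
#' additive effect of QTN i is `a_i = sqrt(h_i^2 V_p / (2 p q))`. An
#' epistatic pair's effect multiplies the elementwise product of its two
#' coded columns, whose Hardy-Weinberg variance (independent loci, equal
#' frequency p) is `(2pq + (p-q)^2)^2 - (p-q)^4`; the pair effect is
#' back-solved from that expected variance, so all true effects are fixed
#' design constants.
#'
#' @param cfg a [sim_config()].
#' @return list with `V_p`, `qtn_effects`, `epi_effects`, `polygenic_var`.
#' @export
derive_qtn_effects <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  total <- sum(cfg$qtn_h2) + cfg$polygenic_h2 + sum(cfg$epistasis_h2)
  if (total >= 1) stop("variance fractions must sum below 1")
  V_p <- cfg$resid_var / (1 - total)
  p <- cfg$maf; q <- 1 - p
  a <- sqrt(cfg$qtn_h2 * V_p / (2 * p * q))
  mu2 <- (p - q)^2
  vprod <- (2 * p * q + mu2)^2 - mu2^2
  e <- if (length(cfg$epistasis_h2)) sqrt(cfg$epistasis_h2 * V_p / vprod)
       else numeric(0)
  list(V_p = V_p, qtn_effects = a, epi_effects = e,
       polygenic_var = cfg$polygenic_h2 * V_p)
}

#' Simulate phenotypes under a design
#'
#' `y = mean + sum a_i z_i + sum e_j (z_j1 * z_j2) + u + eps` with
#' `u ~ MVN(0, polygenic_var * K)` and `eps ~ N(0, resid_var)`. The
#' returned truth records every component so realized variance fractions
#' can be audited.
#'
#' @param sim output of [simulate_genotypes()].
#' @param cfg the [sim_config()].
#' @param K kinship matrix; required when `polygenic_h2 > 0` (computed from
#'   the simulated genotypes if `NULL`).
#' @return list with `y` and `truth` (effects plus the component vectors
#'   `additive` (n x #QTN matrix), `epistatic`, `polygenic`, `residual`).
#' @export
simulate_phenotypes <- function(sim, cfg, K = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- sim$geno; truth <- sim$truth
  eff <- derive_qtn_effects(cfg)
  n <- cfg$n
  Zq <- g$values[, truth$qtn_index, drop = FALSE]
  additive <- sweep(Zq, 2L, eff$qtn_effects, `*`)
  epistatic <- rep(0, n)
  if (length(eff$epi_effects)) {
    for (j in seq_along(eff$epi_effects)) {
      prod_col <- g$values[, truth$epi_index[j, 1]] *
        g$values[, truth$epi_index[j, 2]]
      epistatic <- epistatic + eff$epi_effects[j] * prod_col
    }
  }
  polygenic <- rep(0, n)
  if (eff$polygenic_var > 0) {
    if (is.null(K)) K <- kinship(g)
    L <- chol(K + diag(1e-8, n))
    polygenic <- sqrt(eff$polygenic_var) * drop(crossprod(L, stats::rnorm(n)))
  }
  residual <- stats::rnorm(n, 0, sqrt(cfg$resid_var))
  y <- cfg$mean + rowSums(additive) + epistatic + polygenic + residual
  truth$qtn_effects <- eff$qtn_effects
  truth$epi_effects <- eff$epi_effects
  truth$V_p <- eff$V_p
  truth$components <- list(additive = additive, epistatic = epistatic,
                           polygenic = polygenic, residual = residual)
  list(y = y, truth = truth)
}

#' Audit realized variance components across replicates
#'
#' Regenerates a design `replicates` times and records the realized sample
#' variance of every phenotype component together with the total
#' phenotypic variance, so the generator can be checked against its
#' nominal variance fractions (e.g. the 0.15 heritability of the largest
#' QTN, the residual variance of 10, the collective epistatic fraction
#' 0.15 and the polygenic fraction 0.092).
#'
#' @param cfg a [sim_config()].
#' @param replicates number of Monte Carlo replicates.
#' @return data.frame with one row per replicate: `qtn4` (variance of the
#'   fourth QTN's additive component, `NA` if fewer than four QTNs),
#'   `residual`, `epistatic`, `polygenic` component variances and `total`
#'   (= `var(y)`).
#' @export
sim_variance_audit <- function(cfg, replicates = 500) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- matrix(NA_real_, replicates, 5,
                dimnames = list(NULL, c("qtn4", "residual", "epistatic",
                                        "polygenic", "total")))
  for (r in seq_len(replicates)) {
    sim <- simulate_genotypes(cfg)
    K <- if (cfg$polygenic_h2 > 0) kinship(sim$geno) else NULL
    ph <- simulate_phenotypes(sim, cfg, K = K)
    comp <- ph$truth$components
    out[r, ] <- c(if (length(cfg$qtn_h2) >= 4) stats::var(comp$additive[, 4])
                  else NA_real_,
                  stats::var(comp$residual),
                  stats::var(comp$epistatic),
                  stats::var(comp$polygenic),
                  stats::var(ph$y))
  }
  as.data.frame(out)
}
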