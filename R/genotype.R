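#' Construct a coded genotype matrix
#'
#' Bundles an n x m numeric marker matrix coded {1, 0, -1} (one homozygote,
#' heterozygote, other homozygote) with its SNP map and sample identifiers.
#' Missing genotypes are `NA`; columns flagged monomorphic carry no
#' information for association and are skipped by the scans.
#'
#' @param values numeric n x m matrix, entries in {1, 0, -1} or NA.
#' @param snp_map data.frame with columns `marker`, `chrom`, `pos`
#'   (1-based base pairs, strictly increasing within a chromosome).
#' @param sample_ids character vector of length n.
#' @param monomorphic optional logical vector of length m; recomputed when
#'   missing.
#' @return an object of class `geno_matrix` with elements `values`,
#'   `snp_map`, `sample_ids`, `monomorphic`.
#' @export
geno_matrix <- function(values, snp_map, sample_ids = NULL, monomorphic = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (n < 2L || m < 1L)
    stop("genotype matrix needs n >= 2 individuals and m >= 1 markers")
  ok <- values[!is.na(values)]
  if (length(ok) && any(ok < -1 - 1e-9 | ok > 1 + 1e-9))
    stop("coded genotypes must lie in {1, 0, -1} (imputed values in [-1, 1])")
  snp_map <- as.data.frame(snp_map)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(snp_map)))
    stop("snp_map needs columns marker, chrom, pos")
  if (nrow(snp_map) != m) stop("snp_map rows must match marker columns")
  if (anyDuplicated(snp_map$marker)) stop("duplicate marker ids")
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(n))
  if (length(sample_ids) != n) stop("sample_ids length must equal n")
  if (is.null(monomorphic)) monomorphic <- .monomorphic_cols(values)
  colnames(values) <- snp_map$marker
  rownames(values) <- sample_ids
  structure(list(values = values, snp_map = snp_map,
                 sample_ids = as.character(sample_ids),
                 monomorphic = as.logical(monomorphic)),
            class = "geno_matrix")
}

.is_monomorphic <- function(z) {
  z <- z[!is.na(z)]
  length(z) == 0L || max(z) - min(z) < 1e-12
}

# vectorized monomorphism check (zero variance, NA-tolerant)
.monomorphic_cols <- function(values) {
  nobs <- colSums(!is.na(values))
  mu <- colMeans(values, na.rm = TRUE)
  v <- colMeans(values^2, na.rm = TRUE) - mu^2
  out <- nobs == 0L | (is.finite(v) & v < 1e-24)
  out[is.na(out)] <- TRUE
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Coded genotype matrix: %d individuals x %d markers (%d monomorphic)\n",
              nrow(x$values), ncol(x$values), sum(x$monomorphic)))
  cat("Chromosomes:", paste(unique(x$snp_map$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

#' Encode raw biallelic genotype calls as {1, 0, -1}
#'
#' Converts per-marker character calls (e.g. "AA", "AG", "GG", missing "NN"
#' or NA) to the numeric coding 1 / 0 / -1 for one homozygote, the
#' heterozygote and the other homozygote. The allele sorting first
#' lexicographically is coded +1, so the orientation is deterministic;
#' flipping allele labels flips the column sign only.
#'
#' @param raw_calls character matrix (n individuals x m markers) of two-letter
#'   genotype calls; `NA`, `""`, `"NN"` and `"--"` are treated as missing.
#' @param snp_map SNP map as in [geno_matrix()].
#' @param sample_ids optional sample identifiers.
#' @param missing_policy `"mean"` imputes the marker mean of the coded values
#'   (the default, recorded in the result); `"major"` fills the most frequent
#'   coded genotype; `"none"` leaves `NA`.
#' @return a [geno_matrix()] whose attribute `provenance` records the policy
#'   and any rejected markers (more than two alleles, or all calls missing).
#' @export
encode_genotypes <- function(raw_calls, snp_map, sample_ids = NULL,
                             missing_policy = c("mean", "major", "none")) {
  missing_policy <- match.arg(missing_policy)
  raw_calls <- as.matrix(raw_calls)
  m <- ncol(raw_calls); n <- nrow(raw_calls)
  snp_map <- as.data.frame(snp_map)
  vals <- matrix(NA_real_, n, m)
  rejected <- character(0); reasons <- character(0)
  keep <- logical(m)
  for (j in seq_len(m)) {
    cal <- toupper(as.character(raw_calls[, j]))
    cal[cal %in% c("", "NN", "--", "NA")] <- NA
    al <- sort(unique(unlist(strsplit(cal[!is.na(cal)], ""))))
    if (length(al) == 0L) {
      rejected <- c(rejected, snp_map$marker[j]); reasons <- c(reasons, "all calls missing")
      next
    }
    if (length(al) > 2L) {
      rejected <- c(rejected, snp_map$marker[j]); reasons <- c(reasons, ">2 alleles")
      next
    }
    a <- al[1L]                       # lexicographically first allele -> +1
    cnt <- ifelse(is.na(cal), NA,
                  vapply(strsplit(cal, ""), function(g) sum(g == a), 0L))
    z <- as.numeric(cnt) - 1          # 2,1,0 copies -> 1, 0, -1
    if (missing_policy != "none" && anyNA(z)) {
      obs <- z[!is.na(z)]
      fill <- if (missing_policy == "mean") mean(obs) else
        as.numeric(names(sort(table(obs), decreasing = TRUE))[1L])
      z[is.na(z)] <- fill
    }
    vals[, j] <- z
    keep[j] <- TRUE
  }
  g <- geno_matrix(vals[, keep, drop = FALSE], snp_map[keep, , drop = FALSE],
                   sample_ids)
  attr(g, "provenance") <- list(missing_policy = missing_policy,
                                rejected = data.frame(marker = rejected,
                                                      reason = reasons))
  g
}

#' Minor allele frequency of coded markers
#'
#' Frequencies are computed from the {1, 0, -1} coding as
#' `p = (mean(z) + 1) / 2` for the +1 allele, folded to the minor allele.
#'
#' @param G a [geno_matrix()] or coded numeric matrix.
#' @return numeric vector of per-marker minor allele frequencies.
#' @export
marker_maf <- function(G) {
  Z <- if (inherits(G, "geno_matrix")) G$values else as.matrix(G)
  p <- (colMeans(Z, na.rm = TRUE) + 1) / 2
  pmin(p, 1 - p)
}
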