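#' Read genotypes from delimited text
#'
#' Two layouts are supported. `"coded-csv"`: columns `marker, chrom, pos`
#' followed by one numeric column per sample (header row holds the sample
#' ids), entries coded {1, 0, -1} with empty/NA for missing.
#' `"hapmap-like"`: columns `marker, chrom, pos, alleles` followed by
#' two-letter genotype calls per sample (`NN` missing); calls are encoded
#' with [encode_genotypes()].
#'
#' @param path file path (comma- or tab-delimited, inferred from the
#'   extension: `.tsv`/`.txt` tab, otherwise comma).
#' @param format `"coded-csv"` or `"hapmap-like"`.
#' @param missing_policy forwarded to [encode_genotypes()] /
#'   mean-imputation of coded values.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("coded-csv", "hapmap-like"),
                           missing_policy = "mean") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed genotype file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty genotype file: ", path)
  meta_n <- if (format == "coded-csv") 3L else 4L
  need <- c("marker", "chrom", "pos", if (format == "hapmap-like") "alleles")
  if (!all(need %in% names(df)[seq_len(meta_n)]))
    stop("genotype file must start with columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$marker))
    stop("duplicate marker id: ",
         df$marker[anyDuplicated(df$marker)])
  ids <- names(df)[-seq_len(meta_n)]
  if (!length(ids)) stop("no sample columns in ", path)
  body <- t(as.matrix(df[, -seq_len(meta_n), drop = FALSE]))
  map <- data.frame(marker = df$marker, chrom = df$chrom, pos = df$pos)
  if (format == "coded-csv") {
    M <- matrix(suppressWarnings(as.numeric(body)), nrow(body), ncol(body))
    bad <- which(is.na(M) & !is.na(body) & body != "" & toupper(body) != "NA",
                 arr.ind = TRUE)
    if (nrow(bad))
      stop("malformed numeric value at marker row ", bad[1, 2],
           " (", map$marker[bad[1, 2]], ")")
    if (anyNA(M) && missing_policy == "mean") {
      mu <- colMeans(M, na.rm = TRUE)
      idx <- which(is.na(M), arr.ind = TRUE)
      M[idx] <- mu[idx[, 2L]]
    }
    g <- geno_matrix(M, map, sample_ids = ids)
  } else {
    g <- encode_genotypes(body, map, sample_ids = ids,
                          missing_policy = missing_policy)
  }
  g
}

#' Read a phenotype table
#'
#' Two-column delimited text (`id`, `value`), tab- or comma-separated.
#' When `geno` is given the values are returned in genotype sample order,
#' erroring on missing ids.
#'
#' @param path file path.
#' @param geno optional [geno_matrix()] to align against.
#' @return named numeric vector.
#' @export
read_phenotypes <- function(path, geno = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs columns id, value")
  y <- stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
  if (!is.null(geno)) {
    miss <- setdiff(geno$sample_ids, names(y))
    if (length(miss)) stop("phenotype missing for: ", paste(miss, collapse = ", "))
    y <- y[geno$sample_ids]
  }
  y
}

#' Read / write a kinship matrix as square CSV
#'
#' @param K kinship matrix with sample-id dimnames.
#' @param path file path.
#' @return `read_kinship` returns the matrix.
#' @export
write_kinship <- function(K, path) {
  utils::write.csv(as.data.frame(K), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write scan or multi-locus results to disk
#'
#' Writes a results TSV (per-marker records for a scan; per-selected-marker
#' table and the declared QTN calls for a multi-locus fit), a thresholds
#' JSON sidecar and a run manifest. Numeric fields are written at 12
#' significant digits so a read-back reproduces them.
#'
#' @param x an `rmlm` or `mrmlm` object.
#' @param out_dir output directory (created if needed).
#' @param manifest optional [run_manifest()] list to write alongside.
#' @return invisibly, the paths written.
#' @export
write_results <- function(x, out_dir, manifest = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    for (j in seq_along(df))
      if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 12)
    df
  }
  paths <- character(0)
  if (inherits(x, "mrmlm")) {
    p1 <- file.path(out_dir, "mrmlm_fit.tsv")
    utils::write.table(fmt(x$fit_table), p1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    p2 <- file.path(out_dir, "mrmlm_calls.tsv")
    utils::write.table(fmt(x$calls), p2, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p1, p2)
    thr <- x$thresholds
  } else if (inherits(x, "rmlm")) {
    p1 <- file.path(out_dir, "scan_records.tsv")
    utils::write.table(fmt(x$records), p1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p1)
    thr <- x$thresholds
  } else stop("x must be an rmlm or mrmlm object")
  pt <- file.path(out_dir, "thresholds.json")
  jsonlite::write_json(thr, pt, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pt)
  if (!is.null(manifest)) {
    pm <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(unclass(manifest), pm, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pm)
  }
  invisible(paths)
}

#' Read back a results TSV
#'
#' @param path a TSV written by [write_results()].
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Run manifest for reproducibility
#'
#' Collects input file hashes, the configuration snapshot, seeds, every
#' threshold actually applied, and the package version: together with the
#' input files the manifest determines a rerun.
#'
#' @param inputs named character vector of input file paths (hashed with
#'   md5).
#' @param config list of configuration values.
#' @param seeds named list/vector of seeds used.
#' @param thresholds list of applied thresholds.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(inputs = character(0), config = list(),
                         seeds = list(), thresholds = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(inputs = hashes, config = config, seeds = seeds,
                 thresholds = thresholds,
                 version = as.character(utils::packageVersion("rmlmgwas")),
                 timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
            class = "run_manifest")
}
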