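# Input/output: intensity datasets and genotype-call tables.

#' @keywords internal
CHROMOSOME_LEVELS <- c(as.character(1:22), "X", "Y", "XY")

# genotype integer codes <-> symbols; 0 is reserved for no-call
GENO_SYMBOLS <- c("NC", "AA", "AB", "BB")

geno_code_to_symbol <- function(code) GENO_SYMBOLS[code + 1L]
geno_symbol_to_code <- function(sym) {
  code <- match(sym, GENO_SYMBOLS) - 1L
  if (anyNA(code)) stop("unknown genotype symbol: ",
                        paste(unique(sym[is.na(code)]), collapse = ", "))
  code
}

#' Construct an intensity dataset
#'
#' Bundles the two intensity channels with SNP annotation and sample ids.
#' Missing intensities are carried as `NA` in both channels (an explicit
#' mask); they are excluded per SNP from all downstream clustering.
#'
#' @param X numeric matrix of allele-A intensities, SNP x sample.
#' @param Y numeric matrix of allele-B intensities, same shape as `X`.
#' @param snps data.frame with columns `snp_id`, `chromosome`
#'   (one of 1..22, "X", "Y", "XY"), `position` (integer >= 0).
#' @param samples character vector of unique sample identifiers.
#' @return An object of class `IntensityDataset`: a list with elements
#'   `X`, `Y`, `snps`, `samples`.
#' @export
intensity_dataset <- function(X, Y, snps, samples) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (!identical(dim(X), dim(Y)))
    stop("X and Y must have identical dimensions")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chromosome", "position")
  if (!all(req %in% names(snps)))
    stop("snps annotation must contain columns: ", paste(req, collapse = ", "))
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position <- as.integer(snps$position)
  if (nrow(snps) != nrow(X))
    stop("annotation rows (", nrow(snps), ") != intensity rows (", nrow(X), ")")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in annotation: ",
         paste(head(unique(snps$snp_id[duplicated(snps$snp_id)])), collapse = ", "))
  bad <- setdiff(unique(snps$chromosome), CHROMOSOME_LEVELS)
  if (length(bad))
    stop("chromosome labels outside the allowed vocabulary: ",
         paste(bad, collapse = ", "))
  if (any(snps$position < 0, na.rm = TRUE)) stop("negative SNP position")
  samples <- as.character(samples)
  if (length(samples) != ncol(X))
    stop("sample ids (", length(samples), ") != intensity columns (", ncol(X), ")")
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  # finite or NA only; NA must agree between channels (a masked cell)
  if (any(is.infinite(X)) || any(is.infinite(Y)))
    stop("intensities must be finite (use NA to mask missing cells)")
  mism <- is.na(X) != is.na(Y)
  if (any(mism)) {
    X[mism] <- NA_real_; Y[mism] <- NA_real_
  }
  dimnames(X) <- dimnames(Y) <- list(snps$snp_id, samples)
  structure(list(X = X, Y = Y, snps = snps, samples = samples),
            class = "IntensityDataset")
}

#' @export
print.IntensityDataset <- function(x, ...) {
  cat("IntensityDataset:", nrow(x$X), "SNPs x", ncol(x$X), "samples\n")
  tab <- table(factor(x$snps$chromosome, levels = CHROMOSOME_LEVELS))
  tab <- tab[tab > 0]
  cat("  chromosomes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  nmask <- sum(is.na(x$X))
  if (nmask > 0) cat("  masked cells:", nmask, "\n")
  invisible(x)
}

#' Read a GenomeStudio-style final report
#'
#' Parses a long-format delimited report (one row per SNP per sample) and
#' pivots it into an [intensity_dataset()].  Column names vary between
#' exports, so a column map is accepted; the defaults match common
#' GenomeStudio headers.
#'
#' @param path path to the report file.
#' @param dialect `"tab"` or `"csv"`.
#' @param column_map named character vector mapping the roles
#'   `snp`, `sample`, `x`, `y` to header names in the file.
#' @param annotation optional data.frame (`snp_id`, `chromosome`,
#'   `position`) to attach; if omitted, all SNPs are labelled chromosome
#'   `"1"`, position 0 (calling then treats everything as autosomal).
#' @return An `IntensityDataset`.  SNPs are ordered by first appearance in
#'   the file, samples likewise.
#' @export
read_genomestudio_report <- function(path,
                                     dialect = c("tab", "csv"),
                                     column_map = c(snp = "SNP Name",
                                                    sample = "Sample ID",
                                                    x = "X Raw",
                                                    y = "Y Raw"),
                                     annotation = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tab") "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  need <- column_map[c("snp", "sample", "x", "y")]
  missing_cols <- need[!need %in% names(dt)]
  if (length(missing_cols))
    stop("report is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  snp <- as.character(dt[[need["snp"]]])
  smp <- as.character(dt[[need["sample"]]])
  xv <- as.numeric(dt[[need["x"]]])
  yv <- as.numeric(dt[[need["y"]]])
  key <- paste(snp, smp, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (SNP, sample) pair in report: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  snp_ids <- unique(snp)
  sample_ids <- unique(smp)
  if (length(key) != length(snp_ids) * length(sample_ids)) {
    grid <- outer(snp_ids, sample_ids, paste, sep = "\r")
    miss <- grid[!grid %in% key][1]
    stop("report is not a complete SNP x sample grid; first missing pair: ",
         gsub("\r", " / ", miss, fixed = TRUE))
  }
  ri <- match(snp, snp_ids); ci <- match(smp, sample_ids)
  X <- matrix(NA_real_, length(snp_ids), length(sample_ids))
  Y <- X
  X[cbind(ri, ci)] <- xv
  Y[cbind(ri, ci)] <- yv
  if (is.null(annotation)) {
    annotation <- data.frame(snp_id = snp_ids, chromosome = "1",
                             position = 0L, stringsAsFactors = FALSE)
  } else {
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
    idx <- match(snp_ids, as.character(annotation$snp_id))
    if (anyNA(idx))
      stop("annotation missing SNP(s): ",
           paste(head(snp_ids[is.na(idx)]), collapse = ", "))
    annotation <- annotation[idx, , drop = FALSE]
  }
  intensity_dataset(X, Y, annotation, sample_ids)
}

read_labelled_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[, -1, drop = FALSE], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(dt[[bad + 1]]))))[1]
    stop("non-numeric value in ", path, " at row ", badrow,
         ", column '", names(dt)[bad + 1], "'")
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read an intensity dataset from a matrix-file pair plus annotation
#'
#' Each matrix file is a delimited table with SNP ids in the first column
#' and sample ids as the header.  X and Y are aligned by intersecting and
#' reordering on shared SNP and sample ids (so row/column order in the
#' files does not matter); annotation is joined on `snp_id`.
#'
#' @param x_path,y_path paths to the allele-A and allele-B matrices.
#' @param annot_path path to the annotation table
#'   (`snp_id`, `chromosome`, `position`).
#' @return An `IntensityDataset`.
#' @export
read_matrix_pair <- function(x_path, y_path, annot_path) {
  X <- read_labelled_matrix(x_path)
  Y <- read_labelled_matrix(y_path)
  snp_ids <- intersect(rownames(X), rownames(Y))
  sample_ids <- intersect(colnames(X), colnames(Y))
  if (length(snp_ids) == 0) stop("X and Y share no SNP ids")
  if (length(sample_ids) == 0) stop("X and Y share no sample ids")
  X <- X[snp_ids, sample_ids, drop = FALSE]
  Y <- Y[snp_ids, sample_ids, drop = FALSE]
  annot <- data.table::fread(annot_path, header = TRUE, data.table = FALSE)
  idx <- match(snp_ids, as.character(annot$snp_id))
  if (anyNA(idx))
    stop("annotation missing SNP(s): ",
         paste(head(snp_ids[is.na(idx)]), collapse = ", "))
  intensity_dataset(X, Y, annot[idx, , drop = FALSE], sample_ids)
}

#' Write genotype calls to a delimited table
#'
#' One row per SNP per sample (SNP-major order): `snp_id`, `sample_id`,
#' `genotype` (AA/AB/BB/NC), `confidence` (silhouette width, 6 decimal
#' places), `predicted_k`.
#'
#' @param calls a `GenotypeCalls` object (see [call_genotypes()]).
#' @param path output file path.
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "GenotypeCalls"))
  ns <- length(calls$snp_ids); nj <- length(calls$sample_ids)
  df <- data.frame(
    snp_id = rep(calls$snp_ids, each = nj),
    sample_id = rep(calls$sample_ids, times = ns),
    genotype = geno_code_to_symbol(as.integer(t(calls$calls))),
    confidence = sprintf("%.6f", as.numeric(t(calls$confidence))),
    predicted_k = rep(calls$predicted_k, each = nj),
    stringsAsFactors = FALSE)
  df$confidence[df$confidence == "NA"] <- "NA"
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write calls to ", path, ": ",
                              conditionMessage(e)))
  invisible(ok)
}

#' Read a genotype-call table written by [write_calls()]
#'
#' @param path path to the call table.
#' @return A `GenotypeCalls` object (without `k_probabilities`).
#' @export
read_calls <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = c("snp_id", "sample_id",
                                                          "genotype")))
  snp_ids <- unique(df$snp_id)
  sample_ids <- unique(df$sample_id)
  ri <- match(df$snp_id, snp_ids); ci <- match(df$sample_id, sample_ids)
  calls <- matrix(0L, length(snp_ids), length(sample_ids),
                  dimnames = list(snp_ids, sample_ids))
  conf <- matrix(NA_real_, length(snp_ids), length(sample_ids),
                 dimnames = list(snp_ids, sample_ids))
  calls[cbind(ri, ci)] <- geno_symbol_to_code(df$genotype)
  conf[cbind(ri, ci)] <- suppressWarnings(as.numeric(df$confidence))
  pk <- df$predicted_k[match(snp_ids, df$snp_id)]
  genotype_calls(calls, conf, as.integer(pk), NULL, snp_ids, sample_ids)
}
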