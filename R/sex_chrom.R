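# Gender imputation from chromosome-Y signal and sex-restricted calling.

#' Impute sample sex from chromosome-Y average signal
#'
#' Females have no Y chromosome, so chromosome-Y probes show only
#' background hybridization while male samples carry real signal.  We take
#' each sample's median S-value over the chrY markers (excluding
#' pseudo-autosomal SNPs) and split the samples with exact 2-means; the
#' low-intensity cluster is labelled female, the high one male.  Each
#' sample's margin -- the distance from its median S to the nearer
#' cluster median -- is reported, and a warning is raised when the two
#' clusters are barely separated.
#'
#' @param signal a `NormalizedSignal`.
#' @param annotations SNP annotation data.frame (`snp_id`, `chromosome`,
#'   `position`) aligned with the rows of `signal$S`.
#' @param min_separation_sd warn when the cluster separation is below this
#'   multiple of the pooled within-cluster sd.
#' @return An object of class `SampleSex`: data.frame with columns
#'   `sample_id`, `sex` ("F"/"M"), `source`, `margin`.
#' @export
impute_gender <- function(signal, annotations, min_separation_sd = 2) {
  ychr <- which(annotations$chromosome == "Y")
  if (length(ychr) == 0)
    stop("no chromosome-Y SNPs available; provide sample sex labels instead")
  S <- signal$S[ychr, , drop = FALSE]
  if (ncol(S) < 2) stop("need at least 2 samples to impute sex")
  med <- apply(S, 2, median, na.rm = TRUE)
  fit <- kmeans_1d(med, 2L)
  if (fit$degenerate) {
    warning("all per-sample chrY medians identical; labelling every sample female")
    sex <- rep("F", length(med))
    margin <- rep(0, length(med))
  } else {
    # cluster 1 = higher center = male; compare each sample's median S to
    # the median position of each cluster and take the nearer one
    cl_med <- vapply(1:2, function(c) median(med[fit$assignments == c]),
                     numeric(1))
    d <- abs(outer(med, cl_med, "-"))
    nearer <- max.col(-d, ties.method = "first")
    sex <- ifelse(nearer == 1L, "M", "F")
    margin <- d[cbind(seq_along(med), nearer)]
    pooled_sd <- sqrt(fit$within_ss / max(1, length(med) - 2))
    sep <- abs(cl_med[1] - cl_med[2])
    if (pooled_sd > 0 && sep < min_separation_sd * pooled_sd)
      warning("chrY cluster separation (", signif(sep, 3),
              ") is below ", min_separation_sd,
              "x the within-cluster sd; sex imputation is unreliable")
  }
  structure(data.frame(sample_id = colnames(signal$S) %||%
                         paste0("sample", seq_along(med)),
                       sex = sex, source = "imputed", margin = margin,
                       stringsAsFactors = FALSE),
            class = c("SampleSex", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sample-sex file
#'
#' Two columns: `sample_id` and `sex` (F/M).  Provided labels override
#' imputation in the calling pipeline.
#'
#' @param path path to the file.
#' @param samples sample ids the labels must cover.
#' @return A `SampleSex` data.frame with `source = "provided"`.
#' @export
read_sample_sex <- function(path, samples) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("sample_id", "sex") %in% names(df)))
    stop("sex file must have columns sample_id, sex")
  df$sex <- toupper(df$sex)
  if (!all(df$sex %in% c("F", "M"))) stop("sex labels must be F or M")
  idx <- match(samples, df$sample_id)
  if (anyNA(idx))
    stop("sex file missing sample(s): ",
         paste(head(samples[is.na(idx)]), collapse = ", "))
  structure(data.frame(sample_id = samples, sex = df$sex[idx],
                       source = "provided", margin = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("SampleSex", "data.frame"))
}

#' Call genotypes on the sex chromosomes
#'
#' Non-pseudo-autosomal X and Y SNPs are called separately per sex with a
#' restricted cluster number: chrY is no-call for females and k in {1,2}
#' for males; chrX allows k in {1,2,3} for females but only k in {1,2}
#' for males (hemizygous).  The k restriction is applied by zeroing the
#' predictor's probabilities of disallowed k and renormalizing.  Male
#' clusters on X/Y map only onto the homozygote classes (nearest consensus
#' homozygote center), so males are never called AB there.
#' Pseudo-autosomal ("XY") SNPs are not handled here -- route them through
#' [call_genotypes()] with the autosomes.
#'
#' @param signal a `NormalizedSignal`.
#' @param annotations SNP annotation aligned with `signal` rows.
#' @param sex a `SampleSex` data.frame covering all samples.
#' @param consensus a `ConsensusModel`.
#' @param predictor a `KPredictor`.
#' @return A `GenotypeCalls` for the chrX/chrY (non-PAR) SNPs, in
#'   annotation order.
#' @export
call_sex_chromosomes <- function(signal, annotations, sex, consensus,
                                 predictor) {
  scope <- which(annotations$chromosome %in% c("X", "Y"))
  if (length(scope) == 0) stop("no chrX/chrY SNPs in the annotation")
  M <- signal$M
  sample_ids <- colnames(M) %||% paste0("sample", seq_len(ncol(M)))
  sx <- sex$sex[match(sample_ids, sex$sample_id)]
  if (anyNA(sx)) stop("sex labels missing for some samples")
  males <- which(sx == "M"); females <- which(sx == "F")
  ns <- length(scope); nj <- ncol(M)
  snp_ids <- annotations$snp_id[scope]
  calls <- matrix(0L, ns, nj, dimnames = list(snp_ids, sample_ids))
  conf <- matrix(NA_real_, ns, nj, dimnames = list(snp_ids, sample_ids))
  pk <- rep(NA_integer_, ns)
  small_group_logged <- FALSE
  call_group <- function(r, i, cols, allowed_k, allowed_classes) {
    if (length(cols) < 3) {
      if (!small_group_logged) {
        message("sex group with < 3 samples; its sex-chromosome calls are NC")
        small_group_logged <<- TRUE
      }
      return(NULL)
    }
    v <- M[i, ]
    vg <- rep(NA_real_, length(v)); vg[cols] <- v[cols]
    res <- call_one_snp(vg, consensus, predictor, allowed_k = allowed_k,
                        allowed_classes = allowed_classes)
    if (is.null(res)) return(NULL)
    calls[r, cols] <<- res$codes[cols]
    conf[r, cols] <<- res$confidence[cols]
    res$k
  }
  for (r in seq_len(ns)) {
    i <- scope[r]
    if (annotations$chromosome[i] == "Y") {
      # females: no call; males: k restricted to {1,2}, homozygote classes
      pk[r] <- call_group(r, i, males, allowed_k = 1:2,
                          allowed_classes = c(1L, 3L)) %||% NA_integer_
    } else {
      kf <- call_group(r, i, females, allowed_k = 1:3, allowed_classes = 1:3)
      km <- call_group(r, i, males, allowed_k = 1:2,
                       allowed_classes = c(1L, 3L))
      # record the k used for the larger group (a per-sex k is in `conf`'s
      # structure implicitly; the female k is the fuller model)
      pk[r] <- kf %||% km %||% NA_integer_
    }
  }
  genotype_calls(calls, conf, pk, NULL, snp_ids, sample_ids)
}
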