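# Synthetic two-channel intensity data with known genotypes and known k.

#' Simulation configuration
#'
#' Describes the generative model for synthetic two-channel intensities.
#' Per SNP, a minor allele frequency is drawn from `maf_spectrum` and
#' genotypes are sampled under Hardy-Weinberg proportions; each genotype
#' class sits at a per-SNP jittered M center (AA, AB, BB), a fraction of
#' SNPs has one homozygote cluster skewed toward the heterozygous
#' cluster, Gaussian within-cluster noise is added, average signal S is
#' drawn independently, optional quadratic curvature of M in S emulates
#' the intensity-dependent trend removed by loess, and the exact M/S
#' algebra is inverted to channel intensities X = 2^(S + M/2),
#' Y = 2^(S - M/2), finally scaled by a per-sample log-normal array
#' factor.
#'
#' @param n_snps,n_samples dimensions.
#' @param maf_spectrum either `c(lo, hi)` for uniform MAF sampling or a
#'   vector of length `n_snps` of fixed MAF values.
#' @param center_base genotype-class M centers (AA, AB, BB).
#' @param center_jitter_sd per-SNP sd of the class-center jitter.
#' @param skew_fraction,skew_magnitude fraction of SNPs whose AA or BB
#'   cluster is shifted toward the heterozygous cluster, and shift size.
#' @param within_cluster_sd Gaussian noise sd on M.
#' @param array_scale_sd sd of the per-sample log-normal intensity factor.
#' @param curvature_coeff quadratic M-vs-S distortion amplitude.
#' @param mean_S,S_sd average-signal distribution (log2 fluorescence).
#' @param sex_mix fraction of male samples (sex-chromosome fixtures).
#' @param chry_shift S-value separation between male chrY signal and the
#'   female background.
#' @param seed integer seed; the same config yields identical data.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_snps = 1000, n_samples = 100,
                       maf_spectrum = c(0.01, 0.5),
                       center_base = c(2, 0, -2),
                       center_jitter_sd = 0.1,
                       skew_fraction = 0.15, skew_magnitude = 0.5,
                       within_cluster_sd = 0.3,
                       array_scale_sd = 0.1,
                       curvature_coeff = 0,
                       mean_S = 10, S_sd = 0.5,
                       sex_mix = 0.5, chry_shift = 2,
                       seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), n_samples = as.integer(n_samples),
              maf_spectrum = maf_spectrum, center_base = center_base,
              center_jitter_sd = center_jitter_sd,
              skew_fraction = skew_fraction, skew_magnitude = skew_magnitude,
              within_cluster_sd = within_cluster_sd,
              array_scale_sd = array_scale_sd,
              curvature_coeff = curvature_coeff,
              mean_S = mean_S, S_sd = S_sd,
              sex_mix = sex_mix, chry_shift = chry_shift,
              seed = as.integer(seed))
  sds <- c(cfg$center_jitter_sd, cfg$within_cluster_sd, cfg$array_scale_sd,
           cfg$S_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (any(cfg$maf_spectrum <= 0 | cfg$maf_spectrum > 0.5))
    stop("maf values must lie in (0, 0.5]")
  if (length(cfg$maf_spectrum) == 2 &&
      cfg$maf_spectrum[1] > cfg$maf_spectrum[2])
    stop("maf_spectrum range must be increasing")
  if (cfg$skew_fraction < 0 || cfg$skew_fraction > 1)
    stop("skew_fraction must be in [0, 1]")
  structure(cfg, class = "SimConfig")
}

# length-2 spectra are uniform ranges; anything else is a fixed list
# (recycled to n_snps)
.draw_maf <- function(cfg) {
  if (length(cfg$maf_spectrum) == 2)
    return(runif(cfg$n_snps, cfg$maf_spectrum[1], cfg$maf_spectrum[2]))
  rep_len(cfg$maf_spectrum, cfg$n_snps)
}

# genotype codes 1 = AA (major hom), 2 = AB, 3 = BB (minor hom); allele B
# is the minor allele with frequency maf
.draw_genotypes <- function(n, maf) {
  pr <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample.int(3L, n, replace = TRUE, prob = pr)
}

.ms_to_channels <- function(M, S) {
  list(X = 2^(S + M / 2), Y = 2^(S - M / 2))
}

#' Simulate a two-channel intensity dataset with known truth
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an `IntensityDataset`, all SNPs labelled
#'   autosomal) and `truth` (a `SimTruth`: list with `genotypes` matrix in
#'   {1,2,3}, `true_k` = number of genotype classes realized per SNP,
#'   `maf` = realized minor allele frequency, `maf_drawn`, and the class
#'   centers actually used).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    ns <- cfg$n_snps; nj <- cfg$n_samples
    maf <- .draw_maf(cfg)
    G <- matrix(0L, ns, nj)
    for (i in seq_len(ns)) G[i, ] <- .draw_genotypes(nj, maf[i])
    # per-SNP class centers: base + jitter (+ skew toward AB for some SNPs)
    centers <- matrix(rep(cfg$center_base, each = ns), ns, 3) +
      matrix(rnorm(ns * 3, 0, cfg$center_jitter_sd), ns, 3)
    skewed <- runif(ns) < cfg$skew_fraction
    which_hom <- ifelse(runif(ns) < 0.5, 1L, 3L)
    shift <- ifelse(which_hom == 1L, -cfg$skew_magnitude, cfg$skew_magnitude)
    sel <- which(skewed)
    centers[cbind(sel, which_hom[sel])] <-
      centers[cbind(sel, which_hom[sel])] + shift[sel]
    M <- matrix(centers[cbind(rep(seq_len(ns), nj), as.integer(G))], ns, nj) +
      matrix(rnorm(ns * nj, 0, cfg$within_cluster_sd), ns, nj)
    S <- matrix(rnorm(ns * nj, cfg$mean_S, cfg$S_sd), ns, nj)
    M <- M + cfg$curvature_coeff * (S - cfg$mean_S)^2
    ch <- .ms_to_channels(M, S)
    arr <- rlnorm(nj, 0, cfg$array_scale_sd)
    X <- sweep(ch$X, 2, arr, `*`)
    Y <- sweep(ch$Y, 2, arr, `*`)
    snp_ids <- sprintf("snp%05d", seq_len(ns))
    sample_ids <- sprintf("s%03d", seq_len(nj))
    annot <- data.frame(snp_id = snp_ids,
                        chromosome = as.character(1L + (seq_len(ns) - 1L) %% 22L),
                        position = seq_len(ns) * 1000L,
                        stringsAsFactors = FALSE)
    dimnames(G) <- list(snp_ids, sample_ids)
    nBB <- rowSums(G == 3L); nAB <- rowSums(G == 2L)
    fB <- (2 * nBB + nAB) / (2 * nj)
    truth <- structure(list(genotypes = G,
                            true_k = apply(G, 1, function(g) length(unique(g))),
                            maf = pmin(fB, 1 - fB), maf_drawn = maf,
                            centers = centers, sex = NULL),
                       class = "SimTruth")
    list(dataset = intensity_dataset(X, Y, annot, sample_ids), truth = truth)
  })
}

#' Simulate a sex-chromosome dataset
#'
#' Generates chrX and chrY (non-PAR) SNPs for a mixed-sex cohort.  Males
#' are hemizygous: on chrX and chrY their M-values occupy only
#' homozygote-like positions (one allele, so at most 2 clusters), while
#' females show the usual diploid clusters on chrX and only background on
#' chrY (low S, noisy M).  Male chrY probes carry real signal, with S
#' shifted `chry_shift` above the female background.
#'
#' @param config a [sim_config()]; `n_snps` is split half X / half Y.
#' @return list with `dataset` and `truth`; `truth$sex` holds the
#'   per-sample labels ("F"/"M") and `truth$genotypes` codes hemizygous
#'   calls as the corresponding homozygote (1 = A, 3 = B), `NA` for
#'   female chrY.
#' @export
simulate_sex_dataset <- function(config = sim_config(n_snps = 60,
                                                     n_samples = 100)) {
  cfg <- config
  if (cfg$sex_mix <= 0 || cfg$sex_mix >= 1)
    stop("sex_mix must be in (0, 1)")
  with_seed(cfg$seed + 1L, {
    ns <- cfg$n_snps; nj <- cfg$n_samples
    nx <- ns %/% 2L; ny <- ns - nx
    sex <- ifelse(runif(nj) < cfg$sex_mix, "M", "F")
    if (!any(sex == "M")) sex[1] <- "M"
    if (!any(sex == "F")) sex[1] <- "F"
    males <- sex == "M"
    maf <- .draw_maf(cfg)
    G <- matrix(NA_integer_, ns, nj)
    M <- matrix(0, ns, nj)
    S <- matrix(rnorm(ns * nj, cfg$mean_S, cfg$S_sd), ns, nj)
    hom_centers <- cfg$center_base[c(1, 3)]
    for (i in seq_len(nx)) {              # chrX rows 1..nx
      gF <- .draw_genotypes(sum(!males), maf[i])
      G[i, !males] <- gF
      M[i, !males] <- cfg$center_base[gF]
      alleleB <- rbinom(sum(males), 1, maf[i])
      G[i, males] <- ifelse(alleleB == 1L, 3L, 1L)
      M[i, males] <- hom_centers[ifelse(alleleB == 1L, 2L, 1L)]
    }
    for (i in nx + seq_len(ny)) {         # chrY rows
      alleleB <- rbinom(sum(males), 1, maf[i])
      G[i, males] <- ifelse(alleleB == 1L, 3L, 1L)
      M[i, males] <- hom_centers[ifelse(alleleB == 1L, 2L, 1L)]
      # female background: no target sequence, so low signal and noisy M
      S[i, !males] <- S[i, !males] - cfg$chry_shift
      M[i, !males] <- 0
    }
    M <- M + matrix(rnorm(ns * nj, 0, cfg$within_cluster_sd), ns, nj)
    ch <- .ms_to_channels(M, S)
    arr <- rlnorm(nj, 0, cfg$array_scale_sd)
    X <- sweep(ch$X, 2, arr, `*`)
    Y <- sweep(ch$Y, 2, arr, `*`)
    snp_ids <- c(sprintf("snpX%04d", seq_len(nx)), sprintf("snpY%04d", seq_len(ny)))
    sample_ids <- sprintf("s%03d", seq_len(nj))
    annot <- data.frame(snp_id = snp_ids,
                        chromosome = c(rep("X", nx), rep("Y", ny)),
                        position = seq_len(ns) * 1000L,
                        stringsAsFactors = FALSE)
    dimnames(G) <- list(snp_ids, sample_ids)
    truth <- structure(list(genotypes = G,
                            true_k = apply(G, 1, function(g)
                              length(unique(g[!is.na(g)]))),
                            maf = maf[seq_len(ns)], maf_drawn = maf,
                            centers = NULL, sex = setNames(sex, sample_ids)),
                       class = "SimTruth")
    list(dataset = intensity_dataset(X, Y, annot, sample_ids), truth = truth)
  })
}

#' Write a simulated dataset to matrix-pair + annotation + truth files
#'
#' Emits `X.tsv`, `Y.tsv`, `annotation.tsv`, `truth_genotypes.tsv` and
#' `truth_k.tsv` (snp_id, true_k, maf) under `dir`, readable back with
#' [read_matrix_pair()].
#'
#' @param sim result of [simulate_dataset()] / [simulate_sex_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_simulated <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(x = file.path(dir, "X.tsv"), y = file.path(dir, "Y.tsv"),
             annot = file.path(dir, "annotation.tsv"),
             genotypes = file.path(dir, "truth_genotypes.tsv"),
             k = file.path(dir, "truth_k.tsv"))
  wm <- function(m, path) {
    df <- data.frame(snp_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wm(sim$dataset$X, paths["x"])
  wm(sim$dataset$Y, paths["y"])
  write.table(sim$dataset$snps, paths["annot"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  wm(sim$truth$genotypes, paths["genotypes"])
  write.table(data.frame(snp_id = rownames(sim$truth$genotypes),
                         true_k = sim$truth$true_k, maf = sim$truth$maf),
              paths["k"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
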