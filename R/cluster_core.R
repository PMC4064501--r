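# Exact 1-D k-means, consensus model, SNP-level features and silhouettes.

#' Exact one-dimensional k-means
#'
#' Finds the globally optimal k-means partition of a numeric vector by
#' dynamic programming over contiguous partitions of the sorted values
#' (in one dimension the optimal clusters are always intervals).  The
#' result is deterministic -- no random restarts.  `NA` values (the
#' missing-data mask) receive `NA` assignments and do not enter the fit.
#'
#' @param values numeric vector (one SNP's M-values across samples).
#' @param k requested number of clusters, 1..3.
#' @return An object of class `ClusterFit`: list with `k` (clusters
#'   actually fitted), `requested_k`, `centers` (cluster means in
#'   decreasing order, so cluster 1 sits at the highest M), `assignments`
#'   (per-input cluster index, `NA` for masked entries), `sizes`,
#'   `within_ss`, `degenerate` (TRUE when fewer than `k` distinct values
#'   forced a smaller fit), and `genotype_map` (filled by
#'   [map_clusters_to_genotypes()]).
#' @export
kmeans_1d <- function(values, k) {
  k <- as.integer(k)
  if (k < 1L || k > 3L) stop("k must be 1, 2 or 3")
  kmeans_1d_all(values, k)[[k]]
}

# All fits for k = 1..kmax in one DP pass.  Returns a list indexed by k;
# if the data support fewer distinct values than some k, that slot holds a
# degenerate fit on the largest feasible k.
kmeans_1d_all <- function(values, kmax = 3L) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) == 0) stop("no unmasked values")
  nd <- length(unique(v))
  keff_max <- min(kmax, nd)
  ord <- order(v)
  fits_dp <- kmeans1d_dp_cpp(v[ord], keff_max)
  out <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    keff <- min(k, keff_max)
    f <- fits_dp[[keff]]
    starts <- f$starts
    ends <- c(starts[-1] - 1L, length(v))
    asc_assign <- rep.int(seq_len(keff), ends - starts + 1L)
    # relabel so cluster 1 has the highest center
    assign_sorted <- (keff + 1L) - asc_assign
    assignments <- rep(NA_integer_, length(values))
    assignments[ok][ord] <- assign_sorted
    centers <- rev(f$centers)
    sizes <- rev(ends - starts + 1L)
    out[[k]] <- structure(list(
      k = keff, requested_k = k, centers = centers,
      assignments = assignments, sizes = sizes,
      within_ss = f$within_ss, degenerate = keff < k,
      genotype_map = if (keff == 3L) 1:3 else NULL),
      class = "ClusterFit")
  }
  out
}

#' @export
print.ClusterFit <- function(x, ...) {
  cat("ClusterFit: k =", x$k,
      if (x$degenerate) paste0("(degenerate; requested ", x$requested_k, ")"),
      "\n  centers:", paste(signif(x$centers, 4), collapse = ", "),
      "\n  sizes:", paste(x$sizes, collapse = ", "),
      " within_ss:", signif(x$within_ss, 6), "\n")
  if (!is.null(x$genotype_map))
    cat("  genotype map:", paste(GENO_SYMBOLS[x$genotype_map + 1L],
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the consensus cluster model
#'
#' Applies 3-means to each SNP's M-values separately, collects the per-SNP
#' center vectors (AA, AB, BB), and summarizes them by their elementwise
#' median `mu` (the consensus genotype-class centers) and sample
#' variance-covariance matrix `V`.  For speed, at most `max_snps` SNPs are
#' used (a seeded subsample; medians stabilize quickly).
#'
#' @param M log-ratio matrix, SNP x sample.
#' @param snp_subset optional integer vector of row indices to use.
#' @param max_snps subsample cap.
#' @param seed seed for the subsample.
#' @return An object of class `ConsensusModel`: list with `mu`
#'   (strictly decreasing 3-vector), `V` (3x3 symmetric), `n_snps` used.
#' @export
estimate_consensus <- function(M, snp_subset = NULL, max_snps = 20000,
                               seed = 1L) {
  M <- as.matrix(M)
  idx <- if (is.null(snp_subset)) seq_len(nrow(M)) else sort(unique(as.integer(snp_subset)))
  if (length(idx) == 0) stop("empty SNP subset")
  if (length(idx) > max_snps)
    idx <- sort(with_seed(seed, sample(idx, max_snps)))
  centers <- matrix(NA_real_, length(idx), 3)
  for (r in seq_along(idx)) {
    v <- M[idx[r], ]
    if (length(unique(v[!is.na(v)])) < 3) next
    centers[r, ] <- kmeans_1d(v, 3L)$centers
  }
  keep <- complete.cases(centers)
  if (!any(keep))
    stop("no SNP in the subset has >= 3 distinct values; cannot estimate consensus")
  centers <- centers[keep, , drop = FALSE]
  mu <- apply(centers, 2, median)
  if (!(mu[1] > mu[2] && mu[2] > mu[3]))
    warning("consensus centers are not strictly decreasing; ",
            "check normalization or cluster separation")
  V <- if (nrow(centers) > 1) cov(centers) else matrix(0, 3, 3)
  structure(list(mu = mu, V = (V + t(V)) / 2, n_snps = nrow(centers)),
            class = "ConsensusModel")
}

#' @export
print.ConsensusModel <- function(x, ...) {
  cat("ConsensusModel (", x$n_snps, " SNPs)\n  mu (AA, AB, BB): ",
      paste(signif(x$mu, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# order-preserving injections of k cluster indices into the 3 genotype
# classes (1 = AA, 2 = AB, 3 = BB)
.injections <- list(
  list(1L, 2L, 3L),
  list(c(1L, 2L), c(2L, 3L), c(1L, 3L)),
  list(1:3))

#' Map fitted clusters to genotype classes
#'
#' Chooses, among the order-preserving injections of the k fitted cluster
#' centers into the three consensus genotype classes, the one minimizing
#' the squared distance to the consensus centers.  With k = 3 this is the
#' identity; with k = 2 the candidates are (AA,AB), (AB,BB) and (AA,BB);
#' with k = 1 the single cluster maps to the nearest class.
#'
#' @param fit a `ClusterFit` with decreasing centers.
#' @param consensus a `ConsensusModel`.
#' @param allowed optional subset of genotype classes the clusters may map
#'   to (used for hemizygous male X/Y calling, where AB is excluded).
#' @return The `ClusterFit` with `genotype_map` populated.
#' @export
map_clusters_to_genotypes <- function(fit, consensus, allowed = 1:3) {
  k <- fit$k
  cands <- .injections[[k]]
  cands <- Filter(function(cls) all(cls %in% allowed), cands)
  if (length(cands) == 0) stop("no admissible genotype mapping for k = ", k)
  costs <- vapply(cands, function(cls)
    sum((fit$centers - consensus$mu[cls])^2), numeric(1))
  fit$genotype_map <- cands[[which.min(costs)]]
  fit
}

#' Residual sum of squares feature
#'
#' The total within-cluster sum of squares of the fit -- a tightness
#' measure that is non-increasing in k for exact 1-D k-means.
#'
#' @param values the vector the fit was computed on (unused; kept for a
#'   uniform feature signature).
#' @param fit a `ClusterFit`.
#' @return non-negative scalar.
#' @export
feature_R <- function(values, fit) fit$within_ss

#' Mahalanobis-distance feature
#'
#' Measures the bias of the fitted cluster centers relative to the
#' consensus positions: D = (x - mu_sub) V_sub^-1 (x - mu_sub)', where the
#' subscript takes the consensus subvector/submatrix of the genotype
#' classes the clusters map to.  A pseudo-inverse is used when the
#' submatrix is singular.
#'
#' @param fit a `ClusterFit` with `genotype_map` populated.
#' @param consensus a `ConsensusModel`.
#' @return non-negative scalar.
#' @export
feature_D <- function(fit, consensus) {
  cls <- fit$genotype_map
  if (is.null(cls)) stop("genotype_map not populated; run map_clusters_to_genotypes")
  d <- fit$centers - consensus$mu[cls]
  Vs <- consensus$V[cls, cls, drop = FALSE]
  inv <- tryCatch(solve(Vs), error = function(e) MASS::ginv(Vs))
  max(0, drop(t(d) %*% inv %*% d))
}

#' Genotype counts and Hardy-Weinberg expectations for a fit
#'
#' Counts calls per genotype class under the fit's genotype map (classes
#' with no mapped cluster count zero), derives the empirical major-allele
#' frequency p = (2 N_AA + N_AB) / (2 n), and the Hardy-Weinberg expected
#' proportions (p^2, 2p(1-p), (1-p)^2).
#'
#' @param fit a `ClusterFit` with `genotype_map` populated.
#' @param hemizygous if TRUE the samples carry a single allele copy (male
#'   X/Y), so the expected proportions are the haploid (p, 0, 1 - p) with
#'   p the major-allele frequency of the single-copy calls, rather than
#'   the diploid Hardy-Weinberg (p^2, 2p(1-p), (1-p)^2).
#' @return An object of class `GenotypeCounts`: list with `N` (3-vector),
#'   `n`, `p`, `r`.
#' @export
genotype_counts <- function(fit, hemizygous = FALSE) {
  if (is.null(fit$genotype_map)) stop("genotype_map not populated")
  N <- c(0, 0, 0)
  N[fit$genotype_map] <- fit$sizes
  n <- sum(N)
  if (hemizygous) {
    p <- (N[1] + 0.5 * N[2]) / n
    r <- c(p, 0, 1 - p)
  } else {
    p <- (2 * N[1] + N[2]) / (2 * n)
    r <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  }
  structure(list(N = N, n = n, p = p, r = r), class = "GenotypeCounts")
}

#' Hardy-Weinberg goodness-of-fit feature
#'
#' Chi-square-style statistic H = sum_l (N_l - n r_l)^2 / (n r_l) over the
#' genotype classes.  Classes whose expected count is (numerically) zero
#' contribute nothing when the observed count is also zero -- this happens
#' at p = 0 or 1 -- and are otherwise guarded by a small floor so H stays
#' finite.
#'
#' @param counts a `GenotypeCounts`.
#' @return non-negative scalar.
#' @export
feature_H <- function(counts) {
  if (counts$n <= 0) stop("no calls")
  expd <- counts$n * counts$r
  h <- 0
  for (l in 1:3) {
    if (expd[l] < 1e-12) {
      if (counts$N[l] > 0) h <- h + counts$N[l]^2 / max(expd[l], 1e-12)
    } else {
      h <- h + (counts$N[l] - expd[l])^2 / expd[l]
    }
  }
  h
}

# canonical feature order used everywhere
FEATURE_NAMES <- c("R1", "R2", "R3", "D1", "D2", "D3", "H2", "H3")

#' Compute the 8 cluster-quality features for one SNP
#'
#' Runs exact 1-D k-means for k = 1, 2, 3 on the SNP's M-values, maps each
#' fit's clusters to genotype classes against the consensus, and evaluates
#' the residual sum of squares (R1..R3), Mahalanobis distance to the
#' consensus centers (D1..D3) and Hardy-Weinberg statistics (H2, H3; not
#' defined for k = 1, where a single cluster carries no HWE information).
#'
#' @param values numeric vector of M-values (one SNP).
#' @param consensus a `ConsensusModel`.
#' @param return_fits also return the three mapped `ClusterFit`s.
#' @param allowed_classes genotype classes clusters may map to
#'   (`c(1L, 3L)` for hemizygous male X/Y groups; k = 3 then falls back to
#'   the unrestricted mapping, but k = 3 is disallowed for such groups
#'   anyway).
#' @param hemizygous compute H against haploid expected proportions; see
#'   [genotype_counts()].
#' @return Named numeric vector (R1,R2,R3,D1,D2,D3,H2,H3) with attribute
#'   `degenerate` (logical 3-vector per k); if `return_fits`, a list
#'   `list(features, fits)`.
#' @export
compute_features <- function(values, consensus, return_fits = FALSE,
                             allowed_classes = 1:3, hemizygous = FALSE) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("need at least 3 unmasked values")
  fits <- kmeans_1d_all(values, 3L)
  feats <- setNames(numeric(8), FEATURE_NAMES)
  degen <- logical(3)
  for (k in 1:3) {
    amap <- if (fits[[k]]$k <= length(allowed_classes)) allowed_classes
            else 1:3
    fit <- map_clusters_to_genotypes(fits[[k]], consensus, allowed = amap)
    fits[[k]] <- fit
    degen[k] <- fit$degenerate
    feats[paste0("R", k)] <- feature_R(values, fit)
    feats[paste0("D", k)] <- feature_D(fit, consensus)
    if (k >= 2)
      feats[paste0("H", k)] <-
        feature_H(genotype_counts(fit, hemizygous = hemizygous))
  }
  attr(feats, "degenerate") <- degen
  if (return_fits) list(features = feats, fits = fits) else feats
}

# sum of |x - y| over all y in the sorted vector `sv` (with prefix sums),
# evaluated for each element of x; O((|x| + |sv|) log |sv|)
.sum_absdist <- function(x, sv, prefix) {
  m <- length(sv)
  idx <- findInterval(x, sv)
  total <- prefix[m + 1]
  x * idx - prefix[idx + 1] + (total - prefix[idx + 1]) - x * (m - idx)
}

#' Silhouette widths as call confidences
#'
#' For each unmasked point, the silhouette width SW = (b - w) / max(w, b),
#' where w is the mean absolute distance to the other members of its own
#' cluster and b the smallest mean absolute distance to the members of any
#' other cluster.  Points in singleton clusters get SW = 0 (the PAM
#' convention).  Requires a fit with k >= 2; for k = 1 fits see
#' [confidence_k1()].
#'
#' @param values numeric vector the fit was computed on.
#' @param fit a `ClusterFit` with `k >= 2`.
#' @return numeric vector aligned with `values` (NA where masked), in
#'   \[-1, 1\].
#' @export
silhouette_widths <- function(values, fit) {
  if (fit$k < 2) stop("silhouette width needs k >= 2; use confidence_k1")
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  asg <- fit$assignments
  k <- fit$k
  sorted <- lapply(seq_len(k), function(c) sort(values[ok & asg == c]))
  prefixes <- lapply(sorted, function(s) c(0, cumsum(s)))
  sizes <- vapply(sorted, length, integer(1))
  idxok <- which(ok)
  sw <- numeric(length(idxok))
  x <- values[idxok]; a <- asg[idxok]
  dist_to <- matrix(0, length(x), k)
  for (c in seq_len(k))
    dist_to[, c] <- .sum_absdist(x, sorted[[c]], prefixes[[c]])
  for (p in seq_along(x)) {
    c <- a[p]
    if (sizes[c] == 1L) { sw[p] <- 0; next }
    w <- dist_to[p, c] / (sizes[c] - 1)   # excludes self (|x - x| = 0)
    b <- min(dist_to[p, -c] / sizes[-c])
    sw[p] <- if (max(w, b) == 0) 0 else (b - w) / max(w, b)
  }
  out[idxok] <- sw
  out
}

#' Confidence score for single-cluster fits
#'
#' Silhouette width is undefined when only one cluster is fitted.  As a
#' monotone within-cluster tightness score in (0, 1\] we use
#' 1 / (1 + |value - center| / MAD), where MAD is the median absolute
#' deviation of the SNP's values (falling back to the mean absolute
#' deviation, then to 1 at an exactly constant SNP).
#'
#' @param values numeric vector.
#' @param fit a `ClusterFit` with `k == 1`.
#' @return numeric vector aligned with `values` (NA where masked).
#' @export
confidence_k1 <- function(values, fit) {
  if (fit$k != 1) stop("confidence_k1 requires a k = 1 fit")
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  scale <- mad(values[ok])
  if (scale == 0) scale <- mean(abs(values[ok] - fit$centers[1]))
  dev <- abs(values[ok] - fit$centers[1])
  out[ok] <- if (scale == 0) 1 else 1 / (1 + dev / scale)
  out
}
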