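test_that("exact 1-D k-means matches hand-worked examples", {
  f <- kmeans_1d(c(0, 0, 10, 10), 2)
  expect_equal(f$centers, c(10, 0))
  expect_equal(f$within_ss, 0)
  f2 <- kmeans_1d(c(1, 2, 3, 10), 2)
  expect_equal(f2$centers, c(10, 2))
  expect_equal(f2$within_ss, 2)
  expect_equal(f2$assignments, c(2L, 2L, 2L, 1L))
  # k = 1 closed form
  v <- c(3.5, -1, 0.25, 7)
  f3 <- kmeans_1d(v, 1)
  expect_equal(f3$centers, mean(v))
  expect_equal(f3$within_ss, sum((v - mean(v))^2))
})

test_that("DP k-means agrees with exhaustive enumeration (property)", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    v <- round(rnorm(n, sample(c(0, 5), 1), sample(c(0.5, 3), 1)), 2)
    for (k in 1:min(3, length(unique(v)))) {
      expect_equal(kmeans_1d(v, k)$within_ss, enum_kmeans_ss(v, k),
                   tolerance = 1e-9,
                   label = paste("ss for", paste(v, collapse = ","), "k =", k))
    }
  }
})

test_that("k-means handles masks and degenerate inputs deterministically", {
  v <- c(NA, 1, NA, 1, 5)
  f <- kmeans_1d(v, 2)
  expect_equal(f$assignments, c(NA, 2L, NA, 2L, 1L))
  d <- kmeans_1d(c(3, 3, 3), 2)
  expect_true(d$degenerate)
  expect_equal(d$k, 1L)
  expect_equal(d$requested_k, 2L)
  expect_identical(kmeans_1d(v, 2), kmeans_1d(v, 2))
})

test_that("R is non-increasing in k (nested optimal partitions)", {
  set.seed(7)
  for (rep in 1:30) {
    v <- rnorm(sample(5:60, 1), 0, sample(c(0.3, 1, 4), 1))
    fits <- lapply(1:3, function(k) kmeans_1d(v, k))
    r <- vapply(fits, function(f) feature_R(v, f), numeric(1))
    expect_true(r[1] >= r[2] - 1e-12 && r[2] >= r[3] - 1e-12)
  }
})

test_that("consensus estimation recovers exact and noisy centers", {
  # every SNP shares centers (1, 0, -1) exactly
  M <- matrix(rep(c(1, 1, 0, 0, -1, -1), 50), 50, 6, byrow = TRUE)
  cm <- estimate_consensus(M)
  expect_equal(cm$mu, c(1, 0, -1))
  expect_equal(cm$V, matrix(0, 3, 3))
  # jittered centers around (2, 0, -2), sd 0.1, 2000 SNPs
  set.seed(11)
  cent <- cbind(rnorm(2000, 2, 0.1), rnorm(2000, 0, 0.1), rnorm(2000, -2, 0.1))
  Mj <- cent[, c(1, 1, 1, 2, 2, 2, 3, 3, 3)]
  cmj <- estimate_consensus(Mj)
  expect_lt(max(abs(cmj$mu - c(2, 0, -2))), 0.02)
  expect_true(all(abs(diag(cmj$V) - 0.01) < 0.2 * 0.01 + 2e-4))
  # permuting the subset leaves mu and V unchanged
  cmp <- estimate_consensus(Mj, snp_subset = rev(seq_len(2000)))
  expect_equal(cmp$mu, cmj$mu)
  expect_equal(cmp$V, cmj$V)
})

test_that("cluster-to-genotype mapping minimizes distance to consensus", {
  cons <- toy_consensus()
  f2 <- structure(list(k = 2L, centers = c(2.1, -0.05), sizes = c(5L, 5L),
                       within_ss = 0, degenerate = FALSE),
                  class = "ClusterFit")
  expect_equal(map_clusters_to_genotypes(f2, cons)$genotype_map, c(1L, 2L))
  f1 <- structure(list(k = 1L, centers = -1.9, sizes = 10L, within_ss = 0,
                       degenerate = FALSE), class = "ClusterFit")
  expect_equal(map_clusters_to_genotypes(f1, cons)$genotype_map, 3L)
  f3 <- kmeans_1d(c(rep(9, 3), rep(5, 3), rep(1, 3)), 3)
  expect_equal(map_clusters_to_genotypes(f3, cons)$genotype_map, 1:3)
  # restricted mapping (hemizygous): AB excluded
  expect_equal(map_clusters_to_genotypes(f1, cons, allowed = c(1L, 3L))$genotype_map,
               3L)
  expect_equal(map_clusters_to_genotypes(f2, cons, allowed = c(1L, 3L))$genotype_map,
               c(1L, 3L))
})

test_that("Mahalanobis feature matches the quadratic form", {
  cons <- toy_consensus(V = diag(3))
  fit <- structure(list(k = 3L, centers = cons$mu + c(1, 0, 0),
                        sizes = c(1L, 1L, 1L), within_ss = 0,
                        degenerate = FALSE, genotype_map = 1:3),
                   class = "ClusterFit")
  expect_equal(feature_D(fit, cons), 1)
  fit$centers <- cons$mu
  expect_equal(feature_D(fit, cons), 0)
  # general V: compare with explicit inverse; invariance to reordering
  set.seed(2)
  A <- matrix(rnorm(9), 3); V <- crossprod(A) + diag(3) * 0.1
  cons2 <- toy_consensus(V = V)
  d <- c(0.3, -0.2, 0.5)
  fit$centers <- cons2$mu + d
  expect_equal(feature_D(fit, cons2), drop(t(d) %*% solve(V) %*% d),
               tolerance = 1e-9)
  perm <- c(2, 3, 1)
  cons3 <- toy_consensus(mu = cons2$mu[perm], V = V[perm, perm])
  fit3 <- fit; fit3$centers <- cons2$mu[perm] + d[perm]
  expect_equal(feature_D(fit3, cons3), feature_D(fit, cons2),
               tolerance = 1e-9)
  # singular V falls back to the pseudo-inverse without error
  consS <- toy_consensus(V = matrix(1, 3, 3))
  expect_true(is.finite(feature_D(fit, consS)))
})

test_that("Hardy-Weinberg feature matches hand computations and the oracle", {
  mk <- function(N) structure(list(N = N, n = sum(N),
                                   p = (2 * N[1] + N[2]) / (2 * sum(N)),
                                   r = NULL), class = "GenotypeCounts")
  hwe <- function(N) { c0 <- mk(N); p <- c0$p
    c0$r <- c(p^2, 2 * p * (1 - p), (1 - p)^2); c0 }
  expect_equal(feature_H(hwe(c(49, 42, 9))), 0)
  expect_equal(feature_H(hwe(c(50, 0, 50))), 100)
  # monomorphic: expected counts 0 where observed 0 contribute nothing
  expect_equal(feature_H(hwe(c(100, 0, 0))), 0)
  set.seed(13)
  for (rep in 1:200) {
    N <- as.integer(rmultinom(1, sample(10:500, 1),
                              prob = runif(3, 0.01, 1)))
    expect_equal(feature_H(hwe(N)), chisq_hwe(N), tolerance = 1e-9)
    expect_gte(feature_H(hwe(N)), 0)
  }
})

test_that("genotype_counts derives p and r from the mapped clusters", {
  cons <- toy_consensus()
  v <- c(rep(2, 6), rep(0, 3), rep(-2, 1))
  fit <- map_clusters_to_genotypes(kmeans_1d(v, 3), cons)
  gc <- genotype_counts(fit)
  expect_equal(gc$N, c(6, 3, 1))
  expect_equal(gc$p, (12 + 3) / 20)
  expect_equal(sum(gc$r), 1)
  # k = 2 fit: the unmapped class counts zero
  fit2 <- map_clusters_to_genotypes(kmeans_1d(v[1:9], 2), cons)
  gc2 <- genotype_counts(fit2)
  expect_equal(gc2$N, c(6, 3, 0))
})

test_that("compute_features behaves on archetypal SNPs", {
  cons <- toy_consensus()
  set.seed(21)
  # three tight clusters at consensus positions in HWE proportions
  v3 <- c(rnorm(25, 2, 0.05), rnorm(50, 0, 0.05), rnorm(25, -2, 0.05))
  f3 <- compute_features(v3, cons)
  expect_lt(f3["R3"], 1); expect_lt(f3["D3"], 1); expect_lt(f3["H3"], 1)
  expect_gt(f3["R1"], 100); expect_gt(f3["R2"], 50)
  # single tight cluster at mu_BB
  v1 <- rnorm(80, -2, 0.05)
  f1 <- compute_features(v1, cons)
  expect_lt(f1["R1"], 1); expect_lt(f1["D1"], 0.5)
  # deterministic, named, and permutation-invariant
  expect_identical(compute_features(v3, cons), compute_features(v3, cons))
  fperm <- compute_features(sample(v3), cons)
  expect_equal(unclass(fperm), unclass(f3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(names(f3), c("R1", "R2", "R3", "D1", "D2", "D3",
                                "H2", "H3"))
  expect_error(compute_features(c(1, 2), cons), "3 unmasked")
})

test_that("silhouette widths match hand computation and brute force", {
  v <- c(0, 0.1, 5.0)
  fit <- kmeans_1d(v, 2)
  sw <- silhouette_widths(v, fit)
  expect_equal(sw[1], (5 - 0.1) / 5)      # w = 0.1, b = 5
  expect_equal(sw[3], 0)                  # singleton convention
  # two identical points alone in their cluster, far from others: SW = 1
  v2 <- c(3, 3, -4, -4.2)
  sw2 <- silhouette_widths(v2, kmeans_1d(v2, 2))
  expect_equal(sw2[1], 1)
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    v <- rnorm(n, 0, 2)
    if (runif(1) < 0.3) v[sample(n, 2)] <- NA
    if (length(unique(v[!is.na(v)])) < 3) next
    k <- sample(2:3, 1)
    fit <- kmeans_1d(v, k)
    expect_equal(silhouette_widths(v, fit),
                 brute_silhouette(v, fit$assignments), tolerance = 1e-9)
  }
  expect_error(silhouette_widths(v, kmeans_1d(v, 1)), "k >= 2")
})

test_that("k = 1 confidence is a monotone tightness score in (0, 1]", {
  set.seed(5)
  v <- rnorm(50, -2, 0.3)
  fit <- kmeans_1d(v, 1)
  cf <- confidence_k1(v, fit)
  expect_true(all(cf > 0 & cf <= 1))
  ord <- order(abs(v - fit$centers[1]))
  expect_true(all(diff(cf[ord]) <= 1e-12))
  # constant SNP: confidence 1 everywhere
  vc <- rep(2, 10)
  expect_true(all(confidence_k1(vc, kmeans_1d(vc, 1)) == 1))
})
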