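# synthetic feature matrix whose label is determined by thresholds
make_sep_features <- function(n, seed = 1) {
  set.seed(seed)
  k <- sample(1:3, n, replace = TRUE)
  f <- matrix(abs(rnorm(n * 8, 2, 0.5)), n, 8,
              dimnames = list(NULL, c("R1", "R2", "R3", "D1", "D2", "D3",
                                      "H2", "H3")))
  f[, "R3"] <- ifelse(k == 3, 0.01, 10) + rnorm(n, 0, 0.001)
  f[, "R2"] <- ifelse(k >= 2, 0.01, 10) + rnorm(n, 0, 0.001)
  f[, "R1"] <- pmax(f[, "R1"], f[, "R2"])
  list(features = f, k = k)
}

test_that("training on separable features reaches >= 0.99 accuracy", {
  d <- make_sep_features(600, seed = 4)
  pred <- quiet_train(d$features, d$k, seed = 1)
  pk <- predict_k(d$features, pred)
  expect_gte(mean(pk$k == d$k), 0.99)
  # refit with the same data/seed gives identical coefficients
  pred2 <- quiet_train(d$features, d$k, seed = 1)
  expect_identical(pred$coefficients, pred2$coefficients)
})

test_that("degenerate training inputs are rejected", {
  d <- make_sep_features(50, seed = 2)
  expect_error(train_k_predictor(d$features, rep(2L, 50)), "single class")
  expect_error(train_k_predictor(d$features[, 1:5], d$k[1:50]), "8 columns")
  f <- d$features; f[1, 1] <- Inf
  expect_error(train_k_predictor(f, d$k), "finite")
})

test_that("ordered logistic family fits and predicts coherently", {
  d <- make_sep_features(600, seed = 9)
  pred <- quiet_train(d$features, d$k, family = "ordered_logistic", seed = 1)
  pk <- predict_k(d$features, pred)
  expect_gte(mean(pk$k == d$k), 0.95)
  expect_equal(rowSums(pk$probabilities), rep(1, 600), tolerance = 1e-9)
})

test_that("predicted probabilities are a simplex; ties break to larger k", {
  d <- make_sep_features(300, seed = 6)
  pred <- quiet_train(d$features, d$k, seed = 1)
  set.seed(8)
  f <- matrix(abs(rnorm(1000 * 8, 1, 2)), 1000, 8)
  pk <- predict_k(f, pred)
  expect_true(all(pk$probabilities >= 0 & pk$probabilities <= 1))
  expect_equal(rowSums(pk$probabilities), rep(1, 1000), tolerance = 1e-9)
  # all-zero coefficients force uniform probabilities and the k = 3 tie rule
  flat <- pred
  flat$coefficients <- matrix(0, 9, 2)
  pf <- predict_k(f[1:5, ], flat)
  expect_equal(pf$probabilities, matrix(1 / 3, 5, 3), tolerance = 1e-12)
  expect_equal(pf$k, rep(3L, 5))
  # restricted k: disallowed classes get zero mass
  pr <- predict_k(f[1:5, ], pred, allowed_k = 1:2)
  expect_true(all(pr$probabilities[, 3] == 0))
  expect_equal(rowSums(pr$probabilities), rep(1, 5), tolerance = 1e-9)
  expect_true(all(pr$k <= 2))
})

test_that("predictor parameter files round-trip loss-free", {
  d <- make_sep_features(300, seed = 3)
  for (fam in c("regular_logistic", "ordered_logistic")) {
    pred <- quiet_train(d$features, d$k, family = fam, seed = 7)
    path <- tempfile()
    write_predictor(pred, path)
    expect_match(readLines(path)[2], fam)
    back <- read_predictor(path)
    expect_equal(back$coefficients, pred$coefficients, tolerance = 1e-15)
    expect_identical(predict_k(d$features, back)$k,
                     predict_k(d$features, pred)$k)
  }
  expect_error(read_predictor(write_report_fixture(list(c("a", "b", "1", "2")))),
               "predictor file")
})

# one small simulated world shared by the calling tests
sim_world <- function(seed = 17, n_snps = 120, n_samples = 150, ...) {
  sim <- simulate_dataset(sim_config(n_snps = n_snps, n_samples = n_samples,
                                     seed = seed, ...))
  sig <- normalize_intensities(sim$dataset)
  cons <- estimate_consensus(sig$M, seed = 1)
  fe <- t(vapply(seq_len(n_snps),
                 function(i) compute_features(sig$M[i, ], cons),
                 numeric(8)))
  pred <- quiet_train(fe, sim$truth$true_k, seed = 1)
  list(sim = sim, sig = sig, cons = cons, pred = pred)
}

test_that("calling recovers well-separated simulated genotypes", {
  w <- sim_world(seed = 17)
  calls <- call_genotypes(w$sig, w$cons, w$pred)
  common <- which(w$sim$truth$maf_drawn > 0.3)   # every class well populated
  expect_gt(length(common), 20)
  expect_true(all(calls$predicted_k[common] == 3L))
  expect_gte(mean(calls$calls[common, ] ==
                    w$sim$truth$genotypes[common, ]), 0.99)
  # silhouette confidences recorded for every call
  expect_true(all(is.finite(calls$confidence)))
})

test_that("monomorphic SNPs come back as k = 1 single-genotype calls", {
  # mixed spectrum: enough rare SNPs to realize k = 1, plus common SNPs so
  # the consensus centers are anchored by genuine 3-cluster signal
  mafs <- c(rep(0.002, 50), seq(0.1, 0.5, length.out = 100))
  w <- sim_world(seed = 23, n_snps = 150, maf_spectrum = mafs)
  mono <- which(w$sim$truth$true_k == 1)
  expect_gt(length(mono), 10)
  calls <- call_genotypes(w$sig, w$cons, w$pred)
  expect_gte(mean(calls$predicted_k[mono] == 1L), 0.9)
  hit <- mono[calls$predicted_k[mono] == 1L]
  expect_true(all(calls$calls[hit, ] == w$sim$truth$genotypes[hit, ]))
})

test_that("a duplicated sample column does not disturb other samples' calls", {
  w <- sim_world(seed = 29, n_snps = 40)
  calls <- call_genotypes(w$sig, w$cons, w$pred)
  sig2 <- w$sig
  sig2$M <- cbind(sig2$M, sig2$M[, 1])
  sig2$S <- cbind(sig2$S, sig2$S[, 1])
  colnames(sig2$M) <- colnames(sig2$S) <- c(colnames(w$sig$M), "dup")
  calls2 <- call_genotypes(sig2, w$cons, w$pred)
  # the duplicate re-weights each SNP's k-means objective, so an isolated
  # boundary point may legitimately flip; everything else must be stable
  same <- calls2$calls[, seq_len(ncol(w$sig$M))] == calls$calls
  expect_gte(mean(same), 0.999)
  expect_equal(calls2$predicted_k, calls$predicted_k)
})

test_that("SNPs with < 3 unmasked samples are emitted all-NC", {
  w <- sim_world(seed = 31, n_snps = 30)
  sig <- w$sig
  sig$M[5, -(1:2)] <- NA
  calls <- call_genotypes(sig, w$cons, w$pred)
  expect_true(all(calls$calls[5, ] == 0L))
  expect_true(is.na(calls$predicted_k[5]))
})

test_that("drop-rate masking removes exactly the lowest-confidence calls", {
  calls <- genotype_calls(matrix(1L, 2, 5), matrix(seq(0.1, 1, 0.1), 2, 5),
                          c(3L, 3L), NULL, c("a", "b"), paste0("s", 1:5))
  expect_identical(apply_drop_rate(calls, 0), calls)
  half <- apply_drop_rate(calls, 0.5)
  expect_equal(sum(half$calls == 0L), 5)
  expect_true(all(half$confidence[half$calls == 0L] <= 0.5))
  # monotone nesting of the masked set in the rate
  prev <- rep(FALSE, 10)
  for (r in c(0.1, 0.3, 0.5, 0.8)) {
    cur <- apply_drop_rate(calls, r)$calls == 0L
    expect_true(all(cur[prev]))
    prev <- cur
  }
  expect_error(apply_drop_rate(calls, 1), "rate")
})

test_that("concordance curves report accuracy and honest NAs", {
  truth <- matrix(c(1L, 2L, 3L, 1L), 2, 2,
                  dimnames = list(c("a", "b"), c("s1", "s2")))
  calls <- genotype_calls(truth, matrix(0.9, 2, 2), c(3L, 3L), NULL,
                          c("a", "b"), c("s1", "s2"))
  cc <- concordance_curve(calls, truth, rates = c(0, 0.25))
  expect_true(all(cc$overall$accuracy == 1))
  # one error in 100 comparable calls
  set.seed(1)
  big_truth <- matrix(sample(1:3, 100, TRUE), 10, 10)
  wrong <- big_truth
  wrong[1, 1] <- if (big_truth[1, 1] == 1L) 2L else 1L
  calls2 <- genotype_calls(wrong, matrix(runif(100, 0.5, 1), 10, 10),
                           rep(3L, 10), NULL, paste0("r", 1:10),
                           paste0("c", 1:10))
  cc2 <- concordance_curve(calls2, big_truth, rates = 0)
  expect_equal(cc2$overall$accuracy, 0.99)
  # all calls NC: accuracy NA, not 0
  nc <- genotype_calls(matrix(0L, 2, 2), matrix(NA_real_, 2, 2),
                       c(NA_integer_, NA_integer_), NULL,
                       c("a", "b"), c("s1", "s2"))
  ccn <- concordance_curve(nc, truth, rates = 0)
  expect_true(is.na(ccn$overall$accuracy))
})

test_that("minor-allele errors only degrade the minor stratum", {
  set.seed(41)
  # truth: B is the minor allele everywhere
  truth <- matrix(sample(1:3, 400, TRUE, prob = c(0.7, 0.25, 0.05)), 20, 20)
  conf <- matrix(runif(400, 0.5, 1), 20, 20)
  perfect <- genotype_calls(truth, conf, rep(3L, 20), NULL,
                            paste0("r", 1:20), paste0("c", 1:20))
  base <- concordance_curve(perfect, truth, rates = 0)$by_allele
  # flip the minor-allele homozygotes only
  bad <- truth
  bad[truth == 3L] <- 1L
  flipped <- genotype_calls(bad, conf, rep(3L, 20), NULL,
                            paste0("r", 1:20), paste0("c", 1:20))
  cc <- concordance_curve(flipped, truth, rates = 0)$by_allele
  major_b <- base[base$stratum == "major", "accuracy"]
  major_f <- cc[cc$stratum == "major", "accuracy"]
  minor_f <- cc[cc$stratum == "minor", "accuracy"]
  expect_equal(major_f, major_b)
  expect_lt(minor_f, base[base$stratum == "minor", "accuracy"])
})
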