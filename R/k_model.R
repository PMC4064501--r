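# Logistic-regression prediction of the cluster number k, genotype calling,
# drop-rate masking and concordance evaluation.

#' Container for genotype calls
#'
#' @param calls integer matrix SNP x sample, codes 0 = NC, 1 = AA,
#'   2 = AB, 3 = BB.
#' @param confidence numeric matrix of call confidences (silhouette widths;
#'   `NA` where no confidence was computed).
#' @param predicted_k integer vector, per-SNP predicted cluster number.
#' @param k_probabilities numeric matrix SNP x 3 of class probabilities
#'   (may be `NULL`).
#' @param snp_ids,sample_ids identifiers.
#' @return An object of class `GenotypeCalls`.
#' @export
genotype_calls <- function(calls, confidence, predicted_k,
                           k_probabilities, snp_ids, sample_ids) {
  storage.mode(calls) <- "integer"
  if (any(!(calls %in% 0:3)))
    stop("genotype codes outside {0,1,2,3}")
  structure(list(calls = calls, confidence = confidence,
                 predicted_k = as.integer(predicted_k),
                 k_probabilities = k_probabilities,
                 snp_ids = as.character(snp_ids),
                 sample_ids = as.character(sample_ids)),
            class = "GenotypeCalls")
}

#' @export
print.GenotypeCalls <- function(x, ...) {
  cat("GenotypeCalls:", length(x$snp_ids), "SNPs x",
      length(x$sample_ids), "samples\n")
  tab <- table(factor(x$calls, levels = 0:3, labels = GENO_SYMBOLS))
  cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  cat("  predicted k:",
      paste(names(table(x$predicted_k)), table(x$predicted_k),
            sep = ":", collapse = "  "), "\n")
  invisible(x)
}

# ---- multinomial / ordered logistic fitting -------------------------------

.softmax_probs <- function(Z, beta) {
  eta <- cbind(Z %*% beta, 0)          # class 3 is the reference
  eta <- eta - apply(eta, 1, max)
  e <- exp(eta)
  e / rowSums(e)
}

.fit_multinomial <- function(Z, y, lambda = 0, maxit = 500, init = NULL) {
  nclass <- 3L
  npar <- ncol(Z) * (nclass - 1L)
  Yind <- matrix(0, nrow(Z), nclass)
  Yind[cbind(seq_len(nrow(Z)), y)] <- 1
  pen_mask <- rbind(0, matrix(1, ncol(Z) - 1, nclass - 1L))  # no intercept penalty
  fn <- function(par) {
    beta <- matrix(par, ncol(Z), nclass - 1L)
    P <- .softmax_probs(Z, beta)
    -sum(log(pmax(P[cbind(seq_len(nrow(Z)), y)], 1e-300))) +
      0.5 * lambda * sum((pen_mask * beta)^2)
  }
  gr <- function(par) {
    beta <- matrix(par, ncol(Z), nclass - 1L)
    P <- .softmax_probs(Z, beta)
    G <- t(Z) %*% (P[, 1:2, drop = FALSE] - Yind[, 1:2, drop = FALSE]) +
      lambda * (pen_mask * beta)
    as.numeric(G)
  }
  start <- if (is.null(init)) numeric(npar) else as.numeric(init)
  opt <- optim(start, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  list(beta = matrix(opt$par, ncol(Z), nclass - 1L),
       convergence = opt$convergence, value = opt$value)
}

.ordered_probs <- function(X, par) {
  p <- ncol(X)
  z1 <- par[1]; z2 <- par[1] + exp(par[2])
  eta <- drop(X %*% par[-(1:2)])
  c1 <- plogis(z1 - eta); c2 <- plogis(z2 - eta)
  cbind(pmax(c1, 1e-300), pmax(c2 - c1, 1e-300), pmax(1 - c2, 1e-300))
}

.fit_ordered <- function(X, y, lambda = 0, maxit = 1000) {
  fn <- function(par) {
    P <- .ordered_probs(X, par)
    -sum(log(P[cbind(seq_along(y), y)])) + 0.5 * lambda * sum(par[-(1:2)]^2)
  }
  opt <- optim(c(-1, log(2), numeric(ncol(X))), fn, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  list(par = opt$par, convergence = opt$convergence, value = opt$value)
}

#' Train the cluster-number predictor
#'
#' Fits a logistic-regression model predicting the per-SNP cluster number
#' k in {1,2,3} from the 8 cluster-quality features
#' (R1,R2,R3,D1,D2,D3,H2,H3).  The default `regular_logistic` family is a
#' multinomial logit with k = 3 as the reference class;
#' `ordered_logistic` is a proportional-odds model over k ordered
#' 1 < 2 < 3 (consistent with increasing dose of the alternate allele).
#' Features are standardized internally and the transform is stored with
#' the model.  On apparent complete separation (exploding coefficients)
#' the model is refitted with a small ridge penalty (1e-4) and a warning.
#'
#' @param features numeric matrix, SNP x 8, columns in `FEATURE_NAMES`
#'   order.
#' @param true_k integer vector of labels in {1,2,3}.
#' @param family `"regular_logistic"` or `"ordered_logistic"`.
#' @param seed integer recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return An object of class `KPredictor`.
#' @export
train_k_predictor <- function(features, true_k,
                              family = c("regular_logistic",
                                         "ordered_logistic"),
                              seed = 1L) {
  family <- match.arg(family)
  features <- as.matrix(features)
  if (ncol(features) != 8)
    stop("features must have 8 columns (", paste(FEATURE_NAMES, collapse = ","), ")")
  if (!all(is.finite(features))) stop("features must be finite")
  y <- as.integer(true_k)
  if (length(y) != nrow(features)) stop("label length mismatch")
  if (!all(y %in% 1:3)) stop("labels must be in {1,2,3}")
  if (length(unique(y)) < 2)
    stop("training labels contain a single class; cannot fit")
  center <- colMeans(features)
  scl <- apply(features, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(features, center = center, scale = scl)
  ridge <- 0
  if (family == "regular_logistic") {
    Z <- cbind(1, Xs)
    fit <- .fit_multinomial(Z, y, lambda = 0)
    if (fit$convergence != 0 || max(abs(fit$beta)) > 30) {
      # non-convergence of the unpenalized fit almost always means the
      # likelihood is unbounded (separation); stabilize and retry
      warning("apparent complete separation; refitting with ridge penalty 1e-4")
      ridge <- 1e-4
      fit <- .fit_multinomial(Z, y, lambda = ridge, maxit = 3000,
                              init = pmax(pmin(fit$beta, 30), -30))
      if (fit$convergence != 0)
        stop("ridge-stabilized multinomial fit did not converge (optim code ",
             fit$convergence, ", deviance ", signif(2 * fit$value, 6), ")")
    }
    coefs <- fit$beta
  } else {
    fit <- .fit_ordered(Xs, y, lambda = 0)
    if (fit$convergence != 0 || max(abs(fit$par[-(1:2)])) > 30) {
      warning("apparent complete separation; refitting with ridge penalty 1e-4")
      ridge <- 1e-4
      fit <- .fit_ordered(Xs, y, lambda = ridge, maxit = 5000)
      if (fit$convergence != 0)
        stop("ridge-stabilized ordered fit did not converge (optim code ",
             fit$convergence, ", deviance ", signif(2 * fit$value, 6), ")")
    }
    coefs <- fit$par
  }
  pred <- structure(list(family = family, coefficients = coefs,
                         feature_names = FEATURE_NAMES,
                         center = center, scale = scl,
                         n_train = length(y), seed = as.integer(seed),
                         ridge = ridge, converged = TRUE),
                    class = "KPredictor")
  pk <- predict_k(features, pred)
  pred$training_accuracy <- mean(pk$k == y)
  pred
}

#' @export
print.KPredictor <- function(x, ...) {
  cat("KPredictor (", x$family, "), trained on ", x$n_train, " SNPs",
      if (x$ridge > 0) paste0(", ridge ", x$ridge), "\n", sep = "")
  if (!is.null(x$training_accuracy))
    cat("  training accuracy:", round(x$training_accuracy, 4), "\n")
  invisible(x)
}

#' Predict the cluster number for one or more SNPs
#'
#' @param features numeric 8-vector or SNP x 8 matrix.
#' @param predictor a `KPredictor`.
#' @param allowed_k subset of {1,2,3}; probabilities of disallowed k are
#'   zeroed and the rest renormalized (used for sex-restricted calling).
#' @return list with `k` (integer vector; ties in the argmax broken
#'   toward larger k) and `probabilities` (matrix SNP x 3, rows sum to 1).
#' @export
predict_k <- function(features, predictor, allowed_k = 1:3) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  Xs <- scale(features, center = predictor$center, scale = predictor$scale)
  P <- if (predictor$family == "regular_logistic") {
    .softmax_probs(cbind(1, Xs), predictor$coefficients)
  } else {
    .ordered_probs(Xs, predictor$coefficients)
  }
  P <- P / rowSums(P)
  if (!identical(sort(unique(as.integer(allowed_k))), 1:3)) {
    P[, setdiff(1:3, allowed_k)] <- 0
    rs <- rowSums(P)
    zero <- rs == 0
    if (any(zero)) P[zero, allowed_k] <- 1 / length(allowed_k)
    P <- P / rowSums(P)
  }
  k <- max.col(P, ties.method = "last")   # ties break toward larger k
  list(k = as.integer(k), probabilities = unname(P))
}

# Call one SNP given its M-values: features -> k -> k-means -> genotype map
# -> codes + confidences.  Returns NULL when fewer than 3 usable values.
call_one_snp <- function(values, consensus, predictor,
                         allowed_k = 1:3, allowed_classes = 1:3,
                         fixed_k = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 3 || length(unique(values[ok])) < 1) return(NULL)
  hemi <- length(allowed_classes) < 3
  cf <- tryCatch(compute_features(values, consensus, return_fits = TRUE,
                                  allowed_classes = allowed_classes,
                                  hemizygous = hemi),
                 error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  if (is.null(fixed_k)) {
    pr <- predict_k(cf$features, predictor, allowed_k = allowed_k)
    k <- pr$k; probs <- pr$probabilities[1, ]
  } else {
    k <- as.integer(fixed_k); probs <- rep(NA_real_, 3)
  }
  fit <- cf$fits[[k]]
  if (is.null(fit$genotype_map) || !all(fit$genotype_map %in% allowed_classes))
    fit <- map_clusters_to_genotypes(fit, consensus,
                                     allowed = allowed_classes)
  codes <- rep(0L, length(values))
  codes[ok] <- fit$genotype_map[fit$assignments[ok]]
  conf <- if (fit$k >= 2) silhouette_widths(values, fit)
          else confidence_k1(values, fit)
  list(codes = codes, confidence = conf, k = k, probabilities = probs)
}

#' Call genotypes for autosomal and pseudo-autosomal SNPs
#'
#' For each SNP in scope: compute the 8 features, predict k, refit exact
#' 1-D k-means at the predicted k, map the clusters to genotype classes
#' via the consensus model, and record per-sample genotype codes and
#' silhouette confidences.  SNPs with fewer than 3 unmasked samples are
#' emitted as all-NC.
#'
#' @param signal a `NormalizedSignal`.
#' @param consensus a `ConsensusModel`.
#' @param predictor a `KPredictor`.
#' @param snp_scope integer vector of row indices to call (default: all
#'   rows; the command-line driver passes autosomes + PAR here and routes
#'   X/Y through [call_sex_chromosomes()]).
#' @param snp_ids,sample_ids identifiers (default from `signal` dimnames).
#' @param fixed_k optionally force a fixed cluster number for every SNP
#'   (bypassing the predictor) -- the non-adaptive baseline.
#' @return A `GenotypeCalls` covering the SNPs in `snp_scope`.
#' @export
call_genotypes <- function(signal, consensus, predictor, snp_scope = NULL,
                           snp_ids = NULL, sample_ids = NULL,
                           fixed_k = NULL) {
  M <- signal$M
  if (is.null(snp_scope)) snp_scope <- seq_len(nrow(M))
  if (is.null(snp_ids))
    snp_ids <- if (!is.null(rownames(M))) rownames(M)[snp_scope]
               else paste0("snp", snp_scope)
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(colnames(M))) colnames(M)
                  else paste0("sample", seq_len(ncol(M)))
  ns <- length(snp_scope); nj <- ncol(M)
  calls <- matrix(0L, ns, nj, dimnames = list(snp_ids, sample_ids))
  conf <- matrix(NA_real_, ns, nj, dimnames = list(snp_ids, sample_ids))
  pk <- rep(NA_integer_, ns)
  probs <- matrix(NA_real_, ns, 3)
  for (r in seq_len(ns)) {
    res <- call_one_snp(M[snp_scope[r], ], consensus, predictor,
                        fixed_k = fixed_k)
    if (is.null(res)) next
    calls[r, ] <- res$codes
    conf[r, ] <- res$confidence
    pk[r] <- res$k
    probs[r, ] <- res$probabilities
  }
  genotype_calls(calls, conf, pk, probs, snp_ids, sample_ids)
}

#' Mask the lowest-confidence calls
#'
#' Sets the lowest-confidence fraction `rate` of all non-NC calls to NC.
#' The threshold is a single global confidence quantile across the whole
#' dataset (not per SNP); exactly `round(rate * n_calls)` calls are
#' masked, ties broken deterministically by position, so masked sets are
#' nested across increasing rates.
#'
#' @param calls a `GenotypeCalls`.
#' @param rate fraction in \[0, 1).
#' @return A `GenotypeCalls` with the masked entries set to code 0
#'   (their confidences remain recorded).
#' @export
apply_drop_rate <- function(calls, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1)
    stop("rate must be a single number in [0, 1)")
  if (rate == 0) return(calls)
  idx <- which(calls$calls != 0L)
  m <- round(rate * length(idx))
  if (m > 0) {
    cf <- calls$confidence[idx]
    cf[is.na(cf)] <- -Inf                 # callable but unconfident: drop first
    drop_idx <- idx[order(cf, idx)[seq_len(m)]]
    calls$calls[drop_idx] <- 0L
  }
  calls
}

# per-SNP minor-allele summary from a truth matrix (codes 1/2/3, NA ok)
.truth_maf <- function(truth) {
  nAA <- rowSums(truth == 1L, na.rm = TRUE)
  nAB <- rowSums(truth == 2L, na.rm = TRUE)
  nBB <- rowSums(truth == 3L, na.rm = TRUE)
  n <- nAA + nAB + nBB
  fB <- ifelse(n > 0, (2 * nBB + nAB) / (2 * n), NA_real_)
  minor_hom <- ifelse(fB <= 0.5, 3L, 1L)
  list(maf = pmin(fB, 1 - fB), minor_hom = minor_hom,
       major_hom = ifelse(minor_hom == 3L, 1L, 3L))
}

#' Accuracy versus drop rate against a truth matrix
#'
#' For each requested drop rate, masks the lowest-confidence calls and
#' computes concordance with the truth over the comparable entries
#' (called, and truth non-missing).  Also reports accuracy stratified by
#' truth minor-allele-frequency bin and by whether the true genotype
#' involves the minor allele (heterozygote or minor homozygote) or only
#' the major allele.
#'
#' @param calls a `GenotypeCalls`.
#' @param truth integer matrix SNP x sample with codes 1/2/3 (NA =
#'   missing); aligned to `calls` by snp/sample ids when dimnames are
#'   present, by position otherwise.
#' @param rates numeric vector of drop rates in \[0, 1).
#' @param maf_breaks bin edges for the MAF stratification.
#' @return list of data.frames `overall`, `by_maf`, `by_allele`.
#'   Undefined accuracies (no comparable calls) are `NA`, never 0.
#' @export
concordance_curve <- function(calls, truth, rates = c(0, 0.01, 0.02, 0.05),
                              maf_breaks = c(0, 0.01, 0.05, 0.5)) {
  truth <- as.matrix(truth)
  if (!is.null(rownames(truth)) && !is.null(calls$snp_ids) &&
      all(calls$snp_ids %in% rownames(truth))) {
    cols <- if (!is.null(colnames(truth)) &&
                all(calls$sample_ids %in% colnames(truth)))
      calls$sample_ids else seq_len(ncol(truth))
    truth <- truth[calls$snp_ids, cols, drop = FALSE]
  }
  if (!identical(dim(truth), dim(calls$calls)))
    stop("truth matrix cannot be aligned with the calls")
  storage.mode(truth) <- "integer"
  ms <- .truth_maf(truth)
  bin <- cut(ms$maf, breaks = maf_breaks, include.lowest = TRUE)
  minor_mask <- truth == 2L | truth == matrix(ms$minor_hom, nrow(truth),
                                              ncol(truth))
  overall <- by_maf <- by_allele <- list()
  for (rt in rates) {
    masked <- apply_drop_rate(calls, rt)
    comp <- masked$calls != 0L & !is.na(truth)
    hit <- comp & masked$calls == truth
    acc <- function(sel) {
      n <- sum(comp & sel)
      c(n = n, accuracy = if (n == 0) NA_real_ else sum(hit & sel) / n)
    }
    a <- acc(TRUE)
    overall[[length(overall) + 1]] <-
      data.frame(rate = rt, n_compared = a["n"], accuracy = a["accuracy"])
    for (b in levels(bin)) {
      sel <- matrix(!is.na(bin) & bin == b, nrow(truth), ncol(truth))
      a <- acc(sel)
      by_maf[[length(by_maf) + 1]] <-
        data.frame(rate = rt, maf_bin = b, n_compared = a["n"],
                   accuracy = a["accuracy"])
    }
    for (s in c("major", "minor")) {
      sel <- if (s == "minor") minor_mask else
        (!is.na(truth) & truth == matrix(ms$major_hom, nrow(truth), ncol(truth)))
      sel[is.na(sel)] <- FALSE
      a <- acc(sel)
      by_allele[[length(by_allele) + 1]] <-
        data.frame(rate = rt, stratum = s, n_compared = a["n"],
                   accuracy = a["accuracy"])
    }
  }
  out <- list(overall = do.call(rbind, overall),
              by_maf = do.call(rbind, by_maf),
              by_allele = do.call(rbind, by_allele))
  rownames(out$overall) <- rownames(out$by_maf) <- rownames(out$by_allele) <- NULL
  out
}

# ---- predictor serialization ---------------------------------------------

#' Write a trained predictor to a plain-text parameter file
#'
#' Self-describing tab-delimited format with a versioned header; see
#' [read_predictor()] for the inverse.
#'
#' @param predictor a `KPredictor`.
#' @param path output path.
#' @export
write_predictor <- function(predictor, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(..., sep = "\t"), con)
  wl("#adaptcall_predictor", "1")
  wl("family", predictor$family)
  wl("features", paste(predictor$feature_names, collapse = ","))
  wl("center", paste(sprintf("%.17g", predictor$center), collapse = ","))
  wl("scale", paste(sprintf("%.17g", predictor$scale), collapse = ","))
  wl("n_train", predictor$n_train)
  wl("seed", predictor$seed)
  wl("ridge", sprintf("%.17g", predictor$ridge))
  wl("coefficients",
     paste(sprintf("%.17g", as.numeric(predictor$coefficients)),
           collapse = ","))
  invisible(path)
}

#' Read a predictor parameter file written by [write_predictor()]
#'
#' @param path path to the parameter file.
#' @return A `KPredictor`.
#' @export
read_predictor <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#adaptcall_predictor"))
    stop("not an adaptcall predictor file: ", path)
  kv <- strsplit(lines[-1], "\t", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, character(1), 2),
                   vapply(kv, `[`, character(1), 1))
  family <- vals[["family"]]
  coefs <- as.numeric(strsplit(vals[["coefficients"]], ",")[[1]])
  if (family == "regular_logistic") coefs <- matrix(coefs, ncol = 2)
  structure(list(family = family, coefficients = coefs,
                 feature_names = strsplit(vals[["features"]], ",")[[1]],
                 center = as.numeric(strsplit(vals[["center"]], ",")[[1]]),
                 scale = as.numeric(strsplit(vals[["scale"]], ",")[[1]]),
                 n_train = as.integer(vals[["n_train"]]),
                 seed = as.integer(vals[["seed"]]),
                 ridge = as.numeric(vals[["ridge"]]), converged = TRUE),
            class = "KPredictor")
}
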