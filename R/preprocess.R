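# Between-sample normalization and the M/S transform.

#' Between-sample quantile normalization of one channel
#'
#' Replaces each column's sorted values by the across-column mean of order
#' statistics (the usual between-array quantile normalization), or, when a
#' `reference` distribution is supplied, maps each column onto that
#' reference (interpolating when lengths differ).  Ranks are preserved
#' within columns; tied values receive the mean of the reference quantiles
#' they span.  `NA` cells (the missing-data mask) are left `NA` and ignored
#' when forming ranks.
#'
#' @param channel numeric matrix, SNP x sample.
#' @param reference optional numeric vector giving the target distribution.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(channel, reference = NULL) {
  channel <- as.matrix(channel)
  if (ncol(channel) < 1) stop("need at least one column")
  n <- nrow(channel)
  all_na <- colSums(!is.na(channel)) == 0
  if (any(all_na)) {
    nm <- colnames(channel)[all_na]
    if (is.null(nm)) nm <- which(all_na)
    stop("column entirely masked: ", paste(nm, collapse = ", "))
  }
  if (any(channel < 0, na.rm = TRUE)) stop("negative intensities")
  if (is.null(reference)) {
    if (anyNA(channel)) {
      # mean of per-column quantiles on a common probability grid
      probs <- (seq_len(n) - 1) / (n - 1)
      qs <- apply(channel, 2, function(col)
        quantile(col, probs = probs, na.rm = TRUE, names = FALSE, type = 7))
      reference <- rowMeans(qs)
    } else {
      reference <- rowMeans(apply(channel, 2, sort))
    }
  } else {
    reference <- sort(as.numeric(reference))
  }
  nref <- length(reference)
  out <- channel
  for (j in seq_len(ncol(channel))) {
    ok <- !is.na(channel[, j])
    v <- channel[ok, j]
    r <- rank(v, ties.method = "average")
    m <- length(v)
    # map average rank r in [1, m] to a position on the reference grid
    pos <- if (m == 1) (nref + 1) / 2 else 1 + (r - 1) * (nref - 1) / (m - 1)
    out[ok, j] <- approx(seq_len(nref), reference, xout = pos,
                         rule = 2)$y
  }
  out
}

#' Log-ratio / average-signal transform
#'
#' Computes M = log2(X*) - log2(Y*) and S = (log2(X*) + log2(Y*)) / 2 from
#' normalized channel intensities.  Values below `floor` are clamped to
#' `floor` before taking logs so that zero intensities stay finite.
#'
#' @param Xstar,Ystar normalized intensity matrices, same shape.
#' @param floor positive clamp applied before log2 (fluorescence units).
#' @return An object of class `NormalizedSignal`: list with matrices
#'   `Xstar`, `Ystar` (clamped), `M`, `S`.
#' @export
compute_MS <- function(Xstar, Ystar, floor = 1.0) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0)
    stop("floor must be a single positive number")
  Xstar <- as.matrix(Xstar); Ystar <- as.matrix(Ystar)
  if (!identical(dim(Xstar), dim(Ystar)))
    stop("Xstar and Ystar must have identical dimensions")
  Xc <- pmax(Xstar, floor); Yc <- pmax(Ystar, floor)
  lX <- log2(Xc); lY <- log2(Yc)
  structure(list(Xstar = Xc, Ystar = Yc, M = lX - lY, S = (lX + lY) / 2),
            class = "NormalizedSignal")
}

#' @export
print.NormalizedSignal <- function(x, ...) {
  cat("NormalizedSignal:", nrow(x$M), "SNPs x", ncol(x$M), "samples\n")
  cat("  M range:", paste(signif(range(x$M, na.rm = TRUE), 3), collapse = " .. "),
      " S range:", paste(signif(range(x$S, na.rm = TRUE), 3), collapse = " .. "),
      "\n")
  invisible(x)
}

#' Per-cluster loess correction of intensity-dependent curvature
#'
#' Within each of the three provisional genotype clusters (pooled across
#' SNPs), fits a loess curve of M on S and subtracts it, removing the
#' intensity-dependent trend in the log-ratios.  The consensus center
#' estimate is then added back to the upper (AA) and lower (BB) clusters
#' and the heterozygous cluster is re-centered at zero.
#'
#' @param signal a `NormalizedSignal`.
#' @param provisional integer matrix, same shape as `signal$M`, of
#'   per-SNP 3-means class assignments (1 = AA, 2 = AB, 3 = BB), e.g. from
#'   [provisional_assignments()].
#' @param consensus a `ConsensusModel` (see [estimate_consensus()]); its
#'   `mu` supplies the add-back centers.
#' @param span loess smoothing fraction.
#' @param subsample_cap maximum number of points per cluster used to fit
#'   the curve (the correction is still applied to all points).
#' @param seed seed for the fitting subsample.
#' @return A `NormalizedSignal` with corrected `M` (and `Xstar`, `Ystar`
#'   recomputed so the algebraic identities still hold).
#' @export
loess_correct <- function(signal, provisional, consensus, span = 0.3,
                          subsample_cap = 50000, seed = 1L) {
  stopifnot(inherits(signal, "NormalizedSignal"))
  M <- signal$M; S <- signal$S
  if (!identical(dim(provisional), dim(M)))
    stop("provisional assignments must match the signal dimensions")
  Mnew <- M
  addback <- c(consensus$mu[1], 0, consensus$mu[3])
  for (cl in 1:3) {
    idx <- which(provisional == cl & !is.na(M))
    if (length(idx) < 10) {
      warning("cluster ", cl, " has ", length(idx),
              " points; loess correction skipped for it")
      next
    }
    fit_idx <- idx
    if (length(idx) > subsample_cap)
      fit_idx <- with_seed(seed + cl, sample(idx, subsample_cap))
    df <- data.frame(m = M[fit_idx], s = S[fit_idx])
    fit <- loess(m ~ s, data = df, span = span, degree = 1,
                 family = "gaussian")
    srange <- range(df$s)
    sclamp <- pmin(pmax(S[idx], srange[1]), srange[2])
    trend <- predict(fit, newdata = data.frame(s = sclamp))
    resid <- M[idx] - trend
    if (cl == 2L) resid <- resid - median(resid)   # re-center AB at 0
    Mnew[idx] <- resid + addback[cl]
  }
  lX <- signal$S + Mnew / 2
  lY <- signal$S - Mnew / 2
  structure(list(Xstar = 2^lX, Ystar = 2^lY, M = Mnew, S = signal$S),
            class = "NormalizedSignal")
}

#' Per-SNP provisional 3-means class assignments
#'
#' Runs exact 1-D 3-means on each SNP's M-values and labels the clusters
#' 1 = AA (highest M), 2 = AB, 3 = BB.  SNPs with fewer than 3 distinct
#' values keep `NA` assignments.
#'
#' @param M log-ratio matrix.
#' @return integer matrix of the same shape.
#' @export
provisional_assignments <- function(M) {
  out <- matrix(NA_integer_, nrow(M), ncol(M), dimnames = dimnames(M))
  for (i in seq_len(nrow(M))) {
    v <- M[i, ]
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 3) next
    fit <- kmeans_1d(v, 3L)
    out[i, ok] <- fit$assignments[ok]
  }
  out
}

#' Normalization pipeline
#'
#' Applies the configured between-sample normalization to the raw channels
#' and returns the M/S signal.  The default (`"quantile"`) is quantile
#' normalization of each channel separately without loess, which is the
#' combination found to call most accurately; `"quantile_loess"` adds the
#' per-cluster curvature correction; `"none"` only takes logs.
#'
#' @param dataset an `IntensityDataset`.
#' @param normalization one of `"quantile"`, `"quantile_loess"`, `"none"`.
#' @param floor clamp before log2, see [compute_MS()].
#' @param loess_span,subsample_cap,seed passed to [loess_correct()].
#' @param reference_x,reference_y optional per-quantile reference vectors.
#' @return A `NormalizedSignal`.
#' @export
normalize_intensities <- function(dataset,
                                  normalization = c("quantile",
                                                    "quantile_loess",
                                                    "none"),
                                  floor = 1.0, loess_span = 0.3,
                                  subsample_cap = 50000, seed = 1L,
                                  reference_x = NULL, reference_y = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(dataset, "IntensityDataset"))
  if (normalization == "none") {
    return(compute_MS(dataset$X, dataset$Y, floor = floor))
  }
  Xs <- quantile_normalize(dataset$X, reference_x)
  Ys <- quantile_normalize(dataset$Y, reference_y)
  sig <- compute_MS(Xs, Ys, floor = floor)
  if (normalization == "quantile_loess") {
    prov <- provisional_assignments(sig$M)
    cons <- estimate_consensus(sig$M, seed = seed)
    sig <- loess_correct(sig, prov, cons, span = loess_span,
                         subsample_cap = subsample_cap, seed = seed)
  }
  sig
}
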