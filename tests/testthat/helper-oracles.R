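# Independent brute-force oracles used to check the fast implementations.
# These deliberately share no code with the package internals.

# exhaustive 1-D k-means: enumerate every contiguous partition of the
# sorted values into k intervals and return the minimal within-SS
enum_kmeans_ss <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  ss <- function(x) if (length(x) <= 1) 0 else sum((x - mean(x))^2)
  if (k == 1) return(ss(v))
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (cu in cuts) {
    bounds <- c(0, cu, n)
    tot <- 0
    for (j in seq_len(k)) tot <- tot + ss(v[(bounds[j] + 1):bounds[j + 1]])
    if (tot < best) best <- tot
  }
  best
}

# O(n^2) silhouette widths from pairwise absolute distances
brute_silhouette <- function(values, assignments) {
  ok <- !is.na(values)
  out <- rep(NA_real_, length(values))
  idx <- which(ok)
  d <- abs(outer(values[idx], values[idx], "-"))
  a <- assignments[idx]
  for (p in seq_along(idx)) {
    own <- which(a == a[p])
    if (length(own) == 1) { out[idx[p]] <- 0; next }
    w <- sum(d[p, setdiff(own, p)]) / (length(own) - 1)
    b <- min(vapply(setdiff(unique(a), a[p]),
                    function(c) mean(d[p, a == c]), numeric(1)))
    out[idx[p]] <- if (max(w, b) == 0) 0 else (b - w) / max(w, b)
  }
  out
}

# chi-square goodness-of-fit against Hardy-Weinberg expectations, written
# straight from the definition
chisq_hwe <- function(N) {
  n <- sum(N)
  p <- (2 * N[1] + N[2]) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  keep <- e > 1e-12
  sum((N[keep] - e[keep])^2 / e[keep])
}

# training with the expected complete-separation warning silenced
quiet_train <- function(...) suppressWarnings(train_k_predictor(...))

# a small consensus model with convenient numbers
toy_consensus <- function(mu = c(2, 0, -2), V = diag(3) * 0.01) {
  structure(list(mu = mu, V = V, n_snps = NA_integer_),
            class = "ConsensusModel")
}

# tiny wide-format GenomeStudio-style report written to a temp file
write_report_fixture <- function(rows, sep = "\t", path = tempfile()) {
  header <- paste(c("SNP Name", "Sample ID", "X Raw", "Y Raw"),
                  collapse = sep)
  lines <- vapply(rows, function(r) paste(r, collapse = sep), character(1))
  writeLines(c(header, lines), path)
  path
}
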