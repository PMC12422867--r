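# Independent oracles used to pin down implementation behaviour.

# Affine-gap local alignment score by exhaustive dynamic programming
# (gap of length k costs open + k * ext). Small inputs only.
sw_oracle_score <- function(a, b, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F_[i, j])
    }
  }
  max(H)
}

# Two-sided exact binomial p-value as a sum of tail probabilities.
binom_p_oracle <- function(k, n, p = 0.5) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= dbinom(k, n, p) * (1 + 1e-7)])
}

# Brute-force max-sensitivity-plus-specificity threshold search over all
# observed-score midpoints; returns list(threshold, j).
youden_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  us <- sort(unique(scores))
  cand <- (us[-length(us)] + us[-1]) / 2
  j <- sapply(cand, function(thr)
    mean(scores[labels] >= thr) + mean(scores[!labels] < thr))
  best <- max(j)
  list(threshold = min(cand[j >= best - 1e-12]), j = best)
}

# Random DNA string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
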