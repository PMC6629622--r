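# Independent brute-force oracles and tiny fixture generators.

# random state sequence (optionally with MISSING seconds)
random_seq <- function(len, p_missing = 0) {
  s <- sample(state_alphabet(), len, replace = TRUE)
  if (p_missing > 0) s[runif(len) < p_missing] <- "MISSING"
  s
}

# element-wise brute-force chi-squared distance: explicit double sum over
# intervals and states, independent of the vectorized implementation
oracle_chi2 <- function(p, q, marginal) {
  total <- 0
  for (k in seq_len(nrow(p))) {
    for (s in colnames(p)) {
      if (marginal[[s]] > 0) {
        total <- total + (p[k, s] - q[k, s])^2 / marginal[[s]]
      }
    }
  }
  unname(sqrt(total) / sqrt(nrow(p)))
}

oracle_euclid <- function(p, q) {
  total <- 0
  for (k in seq_len(nrow(p))) {
    for (s in colnames(p)) total <- total + (p[k, s] - q[k, s])^2
  }
  unname(sqrt(total) / sqrt(nrow(p)))
}

# brute-force state distribution by explicit counting
oracle_distribution <- function(states) {
  states <- states[states != "MISSING"]
  out <- sapply(state_alphabet(), function(s) sum(states == s))
  out / sum(out)
}

# exhaustive minimum within-cluster-variance 2-partition of 1-D points
oracle_best_partition_1d <- function(y) {
  n <- length(y)
  best <- Inf
  best_lab <- NULL
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 1; skip empty
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    wss <- sum(tapply(y, lab, function(v) sum((v - mean(v))^2)))
    if (wss < best - 1e-12) {
      best <- wss
      best_lab <- lab
    }
  }
  best_lab
}

# noise dissimilarity matrix + covariate for null calibration checks
null_dataset <- function(n = 20, len = 100) {
  seqs <- replicate(n, random_seq(len), simplify = FALSE)
  names(seqs) <- sprintf("p%02d", seq_len(n))
  list(D = seq_dissimilarity(seqs), x = rbinom(n, 1, 0.5))
}
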