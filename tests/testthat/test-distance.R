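test_that("state distributions count proportions among non-missing seconds", {
  d <- state_distribution(rep("APNEA", 4))
  expect_equal(d[1, ], c(NORMAL = 0, HYPOPNEA = 0, BRADYPNEA = 0, APNEA = 1))

  d <- state_distribution(c("NORMAL", "NORMAL", "APNEA", "BRADYPNEA"))
  expect_equal(d[1, ], c(NORMAL = 0.5, HYPOPNEA = 0, BRADYPNEA = 0.25, APNEA = 0.25))

  # missing seconds leave numerator and denominator
  d <- state_distribution(c("NORMAL", "NORMAL", "MISSING", "MISSING"))
  expect_equal(unname(d[1, "NORMAL"]), 1)

  expect_error(state_distribution(rep("MISSING", 3), id = "p9"), "p9")
  expect_error(state_distribution(c("NORMAL", "FOO")), "unknown state")
  expect_error(state_distribution(c("NORMAL"), missing = "redistribute"), "not supported")
})

test_that("interval splitting yields one distribution per equal-width span", {
  s <- c(rep("NORMAL", 5), rep("APNEA", 5))
  d <- state_distribution(s, n_intervals = 2)
  expect_equal(dim(d), c(2L, 4L))
  expect_equal(unname(d[1, "NORMAL"]), 1)
  expect_equal(unname(d[2, "APNEA"]), 1)
  # random sequences: every span sums to 1
  set.seed(5)
  for (i in 1:10) {
    d <- state_distribution(random_seq(sample(20:100, 1)), n_intervals = sample(1:5, 1))
    expect_equal(unname(rowSums(d)), rep(1, nrow(d)))
  }
})

test_that("overall marginal pools counts over seconds, not mean of proportions", {
  s1 <- rep("NORMAL", 10)
  expect_equal(overall_marginal(list(s1))[["NORMAL"]], 1)

  # lengths 10 and 30: pooled counts 10 N + 30 A over 40 seconds
  s2 <- rep("APNEA", 30)
  m <- overall_marginal(list(s1, s2))
  expect_equal(m[["NORMAL"]], 0.25)
  expect_equal(m[["APNEA"]], 0.75)

  expect_error(overall_marginal(list()), "no sequences")
})

test_that("chi-squared and Euclidean distances match hand computations", {
  al <- state_alphabet()
  p <- matrix(c(1, 0, 0, 0), 1, dimnames = list(NULL, al))
  q <- matrix(c(0, 1, 0, 0), 1, dimnames = list(NULL, al))
  m <- c(NORMAL = 0.5, HYPOPNEA = 0.5, BRADYPNEA = 0, APNEA = 0)
  expect_equal(chi2_distance(p, q, m), 2)        # sqrt(1/.5 + 1/.5)
  expect_equal(euclid_distance(p, q), sqrt(2))
  expect_equal(chi2_distance(p, p, m), 0)
  expect_equal(euclid_distance(q, q), 0)
  expect_error(chi2_distance(p, q[, 1:3, drop = FALSE], m), "identical dimensions")
})

test_that("pairwise distances agree with the brute-force oracle", {
  set.seed(11)
  for (i in 1:50) {
    K <- sample(1:3, 1)
    seqs <- list(a = random_seq(sample(30:120, 1), p_missing = 0.05),
                 b = random_seq(sample(30:120, 1), p_missing = 0.05))
    m <- overall_marginal(seqs)
    pa <- state_distribution(seqs$a, K)
    pb <- state_distribution(seqs$b, K)
    Dc <- seq_dissimilarity(seqs, metric = "chi2", n_intervals = K)
    De <- seq_dissimilarity(seqs, metric = "euclid", n_intervals = K)
    expect_equal(Dc["a", "b"], oracle_chi2(pa, pb, m), tolerance = 1e-12)
    expect_equal(De["a", "b"], oracle_euclid(pa, pb), tolerance = 1e-12)
  }
})

test_that("metric axioms hold on random triples", {
  set.seed(12)
  for (metric in c("chi2", "euclid")) {
    for (i in 1:60) {
      seqs <- replicate(3, random_seq(sample(20:80, 1)), simplify = FALSE)
      names(seqs) <- c("x", "y", "z")
      D <- seq_dissimilarity(seqs, metric = metric)
      expect_equal(D, t(D), ignore_attr = TRUE)
      expect_equal(unname(diag(D)), rep(0, 3))
      expect_lte(D[1, 3], D[1, 2] + D[2, 3] + 1e-9)
    }
  }
})

test_that("distances are invariant to sequence length (repeating a sequence)", {
  set.seed(13)
  seqs <- list(a = random_seq(40), b = random_seq(60), c = random_seq(90))
  for (metric in c("chi2", "euclid")) {
    D1 <- seq_dissimilarity(seqs, metric = metric)
    seqs_rep <- seqs
    seqs_rep$b <- rep(seqs$b, 4)   # same distribution, 4x the length
    D2 <- seq_dissimilarity(seqs_rep, metric = metric)
    if (metric == "euclid") {
      expect_equal(D1, D2, tolerance = 1e-12, ignore_attr = TRUE)
    } else {
      # chi2 weights shift with pooled marginal; b's own distances to a
      # fixed pair distribution are unchanged under the same marginal
      expect_equal(attr(D1, "marginal"),
                   overall_marginal(seqs))
    }
  }
  # proportion-based length invariance in its pure form: repeat every
  # sequence the same number of times, pooled marginal and all distances
  # are unchanged
  seqs_rep_all <- lapply(seqs, rep, times = 3)
  for (metric in c("chi2", "euclid")) {
    expect_equal(seq_dissimilarity(seqs_rep_all, metric = metric),
                 seq_dissimilarity(seqs, metric = metric),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("chi-squared reduces to scaled Euclidean under a uniform marginal", {
  set.seed(14)
  al <- state_alphabet()
  for (i in 1:20) {
    p <- matrix(prop.table(runif(4)), 1, dimnames = list(NULL, al))
    q <- matrix(prop.table(runif(4)), 1, dimnames = list(NULL, al))
    m <- setNames(rep(0.25, 4), al)
    expect_equal(chi2_distance(p, q, m), euclid_distance(p, q) * sqrt(4),
                 tolerance = 1e-12)
    # general inequality: euclid <= chi2 * sqrt(max marginal)
    mr <- setNames(prop.table(runif(4) + 0.05), al)
    expect_lte(euclid_distance(p, q),
               chi2_distance(p, q, mr) * sqrt(max(mr)) + 1e-9)
  }
})

test_that("the dissimilarity matrix permutes with its inputs and flags bad input", {
  set.seed(15)
  seqs <- list(a = random_seq(30), b = random_seq(30), c = random_seq(30),
               d = random_seq(30))
  D <- seq_dissimilarity(seqs)
  perm <- c("c", "a", "d", "b")
  Dp <- seq_dissimilarity(seqs[perm])
  expect_equal(Dp, D[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)

  expect_equal(max(abs(seq_dissimilarity(list(a = rep("NORMAL", 10),
                                              b = rep("NORMAL", 20),
                                              c = rep("NORMAL", 5))))), 0)

  bad <- list(a = random_seq(10), b = rep("MISSING", 10))
  expect_error(seq_dissimilarity(bad), "b")
  expect_error(seq_dissimilarity(list(a = random_seq(10))), "at least two")
})
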