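#' State occupancy distribution of a sequence
#'
#' Proportion of time spent in each respiratory state, computed among
#' non-missing seconds. With `n_intervals > 1` the sequence is split into
#' equal-width spans and one distribution is returned per span; the default
#' `n_intervals = 1` uses the whole sequence, which makes all downstream
#' distances functions of state durations only (length-invariant, since
#' proportions do not change when a sequence is repeated).
#'
#' @param states character vector of per-second state codes (may contain
#'   `MISSING`).
#' @param n_intervals number of equal-width spans (default 1 = whole
#'   sequence).
#' @param id optional patient id used in error messages.
#' @param missing how artifact (`MISSING`) seconds are handled. Only
#'   `"drop"` — exclude them from numerator and denominator — is supported;
#'   redistribution schemes are rejected to avoid silent bias.
#' @return Numeric matrix with `n_intervals` rows and one column per state
#'   of [state_alphabet()]; each row sums to 1.
#' @export
#' @examples
#' state_distribution(c("NORMAL", "NORMAL", "APNEA", "BRADYPNEA"))
state_distribution <- function(states, n_intervals = 1L, id = NULL,
                               missing = "drop") {
  if (!identical(missing, "drop")) {
    stop("missing = \"", missing, "\" is not supported; only \"drop\" is")
  }
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("n_intervals must be >= 1")
  L <- length(states)
  if (L < 1L) stop("empty sequence", if (!is.null(id)) paste0(" for patient ", id))
  alphabet <- state_alphabet()
  unknown <- setdiff(unique(states), c(alphabet, "MISSING"))
  if (length(unknown)) stop("unknown state code(s): ", paste(unknown, collapse = ", "))
  bounds <- floor(L * (0:n_intervals) / n_intervals)
  out <- matrix(0, n_intervals, length(alphabet),
                dimnames = list(NULL, alphabet))
  for (k in seq_len(n_intervals)) {
    span <- states[(bounds[k] + 1L):bounds[k + 1L]]
    span <- span[span != "MISSING"]
    if (!length(span)) {
      stop("span ", k, " of sequence", if (!is.null(id)) paste0(" for patient ", id),
           " contains no non-missing seconds")
    }
    out[k, ] <- tabulate(factor(span, levels = alphabet),
                         nbins = length(alphabet)) / length(span)
  }
  out
}

#' Pooled state proportions across a set of sequences
#'
#' The overall proportion of (non-missing) time the cohort spends in each
#' state, pooled over all patients' seconds — i.e. weighted by sequence
#' length, not a mean of per-patient proportions. These pooled proportions
#' are the chi-squared distance weights: each state's squared difference is
#' weighted by the inverse of its pooled proportion, giving rare states
#' higher importance. States with zero pooled time are reported as 0 and
#' excluded from the chi-squared support (they cannot be weighted by 1/0).
#'
#' @param seqs list of per-second state code vectors.
#' @return Named numeric vector over [state_alphabet()], summing to 1.
#' @export
overall_marginal <- function(seqs) {
  if (!length(seqs)) stop("no sequences supplied")
  alphabet <- state_alphabet()
  pooled <- unlist(seqs, use.names = FALSE)
  pooled <- pooled[pooled != "MISSING"]
  if (!length(pooled)) stop("all sequences are entirely missing")
  counts <- tabulate(factor(pooled, levels = alphabet), nbins = length(alphabet))
  stats::setNames(counts / sum(counts), alphabet)
}

#' Chi-squared distance between two state distributions
#'
#' Distance between two sequences' state occupancy distributions, weighting
#' each state's squared difference by the inverse of the pooled marginal
#' proportion of time spent in that state:
#' \deqn{d(x, y) = \sqrt{\sum_k \sum_s (p_{ks} - q_{ks})^2 / m_s} \; / \sqrt{K}}
#' over the `K` spans and the states `s` in the marginal's support. Division
#' by `sqrt(K)` keeps distances comparable across interval settings.
#' States with zero marginal must have zero occupancy in both arguments.
#'
#' @param p,q distribution matrices from [state_distribution()] with the
#'   same dimensions and column names.
#' @param marginal pooled state proportions from [overall_marginal()].
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' p <- matrix(c(1, 0, 0, 0), 1, dimnames = list(NULL, state_alphabet()))
#' q <- matrix(c(0, 1, 0, 0), 1, dimnames = list(NULL, state_alphabet()))
#' chi2_distance(p, q, c(NORMAL = 0.5, HYPOPNEA = 0.5, BRADYPNEA = 0, APNEA = 0))
chi2_distance <- function(p, q, marginal) {
  check_dist_pair(p, q)
  marginal <- marginal[colnames(p)]
  if (anyNA(marginal)) stop("marginal lacks entries for some states of p/q")
  support <- marginal > 0
  if (any(p[, !support, drop = FALSE] > 0) || any(q[, !support, drop = FALSE] > 0)) {
    stop("distribution has mass on a state with zero pooled marginal")
  }
  dif2 <- (p[, support, drop = FALSE] - q[, support, drop = FALSE])^2
  sqrt(sum(sweep(dif2, 2L, marginal[support], "/"))) / sqrt(nrow(p))
}

#' Euclidean distance between two state distributions
#'
#' Unweighted counterpart of [chi2_distance()]:
#' \deqn{d(x, y) = \sqrt{\sum_k \sum_s (p_{ks} - q_{ks})^2} \; / \sqrt{K}.}
#'
#' @inheritParams chi2_distance
#' @return Non-negative scalar distance.
#' @export
euclid_distance <- function(p, q) {
  check_dist_pair(p, q)
  sqrt(sum((p - q)^2)) / sqrt(nrow(p))
}

check_dist_pair <- function(p, q) {
  if (!is.matrix(p) || !is.matrix(q) ||
      !identical(dim(p), dim(q)) || !identical(colnames(p), colnames(q))) {
    stop("p and q must be distribution matrices with identical dimensions and states")
  }
  invisible(NULL)
}

#' Pairwise dissimilarity matrix between state sequences
#'
#' Computes the full symmetric matrix of pairwise sequence distances from
#' state occupancy distributions. The chi-squared metric (default, and the
#' primary metric for respiratory sequences because it up-weights rare
#' states such as bradypnea) uses pooled-cohort marginal proportions as
#' weights; `"euclid"` uses unweighted squared differences. Both are
#' Euclidean distances in a (re-weighted) coordinate system, hence satisfy
#' the metric axioms, and both are invariant to sequence length because
#' distributions are proportions.
#'
#' @param seqs named list of per-second state code vectors.
#' @param metric `"chi2"` (default) or `"euclid"`.
#' @param n_intervals number of equal-width spans per sequence (default 1).
#' @return Symmetric numeric matrix with patient ids as dimnames and
#'   attributes `metric`, `marginal` and `n_intervals`.
#' @export
#' @examples
#' seqs <- list(a = rep("NORMAL", 10), b = c(rep("NORMAL", 5), rep("APNEA", 5)))
#' seq_dissimilarity(seqs)
seq_dissimilarity <- function(seqs, metric = c("chi2", "euclid"), n_intervals = 1L) {
  metric <- match.arg(metric)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  all_missing <- vapply(seqs, function(s) all(s == "MISSING"), logical(1))
  if (any(all_missing)) {
    stop("sequence(s) entirely missing for patient(s): ",
         paste(ids[all_missing], collapse = ", "))
  }
  marginal <- overall_marginal(seqs)
  dists <- lapply(seq_len(n), function(i) {
    state_distribution(seqs[[i]], n_intervals = n_intervals, id = ids[i])
  })
  K <- as.integer(n_intervals)
  # flatten to n x (K * S); both metrics are Euclidean after column scaling
  V <- t(vapply(dists, as.vector, numeric(K * length(state_alphabet()))))
  if (metric == "chi2") {
    support <- marginal > 0
    keep <- rep(support, each = K)
    V <- sweep(V[, keep, drop = FALSE], 2L,
               sqrt(rep(marginal[support], each = K)), "/")
  }
  D <- as.matrix(stats::dist(V)) / sqrt(K)
  dimnames(D) <- list(ids, ids)
  attr(D, "metric") <- metric
  attr(D, "marginal") <- marginal
  attr(D, "n_intervals") <- K
  D
}
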