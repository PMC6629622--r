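#' Gower-centered inner-product matrix of a dissimilarity matrix
#'
#' The standard construction underlying distance matrix regression:
#' \deqn{G = -\tfrac12 J (D \circ D) J, \quad J = I - \mathbf{1}\mathbf{1}'/n.}
#' When `D` holds Euclidean distances between points, `G` is the centered
#' Gram matrix of those points, and in general
#' \eqn{\mathrm{tr}(G) = (1/n)\sum_{i<j} d_{ij}^2} is the total sum of
#' squares of the discrepancy analysis.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @return Symmetric centered matrix `G` of the same dimension.
#' @export
#' @examples
#' gower_center(matrix(c(0, 2, 2, 0), 2))
gower_center <- function(D) {
  D <- check_dissimilarity(D)
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  A - outer(rm, rep(1, length(rm))) - outer(rep(1, length(rm)), rm) + mean(A)
}

#' Multivariable distance matrix regression with permutation inference
#'
#' Regresses a pairwise dissimilarity matrix on patient-level covariates.
#' The squared dissimilarities are Gower-centered into `G` (see
#' [gower_center()]); the share of the total discrepancy
#' \eqn{SS_T = \mathrm{tr}(G)} projected onto the column space of the design
#' (intercept included) is the total pseudo-R\eqn{^2} — a strength of
#' association ranging from 0 (none) to 1 (perfect). Per-term statistics are
#' marginal (drop-one): the explained sum of squares lost when the term's
#' column block is removed from the full design, which is invariant to the
#' order in which terms are written. Significance is assessed by permuting
#' patient identities of the dissimilarity matrix `n_perm` times and
#' recomputing every statistic, with
#' \eqn{p = (1 + \#\{F^{perm} \ge F^{obs}\})/(n_{perm} + 1)}.
#'
#' @param formula model formula whose left-hand side evaluates (in `data` or
#'   the formula environment) to the dissimilarity matrix or `dist` object,
#'   e.g. `D ~ age + sex + osa`.
#' @param data data.frame of covariates, rows aligned with `D`. Rows with
#'   missing covariates are dropped listwise (with the matching rows/columns
#'   of `D`); the count is recorded in the result.
#' @param n_perm number of permutations (default 999; values below 99 give a
#'   warning). `0` skips permutation inference, leaving p-values `NA`.
#' @param seed optional integer seed for the permutation stream.
#' @return Object of class `mdmr`: list with `aov_table` (per-term
#'   `df`, `pseudo_F`, `pseudo_R2`, `proportion_explained`, `p_value` plus a
#'   `Total` row), `SS_T`, `n`, `n_dropped`, `n_perm`, `seed`, `perm_F`
#'   (permutation draws of the total pseudo-F) and `call`.
#' @references The pseudo-F construction is the PERMANOVA-family statistic
#'   on a projected Gower-centered matrix.
#' @seealso [bivariate_mdmr()] for the single-covariate special case.
#' @export
#' @examples
#' set.seed(1)
#' y <- c(rnorm(10), rnorm(10, 2))
#' D <- as.matrix(dist(y))
#' covs <- data.frame(g = rep(c("a", "b"), each = 10))
#' fit <- mdmr(D ~ g, data = covs, n_perm = 199, seed = 1)
#' fit
mdmr <- function(formula, data, n_perm = 999L, seed = NULL) {
  cl <- match.call()
  n_perm <- as.integer(n_perm)
  if (n_perm < 0L) stop("n_perm must be >= 0")
  if (n_perm > 0L && n_perm < 99L) {
    warning("n_perm < 99 gives a coarse permutation p-value")
  }
  D <- eval(formula[[2L]], data, environment(formula))
  D <- check_dissimilarity(D)
  rhs <- formula
  rhs[[2L]] <- NULL
  tf <- stats::terms(rhs, data = data)
  mf <- stats::model.frame(tf, data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  n_dropped <- length(dropped)
  keep <- setdiff(seq_len(nrow(data)), as.integer(dropped))
  if (nrow(D) != nrow(data)) stop("D and data must describe the same patients")
  D <- D[keep, keep, drop = FALSE]
  n <- nrow(D)

  mm <- stats::model.matrix(tf, mf)
  asg <- attr(mm, "assign")
  term_labels <- attr(tf, "term.labels")
  # rescale numeric (non-indicator) columns: does not change any projection
  # but conditions the QR
  for (j in seq_len(ncol(mm))[-1L]) {
    sdj <- stats::sd(mm[, j])
    if (sdj > 0 && !all(mm[, j] %in% c(0, 1))) mm[, j] <- scale(mm[, j])[, 1L]
  }
  # a constant covariate carries no information beyond the intercept: its
  # term stays in the table with zero df, R2 = 0 and no test
  const_col <- c(FALSE, vapply(seq_len(ncol(mm))[-1L],
                               function(j) stats::sd(mm[, j]) == 0, logical(1)))
  aliased <- vapply(seq_along(term_labels), function(v) {
    all(const_col[asg == v])
  }, logical(1))
  keep_col <- !const_col | asg == 0L
  mm <- mm[, keep_col, drop = FALSE]
  asg <- asg[keep_col]
  qr_full <- qr(mm)
  if (qr_full$rank < ncol(mm)) {
    bad_cols <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_full$pivot[seq_len(qr_full$rank)])]
    bad_terms <- unique(term_labels[asg[match(bad_cols, colnames(mm))]])
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(bad_terms, collapse = ", "))
  }
  m <- ncol(mm) - 1L
  if (n < ncol(mm) + 2L) stop("need n >= number of model columns + 2")

  G <- gower_center(D)
  SS_T <- sum(diag(G))

  hat_of <- function(X) {
    q <- qr.Q(qr(X))
    tcrossprod(q)
  }
  H_full <- hat_of(mm)
  H_drop <- lapply(seq_along(term_labels), function(v) {
    hat_of(mm[, asg != v, drop = FALSE])
  })
  df_term <- vapply(seq_along(term_labels), function(v) sum(asg == v), integer(1))

  stats_for <- function(Gmat) {
    ss_full <- sum(H_full * Gmat)
    ss_res <- SS_T - ss_full
    denom <- ss_res / (n - m - 1L)
    dss <- vapply(seq_along(H_drop), function(v) {
      ss_full - sum(H_drop[[v]] * Gmat)
    }, numeric(1))
    F_term <- ifelse(df_term > 0L, (dss / pmax(df_term, 1L)) / denom, NA_real_)
    list(ss_full = ss_full,
         F_total = if (m > 0L) (ss_full / m) / denom else NA_real_,
         F_term = F_term,
         dss = dss)
  }
  obs <- stats_for(G)

  p_total <- NA_real_
  p_term <- rep(NA_real_, length(term_labels))
  perm_F <- numeric(0)
  if (n_perm > 0L && m > 0L) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ge_total <- 0L
    ge_term <- integer(length(term_labels))
    perm_F <- numeric(n_perm)
    tol <- 1e-12
    for (b in seq_len(n_perm)) {
      pi_b <- sample.int(n)
      sb <- stats_for(G[pi_b, pi_b])
      perm_F[b] <- sb$F_total
      ge_total <- ge_total + (sb$F_total >= obs$F_total - tol)
      hit <- sb$F_term >= obs$F_term - tol
      ge_term <- ge_term + ifelse(is.na(hit), 0L, hit)
    }
    p_total <- (1 + ge_total) / (n_perm + 1)
    p_term <- ifelse(df_term > 0L, (1 + ge_term) / (n_perm + 1), NA_real_)
  }

  r2_total <- if (SS_T > 0) obs$ss_full / SS_T else 0
  r2_term <- if (SS_T > 0) obs$dss / SS_T else rep(0, length(term_labels))
  aov_table <- data.frame(
    term = c(term_labels, "Total"),
    df = c(df_term, m),
    pseudo_F = c(obs$F_term, obs$F_total),
    pseudo_R2 = c(r2_term, r2_total),
    proportion_explained = c(
      if (r2_total > 0) r2_term / r2_total else rep(NA_real_, length(term_labels)),
      if (m > 0L) 1 else NA_real_),
    p_value = c(p_term, p_total),
    stringsAsFactors = FALSE)

  structure(
    list(aov_table = aov_table, SS_T = SS_T, SS_expl = obs$ss_full,
         SS_res = SS_T - obs$ss_full, n = n, m = m, n_dropped = n_dropped,
         aliased = term_labels[aliased],
         n_perm = n_perm, seed = seed, perm_F = perm_F, call = cl),
    class = "mdmr")
}

#' @export
print.mdmr <- function(x, digits = 3L, ...) {
  cat("Multivariable distance matrix regression (permutation inference)\n")
  cat("n =", x$n,
      if (x$n_dropped > 0) paste0("(", x$n_dropped, " dropped for missing covariates)"),
      " permutations =", x$n_perm, "\n\n")
  tab <- x$aov_table
  tab$pseudo_F <- round(tab$pseudo_F, digits)
  tab$pseudo_R2 <- round(tab$pseudo_R2, digits)
  tab$proportion_explained <- round(tab$proportion_explained, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mdmr <- function(object, ...) {
  structure(list(fit = object), class = "summary.mdmr")
}

#' @export
print.summary.mdmr <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat(sprintf("\nTotal discrepancy SS_T = %.4f; explained = %.4f (%.1f%%); residual = %.4f\n",
              f$SS_T, f$SS_expl, 100 * f$SS_expl / f$SS_T, f$SS_res))
  invisible(x)
}

#' @export
plot.mdmr <- function(x, ...) {
  if (!length(x$perm_F)) stop("no permutation draws stored; refit with n_perm > 0")
  obs <- x$aov_table$pseudo_F[x$aov_table$term == "Total"]
  graphics::hist(x$perm_F, breaks = 30, main = "Permutation null of total pseudo-F",
                 xlab = "pseudo-F", xlim = range(c(x$perm_F, obs)), ...)
  graphics::abline(v = obs, col = "red", lwd = 2)
  invisible(x)
}

#' Bivariate distance matrix regression
#'
#' Single-covariate special case of [mdmr()] (design = intercept + `x`),
#' used e.g. to test the association between hypoxemia (seconds with SpO2
#' below 90%) and the sequence dissimilarity matrix separately from the
#' multivariable model.
#'
#' @param D dissimilarity matrix or `dist`.
#' @param x single covariate vector aligned with `D`.
#' @inheritParams mdmr
#' @return An `mdmr` object.
#' @export
bivariate_mdmr <- function(D, x, n_perm = 999L, seed = NULL) {
  df <- data.frame(x = x)
  env <- new.env(parent = baseenv())
  assign("..D", D, envir = env)
  f <- stats::as.formula("..D ~ x", env = env)
  mdmr(f, data = df, n_perm = n_perm, seed = seed)
}
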