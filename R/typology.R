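#' Ward hierarchical clustering of a sequence dissimilarity matrix
#'
#' Agglomerative minimum-variance (Ward) clustering of the pairwise
#' dissimilarity matrix, cut at `k` clusters. The Ward.D2 convention is
#' used — the Lance–Williams recurrence is applied to squared
#' dissimilarities — because it is the variance-minimising form for
#' dissimilarities that are not raw Euclidean coordinates. Clusters are
#' numbered by order of first appearance among the patients, and when
#' sequences are supplied each cluster is auto-labelled by its dominant
#' (modal) state across member seconds.
#'
#' @param D symmetric dissimilarity matrix (e.g. from
#'   [seq_dissimilarity()]).
#' @param k number of clusters, `2 <= k <= n - 1`.
#' @param seqs optional named list of state sequences used to label each
#'   cluster by its dominant state.
#' @return Object of class `seq_typology`: a list with `k`, `labels`
#'   (named integer vector), `sizes`, `dominant_state`, `quality` (see
#'   [cluster_quality()]) and the underlying `hclust` tree.
#' @export
seq_cluster <- function(D, k = 4L, seqs = NULL) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 2L || k > n - 1L) stop("k must satisfy 2 <= k <= n - 1")
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  # renumber by order of first appearance for a deterministic, input-order
  # independent-of-dendrogram labelling
  first <- match(unique(labels), labels)
  relab <- match(labels, labels[sort(first)])
  names(relab) <- rownames(D)
  dominant <- NULL
  if (!is.null(seqs)) {
    if (!all(names(relab) %in% names(seqs))) {
      stop("seqs must be named with the same patient ids as D")
    }
    dominant <- vapply(seq_len(k), function(cl) {
      pooled <- unlist(seqs[names(relab)[relab == cl]], use.names = FALSE)
      pooled <- pooled[pooled != "MISSING"]
      names(which.max(table(factor(pooled, levels = state_alphabet()))))
    }, character(1))
  }
  structure(
    list(k = k,
         labels = relab,
         sizes = tabulate(relab, nbins = k),
         dominant_state = dominant,
         quality = cluster_quality(D, relab),
         hclust = hc),
    class = "seq_typology")
}

#' @export
print.seq_typology <- function(x, ...) {
  cat("Respiratory state sequence typology (Ward.D2), k =", x$k, "\n")
  tab <- data.frame(cluster = seq_len(x$k), n = x$sizes,
                    share = round(x$sizes / sum(x$sizes), 3))
  if (!is.null(x$dominant_state)) tab$dominant_state <- x$dominant_state
  print(tab, row.names = FALSE)
  cat(sprintf("Average silhouette width %.3f; point-biserial r %.3f\n",
              x$quality$asw, x$quality$point_biserial))
  invisible(x)
}

#' Cluster-quality metrics for a partition of a dissimilarity matrix
#'
#' Average silhouette width (computed directly from the dissimilarity
#' matrix; silhouette widths of singleton clusters are 0 by convention) and
#' the point-biserial correlation between the pairwise dissimilarities and
#' the same/different-cluster indicator.
#'
#' @param D symmetric dissimilarity matrix.
#' @param labels integer cluster labels, one per row of `D`.
#' @return List with elements `asw` and `point_biserial`.
#' @export
cluster_quality <- function(D, labels) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match D")
  if (length(unique(labels)) < 2L) {
    return(list(asw = NA_real_, point_biserial = NA_real_))
  }
  sil <- cluster::silhouette(labels, dmatrix = D)
  # all-singleton partitions: silhouette widths are 0 by convention
  asw <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
  lower <- lower.tri(D)
  diff_cluster <- outer(labels, labels, "!=")[lower]
  dvec <- D[lower]
  pbc <- if (length(dvec) < 2L || stats::sd(dvec) == 0 || stats::sd(diff_cluster) == 0) {
    NA_real_
  } else {
    stats::cor(dvec, as.numeric(diff_cluster))
  }
  list(asw = asw, point_biserial = pbc)
}

#' Cluster-quality report over a range of cluster counts
#'
#' Fits Ward clusterings for each `k` and tabulates the quality metrics used
#' to choose the final typology size. The final `k` is a user decision
#' informed by this report; `best_k` flags the `k` with the highest average
#' silhouette width as a convention.
#'
#' @param D symmetric dissimilarity matrix.
#' @param ks candidate cluster counts (default 2..6).
#' @return data.frame with columns `k`, `asw`, `point_biserial` and a
#'   `best_k` attribute.
#' @export
cluster_quality_report <- function(D, ks = 2:6) {
  D <- check_dissimilarity(D)
  ks <- as.integer(ks)
  if (any(ks < 2L | ks > nrow(D) - 1L)) stop("ks must lie within [2, n - 1]")
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  rows <- lapply(ks, function(k) {
    q <- cluster_quality(D, stats::cutree(hc, k = k))
    data.frame(k = k, asw = q$asw, point_biserial = q$point_biserial)
  })
  rep_df <- do.call(rbind, rows)
  attr(rep_df, "best_k") <- rep_df$k[which.max(rep_df$asw)]
  rep_df
}

check_dissimilarity <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (any(D < 0)) stop("dissimilarity matrix has negative entries")
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("dissimilarity matrix diagonal is not zero")
  if (is.null(rownames(D))) {
    dimnames(D) <- list(as.character(seq_len(nrow(D))),
                        as.character(seq_len(nrow(D))))
  }
  D
}
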