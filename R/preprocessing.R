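# TF-IDF weighting, PCA embedding and the cell neighborhood graph: the
# standard scCAS embedding workflow the estimators run on.

#' TF-IDF transformation of a peak-by-cell matrix
#'
#' Cells play documents and peaks play terms. With
#' `tf[i,j] = counts[i,j] / colsum_j` and `df_i` the number of cells in
#' which peak i is detected, the two variants are
#'
#' * V1: `tf[i,j] * log(1 + n / df_i)`
#' * V2: `log(1 + tf[i,j] * (n / df_i) * 1e4)`
#'
#' Natural logarithms throughout; the sparsity pattern is preserved exactly
#' (zero counts map to zero output). V1 feeds the WSS/elbow estimator, V2
#' the Davies-Bouldin and silhouette estimators.
#'
#' @param m a [peak_cell_matrix()] with no all-zero peaks or cells
#'   (see [filter_degenerate()]).
#' @param variant `"V1"` or `"V2"`.
#' @param binarize clamp counts to presence/absence before weighting.
#'
#' @return a list of class `transformed_matrix` with elements `values`
#'   (sparse p x n real matrix) and `variant`.
#' @export
tfidf <- function(m, variant = c("V1", "V2"), binarize = FALSE) {
  variant <- match.arg(variant)
  validate_pcm(m)
  counts <- m$counts
  if (isTRUE(binarize)) counts@x <- as.numeric(counts@x > 0)
  n <- ncol(counts)
  colsums <- Matrix::colSums(counts)
  df <- Matrix::rowSums(counts > 0)
  if (any(colsums == 0) || any(df == 0)) {
    stop("internal error: zero column sum or zero detection count; ",
         "run filter_degenerate() first", call. = FALSE)
  }
  tf <- counts %*% Matrix::Diagonal(n, 1 / colsums)
  if (variant == "V1") {
    values <- Matrix::Diagonal(nrow(counts), log(1 + n / df)) %*% tf
  } else {
    values <- Matrix::Diagonal(nrow(counts), (n / df) * 1e4) %*% tf
    values <- as(as(values, "generalMatrix"), "CsparseMatrix")
    values@x <- log1p(values@x)
  }
  values <- as(as(values, "generalMatrix"), "CsparseMatrix")
  structure(list(values = values, variant = variant),
            class = "transformed_matrix")
}

#' PCA embedding of cells
#'
#' Embeds cells (columns of the transformed matrix) on the top principal
#' axes of the cell-by-peak view, after per-peak mean centering and without
#' variance scaling. Uses a truncated implicitly restarted Lanczos SVD for
#' large inputs and a dense SVD when the requested rank is close to the
#' matrix dimensions; both routes are seeded and deterministic. Each
#' component's sign is fixed so that its largest-magnitude peak loading is
#' positive.
#'
#' @param t a `transformed_matrix` from [tfidf()].
#' @param n_components number of components d, with
#'   `2 <= d <= min(p, n) - 1`.
#' @param seed integer seed for the iterative solver.
#'
#' @return a list of class `cell_embedding` with `coords` (n x d matrix of
#'   cell scores), `explained_var` (length-d, non-increasing) and
#'   `n_components`.
#' @export
pca_embed <- function(t, n_components = 50L, seed = 0L) {
  stopifnot(inherits(t, "transformed_matrix"))
  p <- nrow(t$values); n <- ncol(t$values)
  d <- as.integer(n_components)
  if (d < 2L || d > min(p, n) - 1L) {
    stop("n_components must be in [2, min(p, n) - 1] = [2, ",
         min(p, n) - 1L, "]", call. = FALSE)
  }
  A <- Matrix::t(t$values)  # cells x peaks
  centers <- Matrix::colMeans(A)
  if (d <= 0.5 * min(n, p) && min(n, p) > 10L) {
    set.seed(seed)
    sv <- irlba::irlba(A, nv = d, center = centers)
    scores <- sv$u %*% diag(sv$d, d, d)
    loadings <- sv$v
    dvals <- sv$d
  } else {
    Ad <- sweep(as.matrix(A), 2L, centers)
    sv <- svd(Ad, nu = d, nv = d)
    scores <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
    loadings <- sv$v
    dvals <- sv$d[seq_len(d)]
  }
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(d)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  structure(list(coords = scores,
                 explained_var = dvals^2 / (n - 1),
                 n_components = d),
            class = "cell_embedding")
}

#' k-nearest-neighbor graph of cells
#'
#' Builds the kNN graph on Euclidean distances in embedding space,
#' symmetrized by union (an edge is kept if either endpoint lists the other
#' among its `n_neighbors` nearest). Edge weights are `1 / (1 + distance)`,
#' a positive, monotone-decreasing function of distance.
#'
#' @param e a `cell_embedding` from [pca_embed()].
#' @param n_neighbors neighbors per cell, `1 <= n_neighbors < n`.
#'
#' @return a list of class `neighbor_graph` with `graph` (weighted
#'   undirected [igraph::graph]) and `n_neighbors`.
#' @export
knn_graph <- function(e, n_neighbors = 15L) {
  stopifnot(inherits(e, "cell_embedding"))
  n <- nrow(e$coords)
  k <- as.integer(n_neighbors)
  if (k < 1L || k >= n) {
    stop("n_neighbors must be in [1, n - 1] = [1, ", n - 1L, "]",
         call. = FALSE)
  }
  nn <- RANN::nn2(e$coords, k = k + 1L)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$nn.idx[, -1L])
  dist <- as.vector(nn$nn.dists[, -1L])
  # undirected union: duplicate (u,v)/(v,u) pairs collapse to one edge; the
  # distance (hence weight) is symmetric so which copy survives is irrelevant
  key_lo <- pmin(from, to); key_hi <- pmax(from, to)
  keep <- !duplicated(key_lo + (key_hi - 1) * n)
  g <- igraph::graph_from_edgelist(cbind(key_lo[keep], key_hi[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- 1 / (1 + dist[keep])
  structure(list(graph = g, n_neighbors = k), class = "neighbor_graph")
}
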