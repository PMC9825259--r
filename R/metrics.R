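# The three model-selection criteria and knee detection. All distances are
# Euclidean in embedding space; labels are integers 1..k with every label
# occupied.

as_labels <- function(labels, n = NULL) {
  labels <- as.integer(labels)
  if (length(labels) == 0L || anyNA(labels)) {
    stop("cluster labels must be non-missing integers", call. = FALSE)
  }
  if (!is.null(n) && length(labels) != n) {
    stop("labels length ", length(labels), " does not match ", n, " cells",
         call. = FALSE)
  }
  # compact to 1..k preserving order of first appearance of sorted values
  match(labels, sort(unique(labels)))
}

cluster_centroids <- function(coords, labels) {
  k <- max(labels)
  cen <- matrix(0, k, ncol(coords))
  for (j in seq_len(k)) {
    cen[j, ] <- colMeans(coords[labels == j, , drop = FALSE])
  }
  cen
}

# squared Euclidean distances point -> centroid, n x k; computed by direct
# differencing (not the inner-product expansion, which loses precision)
sq_dist_to_centroids <- function(coords, cen) {
  k <- nrow(cen)
  out <- matrix(0, nrow(coords), k)
  for (j in seq_len(k)) {
    out[, j] <- rowSums(sweep(coords, 2L, cen[j, ])^2)
  }
  out
}

#' Within-cluster sum-of-squares
#'
#' `WSS = sum_i min_j || x_i - mu_j ||^2`: the sum over all cells of the
#' squared Euclidean distance to the nearest cluster centroid, centroids
#' being per-cluster means of the embedding rows.
#'
#' @param e a `cell_embedding` or a plain numeric matrix (cells x dims).
#' @param labels integer cluster labels, one per cell.
#'
#' @return a single nonnegative number.
#' @export
wss <- function(e, labels) {
  coords <- if (inherits(e, "cell_embedding")) e$coords else as.matrix(e)
  labels <- as_labels(labels, nrow(coords))
  cen <- cluster_centroids(coords, labels)
  d2 <- sq_dist_to_centroids(coords, cen)
  sum(pmax(apply(d2, 1L, min), 0))
}

#' Davies-Bouldin index
#'
#' `(1/k) sum_i max_{j != i} (s_i + s_j) / d_ij`, where `s_i` is the mean
#' Euclidean distance of cluster-i cells to their centroid and `d_ij` the
#' distance between centroids i and j. Lower is better. Coincident
#' centroids (`d_ij = 0`) make the pair's ratio `+Inf`, which propagates:
#' the partition is degenerate but argmin selection over k still works.
#'
#' @inheritParams wss
#'
#' @return a single number `>= 0`, possibly `Inf`.
#' @export
davies_bouldin <- function(e, labels) {
  coords <- if (inherits(e, "cell_embedding")) e$coords else as.matrix(e)
  labels <- as_labels(labels, nrow(coords))
  k <- max(labels)
  if (k < 2L) stop("Davies-Bouldin requires k >= 2", call. = FALSE)
  cen <- cluster_centroids(coords, labels)
  d2 <- sq_dist_to_centroids(coords, cen)
  s <- vapply(seq_len(k), function(j) {
    mean(sqrt(pmax(d2[labels == j, j], 0)))
  }, 0)
  dc <- as.matrix(stats::dist(cen))
  ratios <- outer(s, s, "+") / dc
  ratios[dc == 0] <- Inf   # coincident centroids: degenerate pair
  diag(ratios) <- -Inf
  mean(apply(ratios, 1L, max))
}

#' Mean silhouette coefficient
#'
#' Per cell, `s = (b - a) / max(a, b)` with `a` the mean distance to the
#' other cells of its own cluster and `b` the minimum over other clusters
#' of the mean distance to that cluster's cells (the next nearest cluster).
#' Cells in singleton clusters contribute 0, as do cells where
#' `max(a, b) = 0`. Returns the mean over all cells, in `[-1, 1]`.
#'
#' @inheritParams wss
#' @param dist_matrix optional precomputed n x n Euclidean distance matrix;
#'   computed from the embedding when absent.
#'
#' @return a single number in `[-1, 1]`.
#' @export
mean_silhouette <- function(e, labels, dist_matrix = NULL) {
  coords <- if (inherits(e, "cell_embedding")) e$coords else as.matrix(e)
  labels <- as_labels(labels, nrow(coords))
  n <- length(labels)
  k <- max(labels)
  if (k < 2L) stop("silhouette requires k >= 2", call. = FALSE)
  if (n < 3L) stop("silhouette requires n >= 3", call. = FALSE)
  if (is.null(dist_matrix)) dist_matrix <- as.matrix(stats::dist(coords))
  sizes <- tabulate(labels, k)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sums <- dist_matrix %*% ind                     # n x k: total dist to each cluster
  mean_other <- sweep(sums, 2L, sizes, "/")       # mean incl. self-cluster bias
  own_size <- sizes[labels]
  a <- sums[cbind(seq_len(n), labels)] / pmax(own_size - 1, 1)
  mean_other[cbind(seq_len(n), labels)] <- Inf    # exclude own cluster from b
  b <- apply(mean_other, 1L, min)
  denom <- pmax(a, b)
  s <- ifelse(own_size == 1L | denom == 0, 0, (b - a) / denom)
  mean(s)
}

#' Knee point of a k-versus-score curve
#'
#' Detects the elbow/knee (the point of maximum curvature) of a broadly
#' decreasing score curve by the normalized chord difference (the Kneedle
#' construction without smoothing): k and score are rescaled to `[0, 1]`,
#' the decreasing curve is flipped to increasing-concave form, and the k
#' maximizing the difference between the flipped curve and the straight
#' chord is returned. Ties break toward smaller k. A curve with no
#' curvature (exactly linear) has no knee and raises an error of class
#' `cask_no_knee`.
#'
#' @param k integer vector of candidate cluster numbers, strictly
#'   increasing, length >= 3.
#' @param score numeric scores, same length as `k`.
#' @param tol minimum normalized difference for a knee to count.
#'
#' @return the k at the knee (integer).
#' @export
knee_point <- function(k, score, tol = 1e-12) {
  k <- as.numeric(k); score <- as.numeric(score)
  if (length(k) < 3L) stop("knee detection needs at least 3 points",
                           call. = FALSE)
  if (any(diff(k) <= 0)) stop("k values must be strictly increasing",
                              call. = FALSE)
  if (anyNA(score) || any(!is.finite(score))) {
    stop("scores must be finite", call. = FALSE)
  }
  xr <- diff(range(k)); yr <- diff(range(score))
  if (yr == 0) {
    stop(structure(class = c("cask_no_knee", "error", "condition"),
                   list(message = "flat curve: no knee", call = NULL)))
  }
  xn <- (k - min(k)) / xr
  yn <- (score - min(score)) / yr
  if (score[length(score)] < score[1]) yn <- 1 - yn  # flip decreasing curves
  d <- yn - xn
  if (max(d) <= tol) {
    stop(structure(class = c("cask_no_knee", "error", "condition"),
                   list(message = "no curvature above tolerance: no knee",
                        call = NULL)))
  }
  # ties (within numerical noise of the maximum, e.g. after an affine
  # rescaling of the score axis) break toward the smallest k
  as.integer(k[which(d >= max(d) - 1e-9)[1L]])
}
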