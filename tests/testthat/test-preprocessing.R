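pcm_from_counts <- function(counts) {
  p <- nrow(counts)
  peak_cell_matrix(counts,
                   data.frame(chrom = "c", start = (seq_len(p) - 1L) * 100L,
                              end = (seq_len(p) - 1L) * 100L + 50L),
                   sprintf("BC%03d", seq_len(ncol(counts))))
}

test_that("TF-IDF variants reproduce the hand-computed 2x2 example", {
  # counts (peaks x cells) = [[1,0],[1,1]]: colsums (2,1); peak detection
  # counts df = (1,2); idf_V1 = (log(1+2/1), log(1+2/2)) = (log 3, log 2)
  m <- pcm_from_counts(matrix(c(1, 1, 0, 1), 2, 2))
  v1 <- as.matrix(tfidf(m, "V1")$values)
  expect_equal(v1[1, 1], 0.5 * log(3), tolerance = 1e-12)
  expect_equal(v1[1, 2], 0)
  expect_equal(v1[2, 1], 0.5 * log(2), tolerance = 1e-12)
  expect_equal(v1[2, 2], 1 * log(2), tolerance = 1e-12)

  # idf_raw = n/df = (2, 1)
  v2 <- as.matrix(tfidf(m, "V2")$values)
  expect_equal(v2[1, 1], log(1 + 0.5 * 2 * 1e4), tolerance = 1e-12)
  expect_equal(v2[1, 2], 0)
  expect_equal(v2[2, 1], log(1 + 0.5 * 1 * 1e4), tolerance = 1e-12)
  expect_equal(v2[2, 2], log(1 + 1 * 1 * 1e4), tolerance = 1e-12)
})

test_that("TF-IDF preserves the sparsity pattern and per-cell scale for V1", {
  set.seed(7)
  for (rep in 1:5) {
    counts <- matrix(rpois(15 * 8, 0.8), 15, 8)
    counts[rowSums(counts) == 0, 1] <- 1
    counts[1, colSums(counts) == 0] <- 1
    m <- pcm_from_counts(counts)
    for (variant in c("V1", "V2")) {
      out <- as.matrix(tfidf(m, variant)$values)
      expect_identical(out != 0, counts != 0)
      expect_true(all(is.finite(out)))
    }
    # doubling one cell's counts leaves its V1 column unchanged (tf and df
    # are unaffected)
    doubled <- counts
    doubled[, 3] <- 2L * doubled[, 3]
    out1 <- as.matrix(tfidf(m, "V1")$values)
    out2 <- as.matrix(tfidf(pcm_from_counts(doubled), "V1")$values)
    expect_equal(out2[, 3], out1[, 3], tolerance = 1e-12)
  }
})

test_that("binarized TF-IDF ignores count magnitudes", {
  counts <- matrix(c(3, 1, 0, 5, 2, 0, 0, 1, 7), 3, 3)
  m <- pcm_from_counts(counts)
  mb <- pcm_from_counts((counts > 0) * 1L)
  expect_equal(as.matrix(tfidf(m, "V1", binarize = TRUE)$values),
               as.matrix(tfidf(mb, "V1")$values), tolerance = 1e-12)
})

test_that("PCA embedding matches a dense eigendecomposition oracle", {
  set.seed(11)
  counts <- matrix(rpois(20 * 6, 2) + 1L, 20, 6)  # no zero rows/cols
  m <- pcm_from_counts(counts)
  t1 <- tfidf(m, "V1")
  e <- pca_embed(t1, n_components = 3, seed = 1)

  A <- t(as.matrix(t1$values))            # cells x peaks
  Ac <- sweep(A, 2, colMeans(A))
  sv <- svd(Ac)
  oracle_scores <- sv$u[, 1:3] %*% diag(sv$d[1:3])
  # compare up to per-component sign
  for (j in 1:3) {
    expect_true(max(abs(e$coords[, j] - oracle_scores[, j])) < 1e-8 ||
                  max(abs(e$coords[, j] + oracle_scores[, j])) < 1e-8)
  }
  expect_equal(e$explained_var, sv$d[1:3]^2 / (nrow(A) - 1),
               tolerance = 1e-8)
  expect_true(all(diff(e$explained_var) <= 1e-12))
})

test_that("rank-1 data leaves the second component with no variance", {
  direction <- c(1, 2, 3, 4, 5)
  counts <- outer(direction, c(1, 2, 3, 4))      # rank-1, positive
  m <- pcm_from_counts(counts)
  tm <- structure(list(values = Matrix::Matrix(counts, sparse = TRUE),
                       variant = "V1"), class = "transformed_matrix")
  e <- pca_embed(tm, n_components = 2, seed = 1)
  expect_lt(e$explained_var[2] / e$explained_var[1], 1e-10)
})

test_that("embedding variance never exceeds the centered input variance", {
  set.seed(13)
  counts <- matrix(rpois(25 * 10, 1.5) + 1L, 25, 10)
  m <- pcm_from_counts(counts)
  t1 <- tfidf(m, "V2")
  A <- t(as.matrix(t1$values))
  total_var <- sum(apply(A, 2, var))
  e_small <- pca_embed(t1, n_components = 3, seed = 1)
  expect_lte(sum(e_small$explained_var), total_var + 1e-10)
  full_rank <- min(dim(A)) - 1L
  e_full <- pca_embed(t1, n_components = full_rank, seed = 1)
  expect_equal(sum(e_full$explained_var), total_var, tolerance = 1e-8)
})

test_that("pca_embed rejects out-of-range component counts", {
  m <- pcm_from_counts(matrix(rpois(20 * 6, 2) + 1L, 20, 6))
  t1 <- tfidf(m, "V1")
  expect_error(pca_embed(t1, n_components = 1), "n_components")
  expect_error(pca_embed(t1, n_components = 6), "n_components")
})

test_that("kNN graph geometry: long thin rectangle pairs up short sides", {
  coords <- matrix(c(0, 0, 0, 1, 10, 0, 10, 1), 4, 2, byrow = TRUE)
  e <- structure(list(coords = coords, explained_var = c(1, 1),
                      n_components = 2L), class = "cell_embedding")
  g <- knn_graph(e, n_neighbors = 1)$graph
  edges <- igraph::as_edgelist(g)
  edges <- edges[order(edges[, 1]), , drop = FALSE]
  expect_equal(nrow(edges), 2)
  expect_equal(edges, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_false(igraph::is_directed(g))
  expect_true(all(igraph::E(g)$weight > 0))
})

test_that("kNN neighbor sets match a brute-force distance sort", {
  set.seed(5)
  coords <- matrix(rnorm(30 * 3), 30, 3)
  e <- structure(list(coords = coords, explained_var = rep(1, 3),
                      n_components = 3L), class = "cell_embedding")
  k <- 4L
  g <- knn_graph(e, n_neighbors = k)$graph
  # union-of-kNN edge set from an all-pairs sort
  d <- as.matrix(dist(coords))
  expected <- matrix(0L, 0, 2)
  for (i in 1:30) {
    nb <- order(d[i, ])[2:(k + 1)]
    expected <- rbind(expected, cbind(pmin(i, nb), pmax(i, nb)))
  }
  expected <- unique(expected)
  got <- igraph::as_edgelist(g)
  got <- got[order(got[, 1], got[, 2]), ]
  expected <- expected[order(expected[, 1], expected[, 2]), ]
  expect_equal(got, expected, ignore_attr = TRUE)
  # union symmetrization only adds edges: degree >= n_neighbors
  expect_true(all(igraph::degree(g) >= k))
  expect_error(knn_graph(e, n_neighbors = 30), "n_neighbors")
})
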