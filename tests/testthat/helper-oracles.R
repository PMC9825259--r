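# Brute-force direct-formula oracles and small fixture builders. The
# oracles use nothing from the package's metric implementations: plain
# double loops over the printed formulas.

oracle_wss <- function(coords, labels) {
  ks <- sort(unique(labels))
  centroids <- lapply(ks, function(j) {
    colMeans(coords[labels == j, , drop = FALSE])
  })
  total <- 0
  for (i in seq_len(nrow(coords))) {
    best <- Inf
    for (mu in centroids) {
      best <- min(best, sum((coords[i, ] - mu)^2))
    }
    total <- total + best
  }
  total
}

oracle_davies_bouldin <- function(coords, labels) {
  ks <- sort(unique(labels))
  k <- length(ks)
  centroids <- lapply(ks, function(j) {
    colMeans(coords[labels == j, , drop = FALSE])
  })
  s <- vapply(seq_len(k), function(j) {
    rows <- coords[labels == ks[j], , drop = FALSE]
    mean(apply(rows, 1L, function(x) sqrt(sum((x - centroids[[j]])^2))))
  }, 0)
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      dij <- sqrt(sum((centroids[[i]] - centroids[[j]])^2))
      r <- if (dij == 0) Inf else (s[i] + s[j]) / dij
      worst <- max(worst, r)
    }
    total <- total + worst
  }
  total / k
}

oracle_mean_silhouette <- function(coords, labels) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- which(labels == own & seq_len(n) != i)
    if (length(same) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- Inf
    for (j in ks) {
      if (j == own) next
      b <- min(b, mean(d[i, labels == j]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# random labeled point set with every label occupied
random_instance <- function(n, d, k) {
  coords <- matrix(rnorm(n * d), n, d)
  labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  list(coords = coords, labels = labels)
}

# tiny deterministic peak-by-cell fixture with block structure
tiny_pcm <- function(p = 12L, n = 9L, seed = 42L) {
  set.seed(seed)
  counts <- matrix(rpois(p * n, 0.6), p, n)
  counts[1:4, 1:3] <- counts[1:4, 1:3] + 2L
  counts[5:8, 4:6] <- counts[5:8, 4:6] + 2L
  counts[9:12, 7:9] <- counts[9:12, 7:9] + 2L
  peaks <- data.frame(chrom = "chrT", start = (seq_len(p) - 1L) * 100L,
                      end = (seq_len(p) - 1L) * 100L + 50L)
  peak_cell_matrix(counts, peaks, sprintf("BC%03d", seq_len(n)))
}

# minimal AnnData-layout HDF5 writer (CSR or dense), matching what the
# Python anndata writer produces for X/obs/var
write_fake_h5ad <- function(path, X, obs_names, var_names,
                            layout = c("csr", "dense")) {
  layout <- match.arg(layout)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  if (layout == "csr") {
    # CSR over obs x var == CSC over var x obs
    sp <- as(as(Matrix::Matrix(t(X), sparse = TRUE), "generalMatrix"),
             "CsparseMatrix")
    rhdf5::h5createGroup(path, "X")
    rhdf5::h5write(sp@x, path, "X/data")
    rhdf5::h5write(sp@i, path, "X/indices")
    rhdf5::h5write(sp@p, path, "X/indptr")
    fid <- rhdf5::H5Fopen(path); gid <- rhdf5::H5Gopen(fid, "X")
    rhdf5::h5writeAttribute("csr_matrix", gid, "encoding-type",
                            asScalar = TRUE)
    rhdf5::h5writeAttribute(dim(X), gid, "shape")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  } else {
    # python stores obs x var row-major; from R that is writing var x obs
    rhdf5::h5write(t(X), path, "X")
  }
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(obs_names, path, "obs/_index")
  rhdf5::h5write(var_names, path, "var/_index")
  rhdf5::H5close()
  invisible(path)
}
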