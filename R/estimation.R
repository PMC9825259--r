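# The three per-criterion estimators of the number of cell types, the
# weighted-bias resolution search for Louvain/Leiden, and the ensemble.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

kmeanspp_centers <- function(coords, k) {
  n <- nrow(coords)
  centers <- matrix(0, k, ncol(coords))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- coords[idx, ]
  d2 <- rowSums(sweep(coords, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    idx <- if (sum(d2) == 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2)
    centers[j, ] <- coords[idx, ]
    d2 <- pmin(d2, rowSums(sweep(coords, 2L, centers[j, ])^2))
  }
  centers
}

#' K-means partition of the cell embedding
#'
#' Best-of-`n_init` K-means with k-means++ initialization and Lloyd
#' iterations, selected by total within-cluster sum-of-squares.
#' Deterministic given `seed`.
#'
#' @param e a `cell_embedding` or numeric matrix (cells x dims).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param iter_max Lloyd iteration cap.
#'
#' @return integer cluster labels in `1..k`, one per cell.
#' @export
kmeans_partition <- function(e, k, seed = 0L, n_init = 10L, iter_max = 300L) {
  coords <- if (inherits(e, "cell_embedding")) e$coords else as.matrix(e)
  n <- nrow(coords)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in [1, n]", call. = FALSE)
  if (k == 1L) return(rep(1L, n))
  best <- NULL; best_wss <- Inf
  for (init in seq_len(n_init)) {
    set.seed(child_seed(seed, k, init))
    centers <- kmeanspp_centers(coords, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(coords, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    if (fit$tot.withinss < best_wss) {
      best_wss <- fit$tot.withinss
      best <- fit$cluster
    }
  }
  if (is.null(best)) {
    # all k-means++ starts degenerate (e.g. many duplicated points)
    set.seed(child_seed(seed, k, 0L))
    fit <- suppressWarnings(stats::kmeans(coords, centers = k,
                                          nstart = n_init,
                                          iter.max = iter_max))
    best <- fit$cluster
  }
  as.integer(best)
}

cluster_graph <- function(g, method, resolution, seed) {
  set.seed(seed)
  com <- if (method == "louvain") {
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                            resolution = resolution)
  } else {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           weights = igraph::E(g)$weight,
                           resolution = resolution, n_iterations = 3L)
  }
  as.integer(igraph::membership(com))
}

#' Weighted-bias resolution search for a target cluster count
#'
#' Louvain and Leiden take a resolution parameter, not a cluster count.
#' To find a partition with `target_k` clusters the search keeps a
#' resolution bracket `[r_lo, r_hi]` with observed cluster counts
#' `k_lo <= target_k <= k_hi` and, instead of plain bisection, proposes
#'
#' `r_next = r_lo + (r_hi - r_lo) * (target_k - k_lo) / (k_hi - k_lo)`
#'
#' i.e. the bracket is interpolated proportionally to where the target sits
#' between the observed counts (the weighted bias). The bracket then
#' shrinks exactly as binary search would: an obtained count below the
#' target raises the lower bound, above lowers the upper bound. Stops on an
#' exact hit, a bracket narrower than `r_tol`, or `search_max_iter`
#' proposals, and returns the evaluated partition whose count is closest to
#' the target (ties toward smaller counts).
#'
#' @param graph a `neighbor_graph` from [knn_graph()].
#' @param target_k desired number of clusters (`>= 2`).
#' @param method `"louvain"` or `"leiden"`.
#' @param cfg a [cask_config()] (bracket, tolerance, iteration cap).
#' @param seed integer seed; each resolution gets a deterministic child
#'   seed, so results do not depend on evaluation order.
#' @param strategy `"weighted-bias"` (default) or `"bisection"` (the
#'   baseline proposal rule, midpoint of the bracket).
#' @param cache optional environment memoizing evaluations across calls
#'   (resolution -> clustering); used by [estimate_k_silhouette()] so the
#'   bracket endpoints are clustered once per data set, not once per k.
#'
#' @return a list with `labels` (integer partition), `achieved_k`, and
#'   `state` (bracket, endpoint counts, number of clustering evaluations,
#'   `hit` flag, `warning` message if the target is outside the achievable
#'   range).
#' @export
resolution_search <- function(graph, target_k,
                              method = c("louvain", "leiden"),
                              cfg = cask_config(), seed = 0L,
                              strategy = c("weighted-bias", "bisection"),
                              cache = NULL) {
  method <- match.arg(method)
  strategy <- match.arg(strategy)
  stopifnot(inherits(graph, "neighbor_graph"))
  target_k <- as.integer(target_k)
  if (target_k < 2L) stop("target_k must be >= 2", call. = FALSE)
  if (cfg$r_min <= 0 || cfg$r_max <= cfg$r_min) {
    stop("resolution bracket must satisfy 0 < r_min < r_max", call. = FALSE)
  }
  g <- graph$graph
  evals <- 0L
  best <- NULL  # list(labels, k)
  note <- NULL

  evaluate <- function(r) {
    key <- sprintf("%s:%.12g", method, r)
    if (!is.null(cache) && !is.null(cache[[key]])) {
      res <- cache[[key]]
    } else {
      labels <- cluster_graph(g, method, r,
                              child_seed(seed, round(r * 1e7)))
      res <- list(labels = labels, k = length(unique(labels)))
      if (!is.null(cache)) cache[[key]] <- res
    }
    evals <<- evals + 1L
    if (is.null(best) || abs(res$k - target_k) < abs(best$k - target_k) ||
        (abs(res$k - target_k) == abs(best$k - target_k) && res$k < best$k)) {
      best <<- res
    }
    res
  }

  r_lo <- cfg$r_min; r_hi <- cfg$r_max
  lo <- evaluate(r_lo)
  k_lo <- lo$k
  hi <- evaluate(r_hi)
  k_hi <- hi$k
  if (k_lo != target_k) {
    if (target_k <= k_lo) {
      if (target_k < k_lo) note <- "target below count at minimum resolution"
    } else if (target_k >= k_hi) {
      if (target_k > k_hi) note <- "target above count at maximum resolution"
    } else {
      stagnant <- FALSE
      for (iter in seq_len(cfg$search_max_iter)) {
        if (best$k == target_k || (r_hi - r_lo) < cfg$r_tol) break
        denom <- k_hi - k_lo
        width <- r_hi - r_lo
        r_next <- if (strategy == "weighted-bias" && denom > 0 && !stagnant) {
          r_lo + width * (target_k - k_lo) / denom
        } else {
          (r_lo + r_hi) / 2  # bisection; also flat-response and stagnation fallback
        }
        # keep proposals a margin inside the bracket: the cluster-count
        # response has plateaus, and interpolation creeping along one edge
        # (regula-falsi stagnation) wastes evaluations
        r_next <- min(max(r_next, r_lo + 0.05 * width), r_hi - 0.05 * width)
        res <- evaluate(r_next)
        if (res$k == target_k) break
        if (res$k < target_k) {
          stagnant <- res$k == k_lo
          r_lo <- r_next; k_lo <- res$k
        } else {
          stagnant <- res$k == k_hi
          r_hi <- r_next; k_hi <- res$k
        }
      }
    }
  }
  list(labels = best$labels,
       achieved_k = best$k,
       state = list(target_k = target_k, method = method,
                    strategy = strategy,
                    r_lo = r_lo, r_hi = r_hi,
                    k_lo_obs = k_lo, k_hi_obs = k_hi,
                    evaluations = evals,
                    hit = best$k == target_k,
                    warning = note))
}

#' First weighted-bias resolution proposal
#'
#' The interpolation rule used by [resolution_search()], exposed directly:
#' `r_this + (r_max - r_min) * (target_k - k_min) / (k_max - k_min)` with
#' `r_this` the bracket lower bound.
#'
#' @param r_this current resolution (the bracket lower bound).
#' @param r_min,r_max the resolution bracket.
#' @param k_min,k_max cluster counts observed at `r_min` and `r_max`.
#' @param target_k desired cluster count.
#'
#' @return the proposed next resolution.
#' @export
next_resolution <- function(r_this, r_min, r_max, k_min, k_max, target_k) {
  if (k_max == k_min) stop("flat cluster-count response: k_max == k_min",
                           call. = FALSE)
  r_this + (r_max - r_min) * (target_k - k_min) / (k_max - k_min)
}

prepare_embedding <- function(m, variant, cfg, seed) {
  t <- tfidf(m, variant, binarize = cfg$binarize)
  d <- min(cfg$n_components, min(dim(m$counts)) - 1L)
  if (d < 2L) stop("too few peaks/cells for a 2-component embedding",
                   call. = FALSE)
  pca_embed(t, d, seed = seed)
}

#' Estimate k by the WSS elbow criterion
#'
#' TF-IDF (V1) -> PCA -> K-means at every candidate k -> within-cluster
#' sum-of-squares -> knee of the k-versus-WSS curve. When the curve has no
#' knee (no curvature), falls back to the k minimizing `WSS * k` with a
#' warning flag.
#'
#' @param m a validated [peak_cell_matrix()].
#' @param kr a [k_range()].
#' @param cfg a [cask_config()].
#' @param seed integer seed.
#'
#' @return a list with `k`, `curve` (data.frame of k and score),
#'   `criterion`, and `fallback` flag.
#' @export
estimate_k_wss <- function(m, kr = k_range(), cfg = cask_config(),
                           seed = 0L) {
  kr <- clip_k_range(kr, ncol(m$counts))
  cask_log("WSS estimator: TF-IDF V1 + PCA", verbose = cfg$verbose)
  e <- prepare_embedding(m, "V1", cfg, child_seed(seed, 11L))
  ks <- seq.int(kr$k_min, kr$k_max)
  score <- vapply(ks, function(k) {
    labs <- kmeans_partition(e, k, seed = child_seed(seed, 12L, k),
                             n_init = cfg$n_init,
                             iter_max = cfg$kmeans_iter_max)
    wss(e, labs)
  }, 0)
  fallback <- FALSE
  k_hat <- tryCatch(knee_point(ks, score, tol = cfg$knee_tol),
                    cask_no_knee = function(cond) {
                      fallback <<- TRUE
                      as.integer(ks[which.min(score * ks)])
                    })
  if (fallback) {
    cask_log("WSS curve has no knee; using penalized-score fallback",
             verbose = cfg$verbose)
  }
  list(k = k_hat, curve = data.frame(k = ks, score = score),
       criterion = "wss_elbow", fallback = fallback)
}

#' Estimate k by the Davies-Bouldin criterion
#'
#' TF-IDF (V2) -> PCA -> K-means at every candidate k -> Davies-Bouldin
#' index -> argmin over k (ties toward smaller k).
#'
#' @inheritParams estimate_k_wss
#'
#' @return a list with `k`, `curve`, `criterion`.
#' @export
estimate_k_db <- function(m, kr = k_range(), cfg = cask_config(),
                          seed = 0L) {
  kr <- clip_k_range(kr, ncol(m$counts))
  cask_log("Davies-Bouldin estimator: TF-IDF V2 + PCA", verbose = cfg$verbose)
  e <- prepare_embedding(m, "V2", cfg, child_seed(seed, 21L))
  ks <- seq.int(kr$k_min, kr$k_max)
  score <- vapply(ks, function(k) {
    labs <- kmeans_partition(e, k, seed = child_seed(seed, 22L, k),
                             n_init = cfg$n_init,
                             iter_max = cfg$kmeans_iter_max)
    davies_bouldin(e, labs)
  }, 0)
  if (all(!is.finite(score))) {
    stop("Davies-Bouldin index degenerate (infinite) at every candidate k",
         call. = FALSE)
  }
  list(k = as.integer(ks[which.min(score)]),
       curve = data.frame(k = ks, score = score),
       criterion = "davies_bouldin")
}

#' Estimate k by the summed Louvain + Leiden silhouette criterion
#'
#' TF-IDF (V2) -> PCA -> kNN graph; for every candidate k a partition of
#' that size is sought with [resolution_search()] under Louvain and under
#' Leiden, the mean silhouette of each partition is computed in embedding
#' space, and the candidate's score is the sum of the two means (in
#' `[-2, 2]`). Returns the argmax k (ties toward smaller k). When a search
#' cannot achieve k exactly the closest achieved partition is scored and
#' the point is flagged.
#'
#' @inheritParams estimate_k_wss
#'
#' @return a list with `k`, `curve` (k, score, achieved counts and flags),
#'   `criterion`, and `evaluations` (total clustering calls per method).
#' @export
estimate_k_silhouette <- function(m, kr = k_range(), cfg = cask_config(),
                                  seed = 0L) {
  kr <- clip_k_range(kr, ncol(m$counts))
  cask_log("silhouette estimator: TF-IDF V2 + PCA + kNN graph",
           verbose = cfg$verbose)
  e <- prepare_embedding(m, "V2", cfg, child_seed(seed, 21L))
  n <- nrow(e$coords)
  g <- knn_graph(e, n_neighbors = min(cfg$n_neighbors, n - 1L))
  dmat <- as.matrix(stats::dist(e$coords))
  ks <- seq.int(kr$k_min, kr$k_max)
  caches <- list(louvain = new.env(parent = emptyenv()),
                 leiden = new.env(parent = emptyenv()))
  evaluations <- c(louvain = 0L, leiden = 0L)
  sil_of <- function(labels) {
    if (length(unique(labels)) < 2L) return(NA_real_)
    mean_silhouette(e, labels, dist_matrix = dmat)
  }
  rows <- lapply(ks, function(k) {
    per <- lapply(c("louvain", "leiden"), function(method) {
      rs <- resolution_search(g, k, method = method, cfg = cfg,
                              seed = child_seed(seed, 23L),
                              cache = caches[[method]])
      evaluations[method] <<- evaluations[method] + rs$state$evaluations
      list(sil = sil_of(rs$labels), achieved = rs$achieved_k,
           hit = rs$state$hit)
    })
    sils <- vapply(per, `[[`, 0, "sil")
    data.frame(k = k,
               score = if (anyNA(sils)) NA_real_ else sum(sils),
               achieved_louvain = per[[1]]$achieved,
               achieved_leiden = per[[2]]$achieved,
               exact = per[[1]]$hit && per[[2]]$hit)
  })
  curve <- do.call(rbind, rows)
  ok <- !is.na(curve$score)
  if (!any(ok)) {
    stop("no candidate k yielded a scorable partition", call. = FALSE)
  }
  # argmax score; on ties prefer candidates the searches achieved exactly
  # (a flagged point scores a stand-in partition of a different size, so it
  # must not shadow the genuine candidate), then smaller k
  cand <- curve[ok, ]
  cand <- cand[order(-cand$score, !cand$exact, cand$k), ]
  k_hat <- cand$k[1L]
  list(k = as.integer(k_hat), curve = curve, criterion = "silhouette_sum",
       evaluations = evaluations)
}

#' Ensemble estimate of the number of cell types
#'
#' Runs the three per-criterion estimators — WSS elbow ([estimate_k_wss()]),
#' Davies-Bouldin minimum ([estimate_k_db()]) and summed Louvain + Leiden
#' silhouette maximum ([estimate_k_silhouette()]) — and reports the rounded
#' arithmetic mean of their estimates (halves round away from zero). The
#' input is degenerate-filtered first. If an estimator fails, the ensemble
#' is taken over the remaining estimates and the report is flagged as
#' degraded.
#'
#' @param m a [peak_cell_matrix()].
#' @param kr a [k_range()]; the upper end is clipped to `n - 1`.
#' @param cfg a [cask_config()].
#' @param seed integer master seed; all randomness (PCA solver, K-means
#'   restarts, community detection) derives from it.
#'
#' @return an object of class `cask_report`: per-criterion estimates
#'   `k_wss`, `k_db`, `k_sil`, the ensemble `k_ensemble`, the three score
#'   curves, search evaluation counts, the resolved configuration, the
#'   seed, and any warnings.
#' @export
ensemble_estimate <- function(m, kr = k_range(), cfg = cask_config(),
                              seed = 0L) {
  validate_pcm(m)
  seed <- as.integer(seed)
  m <- filter_degenerate(m, verbose = cfg$verbose)
  runs <- list(
    wss = function() estimate_k_wss(m, kr, cfg, seed),
    db = function() estimate_k_db(m, kr, cfg, seed),
    sil = function() estimate_k_silhouette(m, kr, cfg, seed)
  )
  results <- list(); warnings <- character()
  for (nm in names(runs)) {
    results[[nm]] <- tryCatch(runs[[nm]](), error = function(e) {
      warnings <<- c(warnings,
                     paste0(nm, " estimator failed: ", conditionMessage(e)))
      NULL
    })
  }
  ks <- vapply(results, function(r) if (is.null(r)) NA_integer_ else r$k,
               0L)
  if (all(is.na(ks))) stop("all three estimators failed", call. = FALSE)
  if (!is.null(results$wss) && isTRUE(results$wss$fallback)) {
    warnings <- c(warnings, "WSS curve had no knee; penalized-score fallback used")
  }
  k_ensemble <- as.integer(round_half_away(mean(ks, na.rm = TRUE)))
  structure(list(
    k_wss = ks[["wss"]], k_db = ks[["db"]], k_sil = ks[["sil"]],
    k_ensemble = k_ensemble,
    curves = lapply(results, function(r) r$curve),
    search_evaluations = if (is.null(results$sil)) NULL else
      results$sil$evaluations,
    degraded = any(is.na(ks)),
    warnings = warnings,
    config_echo = unclass(cfg),
    k_range = unclass(clip_k_range(kr, ncol(m$counts))),
    n_cells = ncol(m$counts), n_peaks = nrow(m$counts),
    seed = seed
  ), class = "cask_report")
}

#' @export
print.cask_report <- function(x, ...) {
  cat("Ensemble cell-type-number estimate\n")
  cat(sprintf("  data: %d peaks x %d cells, k grid [%d, %d], seed %d\n",
              x$n_peaks, x$n_cells, x$k_range$k_min, x$k_range$k_max,
              x$seed))
  cat(sprintf("  WSS elbow:          k = %s\n", x$k_wss))
  cat(sprintf("  Davies-Bouldin min: k = %s\n", x$k_db))
  cat(sprintf("  silhouette max:     k = %s\n", x$k_sil))
  cat(sprintf("  ensemble:           k = %d\n", x$k_ensemble))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Compare weighted-bias search against plain bisection
#'
#' Benchmark battery for the resolution search: generates small synthetic
#' data sets spanning several true cell-type numbers, builds the standard
#' embedding and kNN graph for each, and runs [resolution_search()] toward
#' a range of target counts under both proposal rules (no evaluation
#' cache). Reports the clustering-evaluation count per instance and
#' strategy.
#'
#' @param seed integer seed controlling both the generated instances and
#'   the clusterings.
#' @param n_instances number of (data set, target) instances (>= 20 gives
#'   a stable mean).
#'
#' @return a data.frame with one row per instance: `k_true`, `target`,
#'   `method`, evaluation counts `weighted` and `bisection`, and the
#'   achieved counts under each strategy.
#' @export
search_eval_battery <- function(seed = 0L, n_instances = 24L) {
  cfg <- cask_config(n_components = 15, n_neighbors = 10)
  rows <- vector("list", n_instances)
  for (i in seq_len(n_instances)) {
    k_true <- 4L + (i %% 4L)
    sim <- simulate_sccas(synthetic_spec(
      k_true = k_true, cells_per_type = 80L, n_peaks = 500L,
      n_marker_peaks_per_type = 40L, seed = child_seed(seed, i)))
    e <- pca_embed(tfidf(sim$matrix, "V2"), cfg$n_components,
                   seed = child_seed(seed, i, 1L))
    g <- knn_graph(e, cfg$n_neighbors)
    # targets span the achievable cluster-count range of such graphs
    # (counts run from k_true at r_min to roughly 12-14 at r_max),
    # mirroring how the silhouette estimator sweeps its k grid
    target <- 3L + (i %% 10L)
    method <- if (i %% 2L == 0L) "louvain" else "leiden"
    rw <- resolution_search(g, target, method = method, cfg = cfg,
                            seed = child_seed(seed, i, 2L),
                            strategy = "weighted-bias")
    rb <- resolution_search(g, target, method = method, cfg = cfg,
                            seed = child_seed(seed, i, 2L),
                            strategy = "bisection")
    rows[[i]] <- data.frame(k_true = k_true, target = target,
                            method = method,
                            weighted = rw$state$evaluations,
                            bisection = rb$state$evaluations,
                            achieved_weighted = rw$achieved_k,
                            achieved_bisection = rb$achieved_k)
  }
  do.call(rbind, rows)
}
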