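# Cluster-structured synthetic scCAS matrices with known cell-type number,
# imbalance, sparsity and dropout. Each cell type owns a disjoint block of
# marker peaks that are accessible with probability p_signal in its cells;
# everything else is background at p_background. Accessible entries carry
# a count of 1 + Poisson(depth_lambda) so TF-IDF sees nontrivial term
# frequencies, not just presence/absence.

#' Specification of a synthetic scCAS data set
#'
#' @param k_true number of cell types (>= 2).
#' @param cells_per_type integer vector of length `k_true` (recycled from a
#'   scalar); unequal values model cell-type imbalance.
#' @param n_peaks total number of peaks.
#' @param n_marker_peaks_per_type marker peaks owned by each type; blocks
#'   are disjoint, so `k_true * n_marker_peaks_per_type <= n_peaks`.
#' @param p_signal accessibility probability at a cell's own marker peaks.
#' @param p_background accessibility probability elsewhere; must be below
#'   `p_signal`. Together with the marker fraction this sets the overall
#'   sparsity.
#' @param depth_lambda mean of the Poisson extra-count at accessible
#'   entries (accessible counts are `1 + Poisson(depth_lambda)`).
#' @param dropout_rate fraction of nonzero entries zeroed uniformly at
#'   random after generation, in `[0, 1)`.
#' @param seed integer seed; generation is fully deterministic given it.
#'
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(k_true = 5L,
                           cells_per_type = 200L,
                           n_peaks = 2000L,
                           n_marker_peaks_per_type = 100L,
                           p_signal = 0.3,
                           p_background = 0.02,
                           depth_lambda = 1.0,
                           dropout_rate = 0,
                           seed = 0L) {
  k_true <- as.integer(k_true)
  if (k_true < 2L) stop("k_true must be >= 2", call. = FALSE)
  cells_per_type <- as.integer(rep_len(cells_per_type, k_true))
  if (any(cells_per_type < 1L)) stop("cells_per_type must be positive",
                                     call. = FALSE)
  if (!(p_signal > p_background)) {
    stop("p_signal must exceed p_background", call. = FALSE)
  }
  if (p_background < 0 || p_signal > 1) {
    stop("accessibility probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (k_true * n_marker_peaks_per_type > n_peaks) {
    stop("marker blocks exceed the number of peaks: need k_true * ",
         "n_marker_peaks_per_type <= n_peaks", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (depth_lambda < 0) stop("depth_lambda must be >= 0", call. = FALSE)
  structure(list(k_true = k_true, cells_per_type = cells_per_type,
                 n_peaks = as.integer(n_peaks),
                 n_marker_peaks_per_type = as.integer(n_marker_peaks_per_type),
                 p_signal = p_signal, p_background = p_background,
                 depth_lambda = depth_lambda, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic scCAS matrix with known cell types
#'
#' Entry `(i, j)` is accessible with probability `p_signal` when peak i
#' lies in the marker block of cell j's type and `p_background` otherwise;
#' accessible entries receive a count of `1 + Poisson(depth_lambda)`. Peak
#' coordinates are consecutive non-overlapping intervals on the synthetic
#' chromosome `chrSYN`. If `dropout_rate > 0` the dropout process of
#' [apply_dropout()] is applied and ground-truth labels follow the
#' surviving cells.
#'
#' @param spec a [synthetic_spec()].
#'
#' @return a list with `matrix` (a [peak_cell_matrix()]) and `labels`
#'   (integer ground-truth type per retained cell, aligned with the
#'   matrix's barcodes).
#' @export
simulate_sccas <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- spec$n_peaks
  n <- sum(spec$cells_per_type)
  labels <- rep.int(seq_len(spec$k_true), spec$cells_per_type)
  prob <- matrix(spec$p_background, p, n)
  for (t in seq_len(spec$k_true)) {
    rows <- seq.int((t - 1L) * spec$n_marker_peaks_per_type + 1L,
                    t * spec$n_marker_peaks_per_type)
    prob[rows, labels == t] <- spec$p_signal
  }
  accessible <- matrix(runif(p * n) < prob, p, n)
  counts <- matrix(0, p, n)
  n_acc <- sum(accessible)
  if (n_acc > 0) {
    counts[accessible] <- 1 + if (spec$depth_lambda > 0) {
      stats::rpois(n_acc, spec$depth_lambda)
    } else 0
  }
  peaks <- data.frame(chrom = "chrSYN",
                      start = (seq_len(p) - 1L) * 1000L,
                      end = (seq_len(p) - 1L) * 1000L + 500L)
  barcodes <- sprintf("CELL%05d_T%02d", seq_len(n), labels)
  m <- peak_cell_matrix(counts, peaks, barcodes)
  if (spec$dropout_rate > 0) {
    m <- apply_dropout(m, spec$dropout_rate,
                       seed = child_seed(spec$seed, 97L))
  } else {
    m <- filter_degenerate(m)
  }
  labels <- labels[match(m$barcodes, barcodes)]
  list(matrix = m, labels = as.integer(labels))
}

#' Random dropout of observed accessibility
#'
#' Models sparser protocols by setting each nonzero entry to zero
#' independently with probability `rate` (Bernoulli thinning of presence),
#' then removing peaks and cells left with no signal
#' ([filter_degenerate()]).
#'
#' @param m a [peak_cell_matrix()].
#' @param rate dropout probability in `[0, 1)`.
#' @param seed integer seed.
#'
#' @return a [peak_cell_matrix()] with thinned entries and no all-zero
#'   peaks or cells.
#' @export
apply_dropout <- function(m, rate, seed = 0L) {
  validate_pcm(m)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(filter_degenerate(m))
  set.seed(as.integer(seed))
  counts <- m$counts
  drop <- runif(length(counts@x)) < rate
  counts@x[drop] <- 0
  counts <- Matrix::drop0(counts)
  out <- structure(list(counts = counts, peaks = m$peaks,
                        barcodes = m$barcodes),
                   class = "peak_cell_matrix")
  filter_degenerate(out)
}
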