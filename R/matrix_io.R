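# Readers, writers and validation for peak-by-cell accessibility matrices.
# Internal orientation is peaks x cells throughout, so every formula in the
# estimation pipeline maps directly onto rows (peaks) and columns (cells).

#' Construct a peak-by-cell matrix object
#'
#' The internal container for scCAS count data: a sparse nonnegative matrix
#' of dimension p peaks x n cells with peak interval annotations (0-based
#' half-open, BED convention) and unique cell barcodes.
#'
#' @param counts matrix-like, p x n, nonnegative, no missing values. Coerced
#'   to a sparse `dgCMatrix`.
#' @param peaks data.frame with columns `chrom`, `start`, `end` and p rows.
#' @param barcodes character vector of n unique cell barcodes.
#'
#' @return an object of class `peak_cell_matrix`: a list with elements
#'   `counts`, `peaks`, `barcodes`.
#' @export
peak_cell_matrix <- function(counts, peaks, barcodes) {
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  if (is(counts, "nMatrix") || is(counts, "lMatrix")) counts <- counts * 1
  counts <- as(as(counts, "generalMatrix"), "CsparseMatrix")
  peaks <- as.data.frame(peaks)
  barcodes <- as.character(barcodes)
  m <- structure(list(counts = counts, peaks = peaks, barcodes = barcodes),
                 class = "peak_cell_matrix")
  validate_pcm(m)
  m
}

validate_pcm <- function(m) {
  counts <- m$counts
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("peak_cell_matrix must have at least one peak and one cell",
         call. = FALSE)
  }
  if (anyNA(counts@x) || any(!is.finite(counts@x))) {
    stop("counts contain NA or non-finite entries", call. = FALSE)
  }
  if (any(counts@x < 0)) {
    stop("counts contain negative entries", call. = FALSE)
  }
  if (nrow(m$peaks) != nrow(counts)) {
    stop("number of peak annotations (", nrow(m$peaks),
         ") does not match number of matrix rows (", nrow(counts), ")",
         call. = FALSE)
  }
  if (length(m$barcodes) != ncol(counts)) {
    stop("number of barcodes (", length(m$barcodes),
         ") does not match number of matrix columns (", ncol(counts), ")",
         call. = FALSE)
  }
  if (anyDuplicated(m$barcodes)) {
    dup <- unique(m$barcodes[duplicated(m$barcodes)])
    stop("duplicate barcodes: ", paste(utils::head(dup, 3), collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("chrom", "start", "end") %in% names(m$peaks))) {
    stop("peaks must have columns chrom, start, end", call. = FALSE)
  }
  if (any(m$peaks$start < 0) || any(m$peaks$end <= m$peaks$start)) {
    stop("peak intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.peak_cell_matrix <- function(x, ...) {
  cat(sprintf("peak_cell_matrix: %d peaks x %d cells, %d nonzero (%.2f%% dense)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.peak_cell_matrix <- function(x) dim(x$counts)

parse_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": fewer than 3 columns", call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": non-integer coordinates", call. = FALSE)
  }
  data.frame(chrom = vapply(fields, `[[`, "", 1L), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read a MatrixMarket / BED / barcode triple
#'
#' Reads a peak-by-cell count matrix from the standard three-file export:
#' a MatrixMarket coordinate file (1-based indices on disk), a BED file of
#' peak intervals (rows) and a one-barcode-per-line file (columns). If the
#' stored dimensions only match the annotations after transposition, the
#' matrix is transposed with a warning.
#'
#' @param mtx_path path to the `.mtx` file.
#' @param peaks_bed_path path to the BED peak file (>= 3 columns).
#' @param barcodes_path path to the barcode file, one barcode per line.
#'
#' @return a validated [peak_cell_matrix()].
#' @export
read_mtx_triple <- function(mtx_path, peaks_bed_path, barcodes_path) {
  counts <- Matrix::readMM(mtx_path)
  peaks <- parse_bed(peaks_bed_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  # barcode files are often TSV with the barcode in column 1
  barcodes <- vapply(strsplit(barcodes, "\t", fixed = TRUE), `[[`, "", 1L)
  p <- nrow(peaks); n <- length(barcodes)
  if (nrow(counts) == p && ncol(counts) == n) {
    # orientation already peaks x cells
  } else if (nrow(counts) == n && ncol(counts) == p) {
    warning("matrix stored as cells x peaks (", nrow(counts), " x ",
            ncol(counts), "); transposing to peaks x cells", call. = FALSE)
    counts <- Matrix::t(counts)
  } else {
    stop("matrix dimensions ", nrow(counts), " x ", ncol(counts),
         " match neither ", p, " peaks x ", n, " cells nor its transpose",
         call. = FALSE)
  }
  peak_cell_matrix(counts, peaks, barcodes)
}

#' Write a MatrixMarket / BED / barcode triple
#'
#' Inverse of [read_mtx_triple()]: writes `<prefix>.mtx`, `<prefix>.bed`
#' and `<prefix>.barcodes.tsv`.
#'
#' @param m a [peak_cell_matrix()].
#' @param prefix output path prefix.
#'
#' @return invisibly, the three paths written.
#' @export
write_mtx_triple <- function(m, prefix) {
  validate_pcm(m)
  paths <- c(mtx = paste0(prefix, ".mtx"),
             bed = paste0(prefix, ".bed"),
             barcodes = paste0(prefix, ".barcodes.tsv"))
  Matrix::writeMM(m$counts, paths[["mtx"]])
  utils::write.table(m$peaks[, c("chrom", "start", "end")], paths[["bed"]],
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(m$barcodes, paths[["barcodes"]])
  invisible(paths)
}

# "chr1:100-200" or "chr1_100_200" -> (chrom, start, end); NA row if neither
parse_peak_names <- function(nm) {
  out <- data.frame(chrom = nm, start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  hit1 <- grepl("^(.+):([0-9]+)-([0-9]+)$", nm)
  hit2 <- !hit1 & grepl("^(.+)_([0-9]+)_([0-9]+)$", nm)
  if (any(hit1)) {
    mm <- regmatches(nm[hit1], regexec("^(.+):([0-9]+)-([0-9]+)$", nm[hit1]))
    out$chrom[hit1] <- vapply(mm, `[[`, "", 2L)
    out$start[hit1] <- as.integer(vapply(mm, `[[`, "", 3L))
    out$end[hit1] <- as.integer(vapply(mm, `[[`, "", 4L))
  }
  if (any(hit2)) {
    mm <- regmatches(nm[hit2], regexec("^(.+)_([0-9]+)_([0-9]+)$", nm[hit2]))
    out$chrom[hit2] <- vapply(mm, `[[`, "", 2L)
    out$start[hit2] <- as.integer(vapply(mm, `[[`, "", 3L))
    out$end[hit2] <- as.integer(vapply(mm, `[[`, "", 4L))
  }
  out
}

h5_index_column <- function(path, group) {
  attrs <- tryCatch(rhdf5::h5readAttributes(path, group),
                    error = function(e) list())
  idx <- attrs[["_index"]]
  if (is.null(idx)) idx <- "_index"
  as.character(idx)
}

#' Read an AnnData (.h5ad) container
#'
#' Reads the observations-by-variables matrix `X` of an AnnData HDF5 file
#' (dense, CSR or CSC) and transposes it into the internal peaks-by-cells
#' orientation. Peak intervals are taken from `var` columns named
#' `chrom`/`start`/`end` (or `chr`) when present, otherwise parsed from
#' variable names of the form `chr1:100-200` or `chr1_100_200`; names that
#' parse as neither yield placeholder intervals `(name, 0, 1)` with a
#' warning.
#'
#' @param path path to the `.h5ad` file.
#'
#' @return a validated [peak_cell_matrix()].
#' @export
read_h5ad <- function(path) {
  contents <- rhdf5::h5ls(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  if (!any(contents$group == "/" & contents$name == "X")) {
    stop("no X matrix found in ", path, call. = FALSE)
  }
  x_is_group <- any(contents$group == "/" & contents$name == "X" &
                      contents$otype == "H5I_GROUP")
  if (x_is_group) {
    attrs <- rhdf5::h5readAttributes(path, "X")
    enc <- attrs[["encoding-type"]]
    shape <- as.integer(attrs[["shape"]])  # (n_obs, n_var)
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    if (is.null(enc)) enc <- "csr_matrix"
    if (grepl("^csr", enc)) {
      # CSR over obs x var read column-compressed gives var x obs directly
      counts <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                     dims = c(shape[2], shape[1]))
    } else if (grepl("^csc", enc)) {
      counts <- Matrix::t(Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                               x = data,
                                               dims = c(shape[1], shape[2])))
    } else {
      stop("unsupported X encoding '", enc, "' in ", path, call. = FALSE)
    }
  } else {
    # rhdf5 returns the row-major (obs x var) dataset as var x obs in R
    counts <- rhdf5::h5read(path, "X")
  }
  p <- nrow(counts); n <- ncol(counts)
  if (n < 1L || p < 1L) {
    stop("h5ad container has ", n, " cells and ", p, " peaks", call. = FALSE)
  }
  idx_obs <- h5_index_column(path, "obs")
  barcodes <- as.character(rhdf5::h5read(path, paste0("obs/", idx_obs)))
  idx_var <- h5_index_column(path, "var")
  var_names <- as.character(rhdf5::h5read(path, paste0("var/", idx_var)))

  var_children <- contents$name[contents$group == "/var"]
  chrom_col <- intersect(c("chrom", "chr"), var_children)
  if (length(chrom_col) && all(c("start", "end") %in% var_children)) {
    peaks <- data.frame(
      chrom = as.character(rhdf5::h5read(path, paste0("var/", chrom_col[1]))),
      start = as.integer(rhdf5::h5read(path, "var/start")),
      end = as.integer(rhdf5::h5read(path, "var/end")),
      stringsAsFactors = FALSE)
  } else {
    peaks <- parse_peak_names(var_names)
    if (anyNA(peaks$start)) {
      warning(sum(is.na(peaks$start)), " peak name(s) not parseable as ",
              "intervals; using placeholder coordinates", call. = FALSE)
      peaks$start[is.na(peaks$start)] <- 0L
      peaks$end[is.na(peaks$end)] <- 1L
    }
  }
  peak_cell_matrix(counts, peaks, barcodes)
}

#' Remove all-zero peaks and cells
#'
#' Drops peak rows and cell columns whose totals are zero, iterating until a
#' fixed point (removing cells can empty peaks and vice versa). Required so
#' downstream TF-IDF denominators (per-cell totals, per-peak detection
#' counts) are nonzero.
#'
#' @param m a [peak_cell_matrix()].
#' @param verbose log the number of removed peaks/cells.
#'
#' @return a [peak_cell_matrix()] in which every peak and cell has at least
#'   one nonzero entry.
#' @export
filter_degenerate <- function(m, verbose = FALSE) {
  validate_pcm(m)
  counts <- m$counts
  keep_p <- rep(TRUE, nrow(counts)); keep_n <- rep(TRUE, ncol(counts))
  repeat {
    rs <- Matrix::rowSums(counts)
    cs <- Matrix::colSums(counts)
    drop_p <- rs == 0; drop_n <- cs == 0
    if (!any(drop_p) && !any(drop_n)) break
    counts <- counts[!drop_p, !drop_n, drop = FALSE]
    keep_p[keep_p] <- !drop_p
    keep_n[keep_n] <- !drop_n
    if (nrow(counts) == 0L || ncol(counts) == 0L) {
      stop("all peaks or all cells removed by degenerate filtering",
           call. = FALSE)
    }
  }
  n_drop_p <- sum(!keep_p); n_drop_n <- sum(!keep_n)
  if (n_drop_p + n_drop_n > 0) {
    cask_log("filter_degenerate: removed ", n_drop_p, " peak(s) and ",
             n_drop_n, " cell(s)", verbose = verbose)
    m <- structure(list(counts = counts,
                        peaks = m$peaks[keep_p, , drop = FALSE],
                        barcodes = m$barcodes[keep_n]),
                   class = "peak_cell_matrix")
    validate_pcm(m)
  }
  m
}
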