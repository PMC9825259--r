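write_triple_fixture <- function(dir, mtx_lines, bed_lines, barcodes) {
  paths <- list(mtx = file.path(dir, "m.mtx"),
                bed = file.path(dir, "p.bed"),
                barcodes = file.path(dir, "b.tsv"))
  writeLines(mtx_lines, paths$mtx)
  writeLines(bed_lines, paths$bed)
  writeLines(barcodes, paths$barcodes)
  paths
}

test_that("mtx triple is read with 1-based disk to internal coordinate mapping", {
  dir <- withr::local_tempdir()
  paths <- write_triple_fixture(
    dir,
    c("%%MatrixMarket matrix coordinate integer general",
      "3 2 2", "1 1 2", "3 2 1"),
    c("chr1\t0\t100", "chr1\t200\t300", "chr2\t0\t50"),
    c("AAA", "BBB"))
  m <- read_mtx_triple(paths$mtx, paths$bed, paths$barcodes)
  expect_s3_class(m, "peak_cell_matrix")
  expect_equal(dim(m$counts), c(3L, 2L))
  dense <- as.matrix(m$counts)
  expect_equal(dense[1, 1], 2)
  expect_equal(dense[3, 2], 1)
  expect_equal(sum(dense), 3)
  expect_equal(m$peaks$start, c(0L, 200L, 0L))
})

test_that("transposed mtx orientation is detected and fixed with a warning", {
  dir <- withr::local_tempdir()
  paths <- write_triple_fixture(
    dir,
    c("%%MatrixMarket matrix coordinate integer general",
      "2 3 2", "1 1 2", "2 3 1"),
    c("chr1\t0\t100", "chr1\t200\t300", "chr2\t0\t50"),
    c("AAA", "BBB"))
  expect_warning(m <- read_mtx_triple(paths$mtx, paths$bed, paths$barcodes),
                 "transposing")
  expect_equal(dim(m$counts), c(3L, 2L))
  expect_equal(as.matrix(m$counts)[1, 1], 2)
  expect_equal(as.matrix(m$counts)[3, 2], 1)
})

test_that("malformed inputs raise informative errors", {
  dir <- withr::local_tempdir()
  paths <- write_triple_fixture(
    dir,
    c("%%MatrixMarket matrix coordinate integer general",
      "3 2 1", "1 1 2"),
    c("chr1\t0\t100", "chr1\t200\t300", "chr2\t0\t50"),
    c("AAA", "AAA"))
  expect_error(read_mtx_triple(paths$mtx, paths$bed, paths$barcodes),
               "duplicate barcodes")

  writeLines(c("chr1\t0\t100", "chr1\t200"), paths$bed)
  writeLines(c("AAA", "BBB"), paths$barcodes)
  expect_error(read_mtx_triple(paths$mtx, paths$bed, paths$barcodes),
               "BED line 2")

  # dimensions match neither orientation
  writeLines(c("chr1\t0\t100", "chr1\t200\t300", "chr2\t0\t50",
               "chr2\t60\t80"), paths$bed)
  expect_error(read_mtx_triple(paths$mtx, paths$bed, paths$barcodes),
               "neither")
})

test_that("write/read round-trip preserves the coordinate set exactly", {
  dir <- withr::local_tempdir()
  m <- tiny_pcm()
  prefix <- file.path(dir, "rt")
  write_mtx_triple(m, prefix)
  m2 <- read_mtx_triple(paste0(prefix, ".mtx"), paste0(prefix, ".bed"),
                        paste0(prefix, ".barcodes.tsv"))
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
  expect_equal(m2$barcodes, m$barcodes)
  expect_equal(m2$peaks$start, m$peaks$start)
})

test_that("h5ad containers (sparse and dense) match the mtx reader", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1, 0, 2, 0, 3, 0), nrow = 2, byrow = TRUE)  # obs x var
  var_names <- c("chr1:100-200", "chr1:300-400", "chr2:10-20")
  obs_names <- c("AAA", "BBB")

  p_csr <- write_fake_h5ad(file.path(dir, "a.h5ad"), X, obs_names,
                           var_names, "csr")
  m <- read_h5ad(p_csr)
  expect_equal(dim(m$counts), c(3L, 2L))
  expect_equal(as.matrix(m$counts), t(X), ignore_attr = TRUE)
  expect_equal(m$peaks$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(m$peaks$start, c(100L, 300L, 10L))
  expect_equal(m$peaks$end, c(200L, 400L, 20L))
  expect_equal(m$barcodes, obs_names)

  p_dense <- write_fake_h5ad(file.path(dir, "d.h5ad"), X, obs_names,
                             var_names, "dense")
  m2 <- read_h5ad(p_dense)
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts),
               ignore_attr = TRUE)

  # triple with the same content is element-wise identical
  prefix <- file.path(dir, "eq")
  write_mtx_triple(m, prefix)
  m3 <- read_mtx_triple(paste0(prefix, ".mtx"), paste0(prefix, ".bed"),
                        paste0(prefix, ".barcodes.tsv"))
  expect_equal(as.matrix(m3$counts), as.matrix(m$counts),
               ignore_attr = TRUE)
})

test_that("unparseable h5ad peak names fall back to placeholders with a warning", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1, 1, 0, 2), nrow = 2)
  p <- write_fake_h5ad(file.path(dir, "w.h5ad"), X, c("A", "B"),
                       c("chr1:5-9", "weird_peak"), "csr")
  expect_warning(m <- read_h5ad(p), "placeholder")
  expect_equal(m$peaks$start, c(5L, 0L))
  expect_equal(m$peaks$end, c(9L, 1L))
})

test_that("filter_degenerate iterates to a fixed point and is idempotent", {
  # [[1,0],[0,0]]: dropping the empty peak and empty cell leaves 1x1
  m <- peak_cell_matrix(matrix(c(1, 0, 0, 0), 2, 2),
                        data.frame(chrom = "c", start = c(0L, 100L),
                                   end = c(50L, 150L)),
                        c("A", "B"))
  f <- filter_degenerate(m)
  expect_equal(dim(f$counts), c(1L, 1L))
  expect_equal(as.matrix(f$counts)[1, 1], 1)
  expect_equal(f$barcodes, "A")

  # untouched matrix comes back unchanged; applying twice equals once
  m2 <- tiny_pcm()
  f1 <- filter_degenerate(m2)
  expect_equal(as.matrix(f1$counts), as.matrix(m2$counts))
  expect_equal(filter_degenerate(f1), f1)

  # everything zeroed is an error
  expect_error(
    filter_degenerate(peak_cell_matrix(
      matrix(0, 2, 2) + diag(0, 2),
      data.frame(chrom = "c", start = c(0L, 100L), end = c(50L, 150L)),
      c("A", "B"))),
    "at least one|removed")
})

test_that("structural validation rejects bad containers", {
  peaks2 <- data.frame(chrom = "c", start = c(0L, 100L),
                       end = c(50L, 150L))
  expect_error(peak_cell_matrix(matrix(-1, 2, 2), peaks2, c("A", "B")),
               "negative")
  expect_error(peak_cell_matrix(matrix(NA_real_, 2, 2), peaks2,
                                c("A", "B")),
               "NA|non-finite")
  expect_error(peak_cell_matrix(matrix(1, 2, 2), peaks2[1, ], c("A", "B")),
               "peak annotations")
  expect_error(peak_cell_matrix(matrix(1, 2, 2),
                                data.frame(chrom = "c", start = c(0L, 200L),
                                           end = c(50L, 150L)),
                                c("A", "B")),
               "start < end")
})
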