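test_that("TSV and MatrixMarket round-trips preserve the counts", {
  dir <- withr::local_tempdir()
  m <- matrix(c(0L, 2L, 1L, 3L), 2, 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  cm <- count_matrix(m, gene_lengths = c(1000, 2000))
  tsv <- file.path(dir, "counts.tsv")
  len <- file.path(dir, "lengths.tsv")
  write_counts(cm, tsv, lengths_path = len)
  back <- read_counts(tsv, "tsv", lengths_path = len)
  expect_identical(back$counts, cm$counts)
  expect_equal(unname(back$gene_lengths), c(1000, 2000))

  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  writeLines(rownames(m), file.path(dir, "counts.rownames"))
  writeLines(colnames(m), file.path(dir, "counts.colnames"))
  back2 <- read_counts(mtx, "mtx")
  expect_identical(back2$counts, cm$counts)
})

test_that("malformed inputs are rejected with the offending gene or cell named", {
  dir <- withr::local_tempdir()
  m <- matrix(1:4, 2, 2, dimnames = list(c("gA", "gB"), c("c1", "c2")))
  tsv <- file.path(dir, "c.tsv"); len <- file.path(dir, "l.tsv")
  write_counts(count_matrix(m), tsv)
  writeLines(c("gene_id\tlength_bp", "gA\t500"), len)   # gB missing
  expect_error(read_counts(tsv, "tsv", lengths_path = len), "gB")
  expect_error(count_matrix(matrix(c(1.5, 1, 2, 3), 2, 2,
                                   dimnames = list(c("gA", "gB"), NULL))),
               "integer")
  expect_error(count_matrix(matrix(c(-1L, 1L, 2L, 3L), 2, 2,
                                   dimnames = list(c("gA", "gB"), NULL))),
               "non-negative")
  expect_error(count_matrix(matrix(1:6, 3, 2), gene_lengths = c(100, 200)),
               "one length per gene")
  zc <- count_matrix(cbind(c(5L, 3L), c(0L, 0L)))
  expect_error(compute_norm_factors(zc), "all-zero")
  expect_error(compute_norm_factors(count_matrix(matrix(1:3, 3, 1))),
               "2 cells")
})

test_that("scale normalization behaves like TMM times library size, geometric mean 1", {
  base <- matrix(rep(c(100L, 50L, 20L, 500L, 10L), 3), ncol = 3)
  cm <- compute_norm_factors(count_matrix(base))
  expect_equal(unname(cm$norm_factors), rep(1, 3), tolerance = 1e-9)

  # doubling one cell's column doubles its factor relative to the others
  doubled <- base; doubled[, 2] <- doubled[, 2] * 2L
  cm2 <- compute_norm_factors(count_matrix(doubled))
  expect_equal(unname(cm2$norm_factors[2] / cm2$norm_factors[1]), 2,
               tolerance = 1e-9)
  expect_equal(exp(mean(log(cm2$norm_factors))), 1, tolerance = 1e-9)

  # proportional compositions: factors follow library-size ratios
  prop <- cbind(base[, 1], base[, 1] * 2L, base[, 1] * 4L)
  cm3 <- compute_norm_factors(count_matrix(prop))
  f <- unname(cm3$norm_factors)
  expect_equal(f / f[1], c(1, 2, 4), tolerance = 1e-9)

  # normalized counts agree across the doubled cell
  nc <- normalized_counts(cm2)
  expect_equal(nc[, 2], nc[, 1], tolerance = 1e-9)
})

test_that("normalized counts divide by the cell factor only", {
  cm <- count_matrix(matrix(c(100L, 40L), 1, 2,
                            dimnames = list("g", c("a", "b"))))
  expect_identical(normalized_counts(cm), cm$counts)  # t_j = 1
  cm$norm_factors <- c(a = 2, b = 1)
  expect_equal(normalized_counts(cm)["g", "a"], 50)
})

test_that("the expression filter keeps genes at or above the cutoff", {
  counts <- matrix(c(49L, 24L, 50L, 10L, 0L,
                     30L, 49L, 20L, 120L, 0L), ncol = 2)
  cm <- count_matrix(counts)
  cm$norm_factors <- c(1, 1)
  kept <- filter_genes(cm, cutoff = 50)
  expect_identical(rownames(kept$counts), c("gene003", "gene004"))
  # boundary: max normalized 49.9 removed, 50 retained
  cm2 <- count_matrix(matrix(c(499L, 500L), 2, 1))
  cm2$norm_factors <- 10
  expect_identical(rownames(filter_genes(cm2, 50)$counts), "gene002")
  # cutoff 0 retains everything, all-zero genes included
  expect_equal(nrow(filter_genes(cm, 0)$counts), 5)
  # gene order preserved, lengths subset alongside
  cml <- count_matrix(counts, gene_lengths = c(5, 4, 3, 2, 1) * 1000)
  cml$norm_factors <- c(1, 1)
  expect_equal(unname(filter_genes(cml, 50)$gene_lengths), c(3000, 2000))
})

test_that("filtering commutes with normalization because factors are fixed first", {
  set.seed(21)
  m <- matrix(rpois(60, 40), 10, 6)
  cm <- compute_norm_factors(count_matrix(m))
  a <- normalized_counts(filter_genes(cm, 45))
  b <- normalized_counts(cm)[rownames(filter_genes(cm, 45)$counts), ,
                             drop = FALSE]
  expect_equal(a, b)
})

test_that("length offsets are median-scaled bp", {
  cm <- count_matrix(matrix(1L, 3, 2), gene_lengths = c(1000, 2000, 4000))
  expect_equal(unname(length_offsets(cm)), c(0.5, 1, 2))
  expect_equal(length_offsets(count_matrix(matrix(1L, 2, 2))), c(1, 1))
})
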