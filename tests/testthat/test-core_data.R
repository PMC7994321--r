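test_that("cell_dataset validates dimensions and labels", {
  counts <- matrix(0:11, 3, 4)
  ds <- cell_dataset(counts = counts, batch = c("a", "a", "b", "b"))
  expect_s3_class(ds, "cell_dataset")
  expect_equal(n_genes(ds), 3)
  expect_equal(n_cells(ds), 4)
  expect_equal(nlevels(ds$batch), 2)

  expect_error(cell_dataset(counts = counts, batch = c("a", "b")),
               "does not match cell count")
  expect_error(cell_dataset(counts = matrix(-1, 2, 2), batch = c("a", "b")),
               "non-negative integer")
  expect_error(cell_dataset(counts = matrix(1.5, 2, 2), batch = c("a", "b")),
               "non-negative integer")
  expect_error(cell_dataset(batch = character()), "at least one")

  sub <- subset_cells(ds, c(1, 3))
  expect_equal(n_cells(sub), 2)
  expect_equal(sub$counts, counts[, c(1, 3)],
               ignore_attr = TRUE)
  expect_equal(as.character(sub$batch), c("a", "b"))
})

test_that("MTX triplet and dense CSV round-trip through load_dataset", {
  counts <- matrix(c(0L, 1L, 5L, 2L, 0L, 3L, 7L, 1L, 0L, 4L, 2L, 6L), 3, 4)
  ds <- cell_dataset(counts = counts, batch = c("x", "y", "x", "y"),
                     celltype = c("t1", "t1", "t2", "t2"),
                     gene_ids = c("g1", "g2", "g3"),
                     cell_ids = paste0("c", 1:4))
  dir <- tempfile()
  write_mtx(ds, dir)
  rt <- load_dataset(dir, batch_col = "batch", celltype_col = "celltype")
  expect_identical(unname(rt$counts), unname(counts) * 1)
  expect_equal(rt$gene_ids, ds$gene_ids)
  expect_equal(as.character(rt$batch), as.character(ds$batch))
  expect_equal(nlevels(rt$batch), 2)

  # dense CSV with companion metadata
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(counts, row.names = ds$gene_ids) |>
              setNames(ds$cell_ids), csv)
  rt2 <- load_dataset(csv, batch_col = "batch",
                      metadata = file.path(dir, "metadata.tsv"))
  expect_equal(unname(rt2$counts), unname(counts), ignore_attr = TRUE)

  # error path: metadata lacking the batch column names it
  expect_error(load_dataset(dir, batch_col = "donor"), "donor")
})

test_that("H5AD round-trips counts and labels via the python bridge", {
  counts <- matrix(rpois(60, 3), 6, 10)
  ds <- cell_dataset(counts = counts,
                     batch = rep(c("a", "b"), 5),
                     celltype = rep(c("t1", "t2"), each = 5))
  h5 <- tempfile(fileext = ".h5ad")
  write_h5ad(ds, h5)
  rt <- load_dataset(h5, batch_col = "batch", celltype_col = "celltype")
  expect_identical(unname(rt$counts), unname(counts) * 1)
  expect_equal(as.character(rt$batch), as.character(ds$batch))
  expect_equal(as.character(rt$celltype), as.character(ds$celltype))
})

test_that("qc_filter removes outlier cells and sparse genes", {
  # 100 identical cells plus one with 100x the total: MAD is 0, the odd cell
  # is beyond any finite MAD multiple of the median
  counts <- matrix(2L, 30, 101)
  counts[, 101] <- 200L
  ds <- cell_dataset(counts = counts, batch = rep("a", 101))
  f <- qc_filter(ds, nmads = 2.5, min_cells_per_gene = 0)
  expect_equal(n_cells(f), 100)

  # gene detected in 19 cells is dropped at the default threshold of 20
  counts2 <- matrix(5L, 10, 50)
  counts2[1, ] <- 0L
  counts2[1, 1:19] <- 1L
  ds2 <- cell_dataset(counts = counts2, batch = rep(c("a", "b"), 25))
  f2 <- qc_filter(ds2, nmads = Inf, min_cells_per_gene = 20)
  expect_equal(n_genes(f2), 9)
  f2b <- qc_filter(ds2, nmads = Inf, min_cells_per_gene = 19)
  expect_equal(n_genes(f2b), 10)

  # identity configuration changes nothing
  ds3 <- make_counts_ds(seed = 4)
  f3 <- qc_filter(ds3, nmads = Inf, min_cells_per_gene = 0)
  expect_identical(f3$counts, ds3$counts)
  # already-clean data (every cell a permutation of the same profile, so
  # totals/feature counts are identical): qc_filter is the identity, hence
  # idempotent
  withr_seed(9)
  profile <- rpois(40, 5) + 1L
  clean <- cell_dataset(
    counts = sapply(1:30, function(i) sample(profile)),
    batch = rep(c("a", "b"), 15))
  once <- qc_filter(clean, nmads = 2.5, min_cells_per_gene = 5)
  expect_identical(once$counts, clean$counts)
  expect_identical(qc_filter(once, nmads = 2.5, min_cells_per_gene = 5)$counts,
                   once$counts)
})

test_that("normalize_log computes mean-one size factors and log2 values", {
  # equal library sizes: size factors 1, count 3 -> log2(4) = 2
  counts <- matrix(3L, 4, 3)
  ds <- normalize_log(cell_dataset(counts = counts, batch = rep("a", 3)))
  expect_equal(ds$logexpr, matrix(2, 4, 3), ignore_attr = TRUE)

  # library sizes 100 and 200 -> size factors 2/3 and 4/3
  counts2 <- rbind(c(100L, 200L))
  ds2 <- cell_dataset(counts = counts2, batch = c("a", "b"))
  n2 <- normalize_log(ds2)
  expect_equal(n2$logexpr[1, ], log2(c(100 / (2 / 3), 200 / (4 / 3)) + 1),
               ignore_attr = TRUE)

  # all-zero gene stays exactly zero; zero-total cell errors
  counts3 <- rbind(c(0L, 0L), c(2L, 2L))
  expect_equal(normalize_log(
    cell_dataset(counts = counts3, batch = c("a", "b")))$logexpr[1, ],
    c(0, 0), ignore_attr = TRUE)
  expect_error(normalize_log(
    cell_dataset(counts = matrix(c(1L, 0L), 1), batch = c("a", "b"))),
    "zero total")
})

test_that("select_hvg ranks by variance with index tie-breaks", {
  lx <- rbind(rep(1, 6), c(0, 4, 0, 4, 0, 4), rep(2, 6),
              c(0, 2, 0, 2, 0, 2))
  ds <- cell_dataset(logexpr = lx, batch = rep("a", 6))
  expect_equal(select_hvg(ds, 1), 2L)       # the variable gene
  expect_equal(select_hvg(ds, 2), c(2L, 4L))
  expect_setequal(select_hvg(ds, 4), 1:4)   # n = gene count: a permutation
  expect_equal(select_hvg(ds, 4)[3:4], c(1L, 3L))  # tied zeros by index
  expect_error(select_hvg(ds, 5), "exceeds")
})

test_that("compute_pca matches an eigendecomposition oracle", {
  withr_seed(11)
  # rank-2 data: two components carry all variance
  base <- matrix(rnorm(2 * 40), 2, 40)
  mix <- matrix(rnorm(10 * 2), 10, 2)
  ds <- cell_dataset(logexpr = mix %*% base, batch = rep("a", 40))
  p2 <- compute_pca(ds, 2)
  expect_equal(sum(p2$var_explained), 1, tolerance = 1e-8)

  # determinism: identical input -> bit-identical embedding
  expect_identical(p2$embedding, compute_pca(ds, 2)$embedding)

  # random fixture: component variances equal covariance eigenvalues
  lx <- matrix(rnorm(50 * 200), 50, 200)
  ds2 <- cell_dataset(logexpr = lx, batch = rep("a", 200))
  p <- compute_pca(ds2, 10)
  eig <- eigen(stats::cov(t(lx)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p$var, eig[1:10], tolerance = 1e-8)
  expect_equal(p$var_explained, eig[1:10] / sum(eig), tolerance = 1e-8)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  expect_error(compute_pca(ds2, 51), "exceeds")
})

test_that("knn_search is exact (brute-force oracle) and handles ties", {
  # collinear points at 0, 1, 3 with k = 1
  emb <- cbind(c(0, 1, 3))
  g <- knn_search(emb, 1)
  expect_equal(as.vector(g$indices), c(2L, 1L, 2L))
  expect_equal(as.vector(g$distances), c(1, 1, 2))

  # duplicate points: zero distances allowed, self excluded, ties by index
  emb2 <- cbind(c(0, 0, 0, 5))
  g2 <- knn_search(emb2, 2)
  expect_equal(g2$indices[1, ], c(2L, 3L))
  expect_equal(g2$distances[1, ], c(0, 0))
  expect_equal(g2$indices[2, ], c(1L, 3L))

  # 500-cell Gaussian fixture vs all-pairs oracle
  withr_seed(3)
  emb3 <- matrix(rnorm(500 * 5), 500, 5)
  g3 <- knn_search(emb3, 10)
  oracle <- brute_knn(emb3, 10)
  expect_equal(g3$indices, oracle$indices, ignore_attr = TRUE)
  expect_equal(g3$distances, oracle$distances, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(g3$distances[, -1] - g3$distances[, -10] >= 0))
  expect_error(knn_search(emb2, 4), "smaller than")
})

test_that("permute_batch_labels preserves composition; downsample counts", {
  batch <- factor(rep(c("a", "b", "c"), c(30, 20, 10)))
  expect_identical(permute_batch_labels(batch, 0, 7), batch)
  for (f in c(0.3, 0.7, 1)) {
    perm <- permute_batch_labels(batch, f, 7)
    expect_equal(tabulate(perm), tabulate(batch))
  }
  p1 <- permute_batch_labels(batch, 1, 7)
  expect_gt(sum(p1 != batch), 0)
  # fraction = 0.5, n = 10: exactly 5 positions selected
  b10 <- factor(rep(c("a", "b"), 5))
  p5 <- permute_batch_labels(b10, 0.5, 2)
  expect_lte(sum(p5 != b10), 5)

  ds <- make_counts_ds(n_cells = 80, seed = 5)
  expect_identical(downsample_batch(ds, "t1", "b1", 0, 1)$counts, ds$counts)
  d1 <- downsample_batch(ds, "t1", "b1", 1, 1)
  expect_equal(sum(d1$celltype == "t1" & d1$batch == "b1"), 0)
  expect_true("t1" %in% d1$celltype[d1$batch == "b2"])
  n_strat <- sum(ds$celltype == "t1" & ds$batch == "b1")
  d2 <- downsample_batch(ds, "t1", "b1", 0.5, 1)
  expect_equal(n_cells(d2), n_cells(ds) - round(0.5 * n_strat))
  expect_error(downsample_batch(ds, "missing", "b1", 0.5, 1), "empty")
})
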