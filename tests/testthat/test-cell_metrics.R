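test_that("cms scores biased and mixed neighbourhoods as expected", {
  # two interleaved batches: distances from both batches share a
  # distribution -> high p; batch B pushed far out -> low p
  withr_seed(8)
  n <- 300
  emb_mixed <- cbind(rnorm(n), rnorm(n))
  batch <- factor(rep(c("A", "B"), n / 2))
  g <- knn_search(emb_mixed, 100)
  p <- metric_params(k = 100, k_min = 30)
  r <- cms(g, batch, "default", p)
  expect_true(all(r$per_cell >= 0 & r$per_cell <= 1))
  expect_gt(r$global_score, 0.3)

  emb_biased <- emb_mixed
  emb_biased[batch == "B", 1] <- emb_biased[batch == "B", 1] + 4
  gb <- knn_search(emb_biased, 100)
  rb <- cms(gb, batch, "default", p)
  expect_lt(rb$global_score, r$global_score - 0.2)

  # single-batch dataset errors; renaming labels changes nothing
  expect_error(cms(g, factor(rep("A", n)), "default", p), "at least 2")
  ren <- factor(c(A = "z9", B = "z1")[as.character(batch)])
  expect_equal(cms(g, ren, "default", p)$per_cell, r$per_cell)
})

test_that("cms per-cell p-values are uniform under random labels", {
  ds <- gaussian_mixture_embedding(700, n_clusters = 1, n_batches = 4,
                                   batch_shift = 0, seed = 19)
  g <- knn_search(ds$embedding, 200)
  r <- cms(g, ds$batch)
  ks <- suppressWarnings(stats::ks.test(r$per_cell, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(r$global_score, 0.5, tolerance = 0.05)
})

test_that("find_kmin detects the density valley with floor and cap", {
  withr_seed(5)
  # unimodal profile: full neighbourhood kept
  uni <- sort(abs(rnorm(200)))
  expect_equal(find_kmin(uni, 80), 200)
  # bimodal: 100 near 1, 100 near 10 -> cut at the valley
  bi <- sort(c(runif(100, 0.8, 1.2), runif(100, 9, 11)))
  expect_equal(find_kmin(bi, 10), 100)
  # first cluster smaller than the floor (but still the densest mode):
  # floored at k_min
  bi2 <- sort(c(runif(70, 0.95, 1.05), runif(80, 5, 9)))
  expect_lt(sum(bi2 < 3), 80)
  expect_equal(find_kmin(bi2, 80), 80)
  # degenerate identical distances fall back to k
  expect_equal(find_kmin(rep(1, 50), 10), 50)
})

test_that("extend_bmin reaches b_min cells of every batch", {
  withr_seed(6)
  # balanced two batches: neighbourhood size >= 2 * b_min
  emb <- matrix(rnorm(400 * 3), 400, 3)
  batch <- factor(rep(c("A", "B"), 200))
  nb <- extend_bmin(emb, batch, 1, 80)
  expect_gte(length(nb$indices), 160)
  tabs <- table(batch[nb$indices])
  expect_true(all(tabs >= 80))
  # ...and stops as soon as the last batch is satisfied
  expect_equal(min(tabs), 80)

  # remote scarce batch: the last included cell belongs to it
  emb2 <- rbind(matrix(rnorm(100 * 2), 100, 2),
                matrix(rnorm(20 * 2, mean = 50), 20, 2))
  batch2 <- factor(rep(c("A", "B"), c(100, 20)))
  nb2 <- extend_bmin(emb2, batch2, 1, 10)
  expect_equal(as.character(batch2[utils::tail(nb2$indices, 1)]), "B")

  expect_error(extend_bmin(emb2, batch2, 1, 30), "fewer than b_min")
  ds <- gaussian_mixture_embedding(300, n_batches = 2, seed = 3)
  pp <- metric_params(k = 50, k_min = 30, b_min = 400)
  expect_error(cms(NULL, ds$batch, "bmin", pp, embedding = ds$embedding),
               "b_min")
})

test_that("simpson_index evaluates the inverse Simpson formula", {
  batch <- factor(c("A", "A", "A", "A", "B", "B", "B", "B"))
  # neighbourhood entirely one batch -> 1
  g1 <- fake_graph(rbind(c(2, 3, 4)), distances = rbind(c(1, 2, 3)))
  r1 <- simpson_index(fake_graph(matrix(rep(c(2, 3, 4), 8), 8, 3,
                                        byrow = TRUE)), batch, "none")
  expect_equal(unname(r1$per_cell[1]), 1)
  # p = (0.8, 0.2): 1 / (0.64 + 0.04) = 1.470588...
  g2 <- fake_graph(matrix(rep(c(2, 3, 4, 1, 5), 8), 8, 5, byrow = TRUE))
  idx <- rbind(c(2, 3, 4, 1, 5))
  r2 <- simpson_index(fake_graph(matrix(rep(c(1, 2, 3, 4, 5), 8), 8, 5,
                                        byrow = TRUE)), batch, "none")
  expect_equal(unname(r2$per_cell[1]), 1 / (0.8^2 + 0.2^2), tolerance = 1e-12)

  # 4 equal batches with uniform weights -> exactly 4
  b4 <- factor(rep(c("A", "B", "C", "D"), 2))
  g4 <- fake_graph(matrix(rep(1:8, 8), 8, 8, byrow = TRUE))
  r4 <- simpson_index(g4, b4, "none")
  expect_equal(unname(r4$per_cell[1]), 4, tolerance = 1e-12)

  # single-batch dataset: all scores exactly 1, not an error
  r5 <- simpson_index(g4, factor(rep("A", 8)), "none")
  expect_equal(unname(r5$per_cell), rep(1, 8))

  # wisi: duplicated (zero-distance) neighbours dominate
  gd <- fake_graph(matrix(rep(c(2, 5), 8), 8, 2, byrow = TRUE),
                   matrix(rep(c(0, 3), 8), 8, 2, byrow = TRUE))
  rw <- simpson_index(gd, batch, "inverse_square")
  expect_lt(unname(rw$per_cell[1]), 1.01)  # nearly all weight on batch A
})

test_that("lisi calibrates Gaussian weights to the target perplexity", {
  ds <- gaussian_mixture_embedding(600, n_clusters = 1, n_batches = 4,
                                   batch_shift = 0, seed = 23)
  g <- knn_search(ds$embedding, 200)
  r <- simpson_index(g, ds$batch, "gaussian")
  expect_true(all(r$per_cell >= 1 & r$per_cell <= 4 + 1e-9))
  expect_gt(r$global_score, 3)   # well-mixed: near the batch count
  # weight entropy equals log(perplexity) after calibration
  w <- mixscore:::gaussian_weights(g$distances[, 1:90], 30)
  H <- -rowSums(ifelse(w > 0, w * log(w), 0))
  expect_equal(unname(H[1:5]), rep(log(30), 5), tolerance = 1e-3)
})

test_that("entropy evaluates and normalizes the Shannon formula", {
  batch <- factor(c("A", "A", "A", "B", "B", "B", "C", "D"))
  # one-batch neighbourhood -> 0
  g1 <- fake_graph(matrix(rep(c(1, 2, 3), 8), 8, 3, byrow = TRUE))
  expect_equal(unname(entropy(g1, batch)$per_cell[1]), 0)
  # p = (0.75, 0.25) over two observed batches, normalized by log2(4):
  g2 <- fake_graph(matrix(rep(c(1, 2, 3, 4), 8), 8, 4, byrow = TRUE))
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(unname(entropy(g2, batch)$per_cell[1]), h / log2(4),
               tolerance = 1e-12)
  # two-batch dataset: same neighbourhood normalizes to h exactly
  b2 <- factor(c("A", "A", "A", "B", "B", "B", "A", "B"))
  expect_equal(unname(entropy(g2, b2)$per_cell[1]), h, tolerance = 1e-12)
  # uniform 4-batch neighbourhood -> exactly 1
  b4 <- factor(rep(c("A", "B", "C", "D"), 2))
  g4 <- fake_graph(matrix(rep(1:8, 8), 8, 8, byrow = TRUE))
  expect_equal(unname(entropy(g4, b4)$per_cell[1]), 1, tolerance = 1e-12)
  # printed-formula variant divides by the batch count instead
  expect_equal(unname(entropy(g4, b4, normalization = "batch_count")$
                        per_cell[1]), 2 / 4, tolerance = 1e-12)
  # single batch: all zeros
  expect_equal(unname(entropy(g4, factor(rep("A", 8)))$per_cell),
               rep(0, 8))
})

test_that("mixing_metric attains its analytic minima and cap", {
  p <- metric_params()
  # 3 batches, best-case interleaving of the first 15 neighbours -> 10
  batch <- factor(rep(c("A", "B", "C"), length.out = 301))
  idx <- c(which(batch == "A")[2:6], which(batch == "B")[1:5],
           which(batch == "C")[1:5])
  rest <- setdiff(seq_len(301)[-1], idx)
  g <- fake_graph(matrix(rep(c(idx, rest), 301), 301, 300, byrow = TRUE))
  r <- mixing_metric(g, batch, p)
  expect_equal(unname(r$per_cell[1]), 10)

  # 5 batches, same construction -> 15
  b5 <- factor(rep(c("A", "B", "C", "D", "E"), length.out = 301))
  idx5 <- unlist(lapply(c("A", "B", "C", "D", "E"), function(lv) {
    w <- setdiff(which(b5 == lv), 1)
    w[1:5]
  }))
  rest5 <- setdiff(seq_len(301)[-1], idx5)
  g5 <- fake_graph(matrix(rep(c(idx5, rest5), 301), 301, 300, byrow = TRUE))
  expect_equal(unname(mixing_metric(g5, b5, p)$per_cell[1]), 15)

  # a batch missing from the neighbourhood contributes rank k_mm
  b2 <- factor(rep(c("A", "B"), c(400, 200)))
  onlyA <- 2:301                      # 300 neighbours, all batch A
  gA <- fake_graph(matrix(rep(onlyA, 600), 600, 300, byrow = TRUE))
  rA <- mixing_metric(gA, b2, p)
  # median of (rank_A = 5, rank_B = 300) = 152.5
  expect_equal(unname(rA$per_cell[1]), (5 + 300) / 2)
})

test_that("cell metrics respond monotonically to batch separation", {
  deltas <- c(0, 1, 2, 3, 5)
  means <- sapply(deltas, function(d) {
    ds <- gaussian_mixture_embedding(400, n_clusters = 1, n_batches = 2,
                                     batch_shift = d, seed = 77)
    g <- knn_search(ds$embedding, 100)
    p <- metric_params(k = 100)
    c(cms = cms(g, ds$batch, "default", p)$global_score,
      entropy = entropy(g, ds$batch, p)$global_score,
      isi = simpson_index(g, ds$batch, "none", p)$global_score,
      mm = mixing_metric(knn_search(ds$embedding, 150),
                         ds$batch, metric_params(k_mm = 150))$global_score)
  })
  for (m in c("cms", "entropy", "isi")) {
    expect_gte(abs(spearman_rho(deltas, means[m, ])), 0.9)
    expect_lt(means[m, 5], means[m, 1])
  }
  expect_gte(spearman_rho(deltas, means["mm", ]), 0.9)
})
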