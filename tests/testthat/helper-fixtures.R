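# fixture builders shared across test files; all data generated in code

# small Poisson count dataset with balanced batch/celltype labels
make_counts_ds <- function(n_genes = 50, n_cells = 60, n_batches = 2,
                           n_celltypes = 2, lambda = 5, seed = 1) {
  withr_seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  cell_dataset(counts = counts,
               batch = rep_len(paste0("b", seq_len(n_batches)), n_cells),
               celltype = rep_len(rep(paste0("t", seq_len(n_celltypes)),
                                      each = n_batches), n_cells))
}

# fabricate a neighbor_graph row-by-row from explicit batches of neighbours
fake_graph <- function(indices, distances = NULL) {
  indices <- as.matrix(indices)
  if (is.null(distances)) {
    distances <- matrix(rep(seq_len(ncol(indices)), each = nrow(indices)),
                        nrow(indices), ncol(indices))
  }
  structure(list(indices = indices, distances = as.matrix(distances),
                 k = ncol(indices)),
            class = "neighbor_graph")
}

# brute-force exact kNN oracle (independent of knn_search internals)
brute_knn <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  idx <- t(sapply(seq_len(n), function(i) {
    order(d[i, ], seq_len(n))[seq_len(k)]
  }))
  dst <- t(sapply(seq_len(n), function(i) d[i, idx[i, ]]))
  list(indices = idx, distances = dst)
}

# flood-fill connected components oracle on an undirected edge list
flood_components <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0])
    }
  }
  comp
}

withr_seed <- function(seed) set.seed(seed)

# exact permutation-null p-value oracle for the 2-sample AD statistic
# (enumerates all splits of the pooled values)
ad_exact_perm <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  splits <- utils::combn(length(pooled), n1)
  obs <- ad_ksample(list(x, y))$statistic
  stats <- apply(splits, 2, function(ix) {
    ad_ksample(list(pooled[ix], pooled[-ix]))$statistic
  })
  list(p = mean(stats >= obs - 1e-12), stats = stats)
}
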