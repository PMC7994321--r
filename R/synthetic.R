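#' Gaussian-cluster embedding fixture
#'
#' Generates a low-dimensional embedding of well-separated Gaussian
#' cell-type clusters with batch labels, optionally displaced per batch to
#' emulate a batch effect of tunable magnitude. Cluster centres are drawn
#' once from `N(0, sep^2)` per dimension; each batch (beyond the first) gets
#' a random unit direction scaled by `batch_shift` added to its cells. With
#' `batch_shift = 0` the batch labels are pure annotation and the dataset is
#' batch-free by construction.
#'
#' @param n_cells number of cells.
#' @param n_dims embedding dimensionality.
#' @param n_clusters number of cell-type clusters.
#' @param n_batches number of batches (balanced assignment).
#' @param batch_shift Euclidean magnitude of the per-batch displacement, in
#'   units of the within-cluster sd.
#' @param cluster_sd within-cluster standard deviation per dimension.
#' @param sep scale of the cluster-centre spread (default 10, i.e. clusters
#'   well separated relative to `cluster_sd`).
#' @param seed integer seed.
#' @return a [cell_dataset()] with `embedding`, `batch` and `celltype`.
#' @export
gaussian_mixture_embedding <- function(n_cells, n_dims = 10L,
                                       n_clusters = 3L, n_batches = 2L,
                                       batch_shift = 0, cluster_sd = 1,
                                       sep = 10, seed = 1L) {
  with_seed(seed, {
    centers <- matrix(stats::rnorm(n_clusters * n_dims, sd = sep),
                      n_clusters, n_dims)
    ct <- sample.int(n_clusters, n_cells, replace = TRUE)
    # balanced batch assignment, shuffled
    b <- sample(rep_len(seq_len(n_batches), n_cells))
    emb <- centers[ct, , drop = FALSE] +
      matrix(stats::rnorm(n_cells * n_dims, sd = cluster_sd),
             n_cells, n_dims)
    if (batch_shift > 0 && n_batches > 1) {
      for (bb in 2:n_batches) {
        dir <- stats::rnorm(n_dims)
        dir <- dir / sqrt(sum(dir^2)) * batch_shift
        emb[b == bb, ] <- sweep(emb[b == bb, , drop = FALSE], 2, -dir)
      }
    }
    cell_dataset(embedding = emb, batch = paste0("batch", b),
                 celltype = paste0("type", ct))
  })
}
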