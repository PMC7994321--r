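#' Exact k-nearest-neighbour search
#'
#' Brute-force Euclidean k-nearest neighbours for every cell of an embedding.
#' Self is excluded by identity; rows are distance-ascending with ties broken
#' by ascending cell index.
#'
#' @param embedding numeric matrix, cells x D.
#' @param k neighbourhood size (`k < nrow(embedding)`).
#' @return a `neighbor_graph`: list with `indices` and `distances`
#'   (cells x k matrices) and `k`.
#' @export
knn_search <- function(embedding, k) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  sq <- rowSums(embedding^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  block <- max(1L, min(n, floor(2e7 / n)))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- sq[rows] - 2 * tcrossprod(embedding[rows, , drop = FALSE],
                                    embedding) +
      rep(sq, each = length(rows))
    d2[cbind(seq_along(rows), rows)] <- Inf   # exclude self
    for (i in seq_along(rows)) {
      o <- order(d2[i, ], seq_len(n), method = "radix")[seq_len(k)]
      idx[rows[i], ] <- o
      dst[rows[i], ] <- sqrt(pmax(d2[i, o], 0))
    }
  }
  structure(list(indices = idx, distances = dst, k = as.integer(k)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph:", nrow(x$indices), "cells, k =", x$k, "\n")
  invisible(x)
}

# distances from one cell to all others, order and indices (self excluded,
# ties by index); used by the batch-extended cms neighbourhood
all_neighbors <- function(embedding, cell) {
  d2 <- colSums((t(embedding) - embedding[cell, ])^2)
  d2[cell] <- Inf
  o <- order(d2, seq_along(d2), method = "radix")[-length(d2)]
  list(indices = o, distances = sqrt(pmax(d2[o], 0)))
}
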