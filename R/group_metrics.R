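#' kBET-style chi-squared batch composition test
#'
#' For each cell type, compares the batch composition of within-cell-type
#' kNN neighbourhoods against the cell type's overall batch composition with
#' a Pearson chi-squared test, for a random subset of the cell type's cells,
#' and reports the rejection rate at level `params$alpha_kbet`. Expected
#' counts come from the batch proportions *within* the cell type (batches
#' absent from a cell type are dropped, i.e. pooled away, since their
#' observed neighbourhood count is necessarily zero as well). The
#' neighbourhood size is `k0 = ceiling(0.25 * mean per-batch cell count in
#' the cell type)` (capped at the cell-type size) and includes the tested
#' cell itself.
#'
#' @param embedding cells x D matrix (e.g. top principal components).
#' @param batch per-cell batch labels.
#' @param celltype per-cell cell-type labels.
#' @param params a [metric_params()].
#' @param test_size fraction of each cell type's cells tested (at least 25
#'   where available).
#' @param seed integer seed for the tested-cell subsets.
#' @return a `metric_result` with per-cell-type rejection rates in \[0, 1\],
#'   direction -1 (high rejection = batch effect). Cell types with a single
#'   batch score 0.
#' @export
kbet <- function(embedding, batch, celltype, params = metric_params(),
                 test_size = 0.1, seed = 1L) {
  batch <- factor(batch)
  celltype <- factor(celltype)
  if (nlevels(batch) < 2) stop("kbet needs at least 2 batches")
  types <- levels(celltype)
  rates <- stats::setNames(numeric(length(types)), types)
  sizes <- stats::setNames(integer(length(types)), types)
  for (ti in seq_along(types)) {
    cells <- which(celltype == types[ti])
    sizes[ti] <- length(cells)
    comp <- table(droplevels(batch[cells]))
    if (length(comp) < 2) { rates[ti] <- 0; next }
    props <- comp / sum(comp)
    k0 <- min(ceiling(0.25 * mean(comp)), length(cells))
    if (k0 < 2) { rates[ti] <- 0; next }
    sub_emb <- embedding[cells, , drop = FALSE]
    g <- knn_search(sub_emb, k0 - 1L)
    n_test <- min(length(cells), max(ceiling(test_size * length(cells)), 25L))
    tested <- with_seed(derive_seed(seed, ti),
                        sample.int(length(cells), n_test))
    bt <- droplevels(batch[cells])
    rej <- vapply(tested, function(i) {
      nb <- c(i, g$indices[i, ])
      obs <- tabulate(as.integer(bt[nb]), nbins = length(comp))
      expd <- k0 * as.numeric(props)
      stat <- sum((obs - expd)^2 / expd)
      p <- stats::pchisq(stat, df = length(comp) - 1, lower.tail = FALSE)
      p < params$alpha_kbet
    }, NA)
    rates[ti] <- mean(rej)
  }
  new_metric_result("kbet", "celltype", per_group = rates,
                    group_sizes = sizes, direction = -1L, params = params)
}

#' Graph connectivity of cell types
#'
#' Builds a kNN graph (`k = params$k_graph`, undirected union of directed
#' edges) on the full embedding, induces the subgraph of each cell type, and
#' scores each cell type by the fraction of its cells inside the largest
#' connected component. The global score is the unweighted mean over cell
#' types; 1 means every cell type is fully connected (a batch-free dataset
#' under the metric's assumption). The score is independent of the batch
#' labels by construction.
#'
#' @param embedding cells x D matrix.
#' @param celltype per-cell cell-type labels.
#' @param params a [metric_params()].
#' @return a `metric_result` with per-cell-type scores in (0, 1\],
#'   direction +1.
#' @export
graph_connectivity <- function(embedding, celltype, params = metric_params()) {
  celltype <- factor(celltype)
  g <- knn_search(embedding, params$k_graph)
  n <- nrow(g$indices)
  edges <- cbind(rep(seq_len(n), each = params$k_graph),
                 as.vector(t(g$indices)))
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- igraph::simplify(ig)
  types <- levels(celltype)
  scores <- stats::setNames(numeric(length(types)), types)
  sizes <- stats::setNames(integer(length(types)), types)
  for (ti in seq_along(types)) {
    cells <- which(celltype == types[ti])
    sizes[ti] <- length(cells)
    sub <- igraph::induced_subgraph(ig, cells)
    comp <- igraph::components(sub)
    scores[ti] <- max(comp$csize) / length(cells)
  }
  new_metric_result("graph", "celltype", per_group = scores,
                    group_sizes = sizes,
                    global_score = mean(scores),  # unweighted across types
                    direction = 1L, params = params)
}

#' Batch average silhouette width score
#'
#' Within each cell type, computes the silhouette width of every cell with
#' batch as the cluster label (`a_i` = mean distance to same-batch cells,
#' `b_i` = smallest mean distance to another batch,
#' `s_i = (b_i - a_i)/max(a_i, b_i)`), averages to a per-cell-type `asw`, and
#' reports `1 - |asw|` so 1 means mixed batches and 0 separated batches. The
#' global score is the cell-count-weighted mean over scored cell types. A
#' cell alone in its batch within a cell type gets `s_i = 0`; cell types
#' with a single batch are skipped with a warning.
#'
#' @param embedding cells x D matrix (top principal components).
#' @param batch per-cell batch labels.
#' @param celltype per-cell cell-type labels.
#' @return a `metric_result` with per-cell-type scores in \[0, 1\],
#'   direction +1, and per-cell silhouette widths in `per_cell`.
#' @export
asw_batch <- function(embedding, batch, celltype) {
  batch <- factor(batch)
  celltype <- factor(celltype)
  types <- levels(celltype)
  scores <- sizes <- stats::setNames(rep(NA_real_, length(types)), types)
  sil <- rep(NA_real_, length(batch))
  for (ti in seq_along(types)) {
    cells <- which(celltype == types[ti])
    bt <- droplevels(batch[cells])
    if (nlevels(bt) < 2) {
      warning("cell type '", types[ti], "' has a single batch; skipped")
      next
    }
    d <- as.matrix(stats::dist(embedding[cells, , drop = FALSE]))
    s <- numeric(length(cells))
    for (i in seq_along(cells)) {
      same <- which(bt == bt[i])
      same <- same[same != i]
      if (length(same) == 0) { s[i] <- 0; next }
      a_i <- mean(d[i, same])
      b_i <- min(vapply(setdiff(levels(bt), as.character(bt[i])),
                        function(lv) mean(d[i, bt == lv]), 0))
      s[i] <- if (max(a_i, b_i) > 0) (b_i - a_i) / max(a_i, b_i) else 0
    }
    sil[cells] <- s
    scores[ti] <- 1 - abs(mean(s))
    sizes[ti] <- length(cells)
  }
  ok <- !is.na(scores)
  if (!any(ok)) stop("no cell type with at least 2 batches")
  new_metric_result("asw", "celltype", per_cell = sil,
                    per_group = scores[ok], group_sizes = sizes[ok],
                    direction = 1L)
}

#' Principal-component regression batch score
#'
#' PCA on the log-expression of the `n_hvg` most variable genes; for each of
#' the top `n_pcs_pcr` components, the coefficient of determination R^2 of
#' the batch variable (squared Pearson correlation with a 0/1 indicator for
#' two batches; least-squares projection on the one-hot batch design for
#' more); the score is the PC-variance-weighted mean of the R^2 values --
#' the fraction of the top components' variance attributable to batch.
#'
#' @param ds a [cell_dataset()] with `logexpr`.
#' @param params a [metric_params()]; if fewer than `n_pcs_pcr` components
#'   are available all of them are used and the scaling adapts.
#' @return a `metric_result` with a global score in \[0, 1\], direction -1,
#'   and `pc_var` / `r2_per_pc` components in `$details`.
#' @export
pcr <- function(ds, params = metric_params()) {
  if (is.null(ds$logexpr)) stop("pcr needs logexpr")
  genes <- select_hvg(ds, min(params$n_hvg, n_genes(ds)))
  n_pc <- min(params$n_pcs_pcr, length(genes) - 1L, n_cells(ds) - 1L)
  pca <- compute_pca(ds, n_pcs = n_pc, genes = genes)
  r2 <- pc_batch_r2(pca$embedding, ds$batch)
  score <- sum(pca$var * r2) / sum(pca$var)
  res <- new_metric_result("pcr", "global", global_score = score,
                           direction = -1L, params = params)
  res$details <- list(pc_var = pca$var, r2_per_pc = r2)
  res
}

pc_batch_r2 <- function(scores, batch) {
  batch <- factor(batch)
  if (nlevels(batch) == 2) {
    ind <- as.numeric(batch) - 1
    apply(scores, 2, function(s) {
      if (stats::sd(s) == 0) 0 else stats::cor(s, ind)^2
    })
  } else {
    x <- stats::model.matrix(~batch)
    qx <- qr(x)
    apply(scores, 2, function(s) {
      tss <- sum((s - mean(s))^2)
      if (tss == 0) return(0)
      rss <- sum(qr.resid(qx, s)^2)
      1 - rss / tss
    })
  }
}
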