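#' Container for a single-cell expression dataset
#'
#' Lightweight container holding raw counts (genes x cells), log-normalized
#' expression, per-cell batch and (optionally) cell-type labels, and an
#' optional low-dimensional embedding (cells x D). At least one of `counts`,
#' `logexpr` or `embedding` must be supplied; all components must agree on the
#' number of cells (and, for the matrices, genes).
#'
#' @param counts non-negative integer matrix, genes x cells.
#' @param batch per-cell batch labels (coerced to factor); required.
#' @param celltype optional per-cell cell-type labels (coerced to factor).
#' @param logexpr optional log-normalized expression matrix, genes x cells.
#' @param embedding optional numeric matrix, cells x D.
#' @param gene_ids,cell_ids optional identifier vectors; default to matrix
#'   dimnames or generated ids.
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(counts = NULL, batch, celltype = NULL,
                         logexpr = NULL, embedding = NULL,
                         gene_ids = NULL, cell_ids = NULL) {
  if (is.null(counts) && is.null(logexpr) && is.null(embedding)) {
    stop("at least one of 'counts', 'logexpr' or 'embedding' is required")
  }
  n_cells <- if (!is.null(counts)) ncol(counts)
    else if (!is.null(logexpr)) ncol(logexpr)
    else nrow(embedding)
  if (n_cells < 1) stop("empty matrix: dataset has no cells")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("'counts' must be a non-negative integer matrix")
    }
  }
  batch <- factor(batch)
  if (length(batch) != n_cells) {
    stop("'batch' length (", length(batch), ") does not match cell count (",
         n_cells, ")")
  }
  if (anyNA(batch)) stop("'batch' contains missing labels")
  if (!is.null(celltype)) {
    celltype <- factor(celltype)
    if (length(celltype) != n_cells) {
      stop("'celltype' length does not match cell count")
    }
  }
  n_genes <- if (!is.null(counts)) nrow(counts)
    else if (!is.null(logexpr)) nrow(logexpr) else 0L
  if (!is.null(logexpr)) {
    logexpr <- as.matrix(logexpr)
    if (ncol(logexpr) != n_cells) stop("'logexpr' cell count mismatch")
    if (!is.null(counts) && nrow(logexpr) != nrow(counts)) {
      stop("'counts' and 'logexpr' disagree on gene count")
    }
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != n_cells) stop("'embedding' cell count mismatch")
  }
  gene_ids <- gene_ids %||%
    (if (!is.null(counts)) rownames(counts) else rownames(logexpr)) %||%
    (if (n_genes > 0) sprintf("gene%d", seq_len(n_genes)) else character())
  cell_ids <- cell_ids %||%
    (if (!is.null(counts)) colnames(counts) else NULL) %||%
    sprintf("cell%d", seq_len(n_cells))
  if (n_genes > 0 && length(gene_ids) != n_genes) {
    stop("'gene_ids' length does not match gene count")
  }
  if (length(cell_ids) != n_cells) {
    stop("'cell_ids' length does not match cell count")
  }
  structure(list(counts = counts, logexpr = logexpr, batch = batch,
                 celltype = celltype, embedding = embedding,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids)),
            class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat("cell_dataset:", n_genes(x), "genes x", n_cells(x), "cells\n")
  cat("  batch levels: ", paste(levels(x$batch), collapse = ", "), "\n", sep = "")
  if (!is.null(x$celltype)) {
    cat("  celltype levels: ", paste(levels(x$celltype), collapse = ", "),
        "\n", sep = "")
  }
  cat("  components:",
      paste(c("counts", "logexpr", "embedding")[
        !vapply(x[c("counts", "logexpr", "embedding")], is.null, TRUE)],
        collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param ds a `cell_dataset`.
#' @return integer count.
#' @export
n_cells <- function(ds) length(ds$cell_ids)

#' @rdname n_cells
#' @export
n_genes <- function(ds) {
  if (!is.null(ds$counts)) nrow(ds$counts)
  else if (!is.null(ds$logexpr)) nrow(ds$logexpr)
  else 0L
}

#' Subset a dataset to a set of cells (all components kept in register)
#' @param ds a `cell_dataset`.
#' @param keep integer or logical index of cells to keep.
#' @return a `cell_dataset` with the selected cells.
#' @export
subset_cells <- function(ds, keep) {
  idx <- seq_len(n_cells(ds))[keep]
  if (length(idx) == 0) stop("subset would remove all cells")
  cell_dataset(
    counts = if (!is.null(ds$counts)) ds$counts[, idx, drop = FALSE],
    batch = ds$batch[idx],
    celltype = if (!is.null(ds$celltype)) ds$celltype[idx],
    logexpr = if (!is.null(ds$logexpr)) ds$logexpr[, idx, drop = FALSE],
    embedding = if (!is.null(ds$embedding)) ds$embedding[idx, , drop = FALSE],
    gene_ids = ds$gene_ids, cell_ids = ds$cell_ids[idx])
}

subset_genes <- function(ds, keep) {
  idx <- seq_len(n_genes(ds))[keep]
  if (length(idx) == 0) stop("subset would remove all genes")
  cell_dataset(
    counts = if (!is.null(ds$counts)) ds$counts[idx, , drop = FALSE],
    batch = ds$batch,
    celltype = ds$celltype,
    logexpr = if (!is.null(ds$logexpr)) ds$logexpr[idx, , drop = FALSE],
    embedding = ds$embedding,
    gene_ids = ds$gene_ids[idx], cell_ids = ds$cell_ids)
}

#' Metric parameter set
#'
#' Bundles the tunable parameters shared by the mixing metrics. Defaults
#' follow the benchmark configuration: `k = 200` neighbours for cell-level
#' metrics, `k_min = 80` as the floor of the density-adaptive neighbourhood,
#' `b_min = 80` cells per batch for the batch-extended neighbourhood,
#' `k_mm = 300` and `k_pos = 5` for the mixing metric, the top `n_pcs = 10`
#' principal components for distances, `n_pcs_pcr = 100` components and
#' `n_hvg = 1000` variable genes for principal-component regression,
#' `k_graph = 5` for the connectivity graph and `alpha_kbet = 0.05` as the
#' chi-squared rejection level.
#'
#' @param k,k_min,b_min,k_mm,k_pos,n_pcs,n_pcs_pcr,n_hvg,k_graph integers.
#' @param alpha_kbet significance level for the kBET rejection rate.
#' @param perplexity Gaussian-kernel perplexity used by `lisi`.
#' @return a list of class `metric_params`.
#' @export
metric_params <- function(k = 200L, k_min = 80L, b_min = 80L, k_mm = 300L,
                          k_pos = 5L, n_pcs = 10L, n_pcs_pcr = 100L,
                          n_hvg = 1000L, k_graph = 5L, alpha_kbet = 0.05,
                          perplexity = 30L) {
  p <- list(k = as.integer(k), k_min = as.integer(k_min),
            b_min = as.integer(b_min), k_mm = as.integer(k_mm),
            k_pos = as.integer(k_pos), n_pcs = as.integer(n_pcs),
            n_pcs_pcr = as.integer(n_pcs_pcr), n_hvg = as.integer(n_hvg),
            k_graph = as.integer(k_graph), alpha_kbet = alpha_kbet,
            perplexity = as.integer(perplexity))
  stopifnot(all(unlist(p) > 0), p$k_min <= p$k, p$k_pos <= p$k_mm,
            alpha_kbet < 1)
  class(p) <- "metric_params"
  p
}

new_metric_result <- function(metric, level, per_cell = NULL, per_group = NULL,
                              group_sizes = NULL, global_score = NULL,
                              direction, params = NULL) {
  global_score <- global_score %||% {
    if (level == "cell") mean(per_cell)
    else stats::weighted.mean(per_group, group_sizes)
  }
  structure(list(metric = metric, level = level, per_cell = per_cell,
                 per_group = per_group, group_sizes = group_sizes,
                 global_score = global_score, direction = direction,
                 params = params),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("metric_result '%s' (%s level, direction %+d): global score %.4f\n",
              x$metric, x$level, x$direction, x$global_score))
  invisible(x)
}
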