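#' Quality-control filtering of genes and cells
#'
#' Removes genes detected in fewer than `min_cells_per_gene` cells and cells
#' whose total count, number of detected genes, or mitochondrial fraction
#' deviates more than `nmads` median absolute deviations (either direction)
#' from the respective median. Cell outliers are flagged on the unfiltered
#' gene set, on the raw (not log) scale; the gene filter is then applied to
#' the retained cells. The input is left untouched.
#'
#' @param ds a [cell_dataset()] with counts.
#' @param nmads MAD multiplier for the cell filters; `Inf` disables them.
#' @param min_cells_per_gene minimum number of cells a gene must be detected
#'   in; genes below the threshold are dropped.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @return a filtered copy of `ds`.
#' @export
qc_filter <- function(ds, nmads = 2.5, min_cells_per_gene = 20L,
                      mito_prefix = "MT-") {
  if (is.null(ds$counts)) stop("qc_filter needs counts")
  detected <- ds$counts > 0
  total <- colSums(ds$counts)
  n_feat <- colSums(detected)
  mito <- startsWith(ds$gene_ids, mito_prefix)
  mito_frac <- if (any(mito)) {
    colSums(ds$counts[mito, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, n_cells(ds))
  bad_cell <- mad_outlier(total, nmads) | mad_outlier(n_feat, nmads) |
    mad_outlier(mito_frac, nmads)
  if (all(bad_cell)) {
    stop("qc_filter removed every cell; relax 'nmads' or check the input")
  }
  out <- subset_cells(ds, !bad_cell)
  keep_gene <- rowSums(detected[, !bad_cell, drop = FALSE]) >=
    min_cells_per_gene
  if (!any(keep_gene)) {
    stop("qc_filter removed every gene; relax 'min_cells_per_gene'")
  }
  subset_genes(out, keep_gene)
}

#' Library-size log-normalization
#'
#' Computes cell size factors proportional to library size and scaled to mean
#' one, and sets `logexpr[g, c] = log2(counts[g, c] / sf_c + pseudocount)`.
#'
#' @param ds a [cell_dataset()] with counts.
#' @param pseudocount added inside the log; the default 1 keeps all-zero genes
#'   at exactly zero.
#' @return `ds` with `logexpr` populated.
#' @export
normalize_log <- function(ds, pseudocount = 1) {
  if (is.null(ds$counts)) stop("normalize_log needs counts")
  lib <- colSums(ds$counts)
  if (any(lib == 0)) {
    stop("cell(s) with zero total count: ",
         paste(utils::head(ds$cell_ids[lib == 0], 3), collapse = ", "),
         " (QC-filter first)")
  }
  sf <- lib / mean(lib)
  ds$logexpr <- log2(sweep(ds$counts, 2, sf, "/") + pseudocount)
  ds
}

#' Highly variable genes
#'
#' Ranks genes by variance of log-normalized expression and returns the
#' indices of the top `n`, variance-descending, ties broken by ascending gene
#' index.
#'
#' @param ds a [cell_dataset()] with `logexpr`.
#' @param n number of genes to return.
#' @return integer vector of gene indices, length `n`.
#' @export
select_hvg <- function(ds, n = 1000L) {
  if (is.null(ds$logexpr)) stop("select_hvg needs logexpr (normalize first)")
  if (n > n_genes(ds)) stop("'n' exceeds the gene count")
  v <- row_vars(ds$logexpr)
  order(-v, seq_along(v))[seq_len(n)]
}

#' Principal component analysis of cells
#'
#' PCA of the cells on gene-centred log-expression. The sign of each
#' component is fixed so its largest-magnitude gene loading is positive,
#' making the embedding deterministic across platforms.
#'
#' @param ds a [cell_dataset()] with `logexpr`.
#' @param n_pcs number of components.
#' @param genes optional gene index subset (e.g. from [select_hvg()]).
#' @return list with `embedding` (cells x `n_pcs` scores), `var_explained`
#'   (share of total variance per component) and `var` (component variances).
#' @export
compute_pca <- function(ds, n_pcs = 10L, genes = NULL) {
  if (is.null(ds$logexpr)) stop("compute_pca needs logexpr")
  x <- ds$logexpr
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  x <- t(x)                                # cells x genes
  if (n_pcs > min(dim(x))) {
    stop("n_pcs exceeds min(genes, cells) = ", min(dim(x)))
  }
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs), 2, flip, "*")
  tot <- sum(sv$d^2)
  list(embedding = scores,
       var_explained = sv$d[seq_len(n_pcs)]^2 / tot,
       var = sv$d[seq_len(n_pcs)]^2 / (nrow(x) - 1))
}
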