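#' Load a gene x cell count dataset from disk
#'
#' Reads a MatrixMarket triplet (`matrix.mtx` + `genes.tsv` + `barcodes.tsv`),
#' a dense CSV/TSV (genes x cells, header row of cell ids, first column gene
#' ids), or an H5AD file, together with a per-cell metadata table providing
#' the batch (and optionally cell-type) column.
#'
#' For the MTX route, `source` is the directory containing `matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv` and `metadata.tsv` (or a named list with
#' elements `mtx`, `genes`, `barcodes`, `metadata`). For dense files,
#' `source` is the matrix file path and `metadata` its companion; for H5AD,
#' `source` is the `.h5ad` path and metadata is taken from `obs`
#' (read through a python/anndata subprocess; python with the anndata module
#' must be on the PATH).
#'
#' @param source path (directory, matrix file or .h5ad) or named list of paths.
#' @param batch_col name of the batch column in the cell metadata.
#' @param celltype_col optional name of the cell-type column.
#' @param metadata optional path to a cell metadata TSV (one row per cell,
#'   header) when `source` is a dense matrix file.
#' @return a [cell_dataset()].
#' @export
load_dataset <- function(source, batch_col = "batch", celltype_col = NULL,
                         metadata = NULL) {
  if (is.list(source)) {
    return(load_mtx(source$mtx, source$genes, source$barcodes,
                    source$metadata, batch_col, celltype_col))
  }
  if (dir.exists(source)) {
    return(load_mtx(file.path(source, "matrix.mtx"),
                    file.path(source, "genes.tsv"),
                    file.path(source, "barcodes.tsv"),
                    file.path(source, "metadata.tsv"),
                    batch_col, celltype_col))
  }
  if (grepl("\\.h5ad$", source)) {
    return(load_h5ad(source, batch_col, celltype_col))
  }
  if (grepl("\\.(csv|tsv|txt)$", source)) {
    if (is.null(metadata)) stop("dense input needs a 'metadata' TSV path")
    return(load_dense(source, metadata, batch_col, celltype_col))
  }
  stop("unrecognized input format: ", source)
}

check_meta_cols <- function(meta, batch_col, celltype_col) {
  if (!batch_col %in% colnames(meta)) {
    stop("metadata lacks batch column '", batch_col, "'")
  }
  if (!is.null(celltype_col) && !celltype_col %in% colnames(meta)) {
    stop("metadata lacks celltype column '", celltype_col, "'")
  }
}

load_mtx <- function(mtx, genes, barcodes, metadata, batch_col, celltype_col) {
  m <- as.matrix(Matrix::readMM(mtx))
  gene_ids <- utils::read.delim(genes, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  cell_ids <- utils::read.delim(barcodes, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match gene/barcode files")
  }
  meta <- utils::read.delim(metadata, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(m)) stop("metadata row count does not match cells")
  check_meta_cols(meta, batch_col, celltype_col)
  cell_dataset(counts = m, batch = meta[[batch_col]],
               celltype = if (!is.null(celltype_col)) meta[[celltype_col]],
               gene_ids = gene_ids, cell_ids = cell_ids)
}

load_dense <- function(path, metadata, batch_col, celltype_col) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  meta <- utils::read.delim(metadata, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(m)) stop("metadata row count does not match cells")
  check_meta_cols(meta, batch_col, celltype_col)
  cell_dataset(counts = m, batch = meta[[batch_col]],
               celltype = if (!is.null(celltype_col)) meta[[celltype_col]],
               gene_ids = rownames(m), cell_ids = colnames(m))
}

#' Write a dataset as a MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `metadata.tsv` into
#' `dir`; integer counts round-trip bit-compatibly through [load_dataset()].
#'
#' @param ds a [cell_dataset()] with counts.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(ds, dir) {
  if (is.null(ds$counts)) stop("dataset has no counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(ds$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(ds$gene_ids), file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(ds$cell_ids), file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  meta <- data.frame(cell_id = ds$cell_ids, batch = as.character(ds$batch))
  if (!is.null(ds$celltype)) meta$celltype <- as.character(ds$celltype)
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

python_bin <- function() {
  p <- Sys.which("python")
  if (p == "") p <- Sys.which("python3")
  if (p == "") stop("no python interpreter found for H5AD IO")
  p
}

#' Write a dataset to H5AD (via a python/anndata subprocess)
#'
#' @param ds a [cell_dataset()] with counts.
#' @param path output `.h5ad` path.
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(ds, path) {
  tmp <- tempfile("h5ad_bridge_")
  write_mtx(ds, tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  script <- paste(
    "import sys, anndata, pandas as pd, scipy.io, scipy.sparse, numpy as np",
    "d, out = sys.argv[1], sys.argv[2]",
    "m = scipy.io.mmread(d + '/matrix.mtx').tocsr().T",  # cells x genes
    "genes = pd.read_csv(d + '/genes.tsv', header=None, sep='\\t')[0].astype(str)",
    "meta = pd.read_csv(d + '/metadata.tsv', sep='\\t').set_index('cell_id')",
    "meta.index = meta.index.astype(str)",
    "var = pd.DataFrame(index=pd.Index(genes.values.astype(str), name='gene_id'))",
    "a = anndata.AnnData(X=m, obs=meta, var=var)",
    "a.write_h5ad(out)",
    sep = "\n")
  run_python(script, c(tmp, path))
  invisible(path)
}

load_h5ad <- function(path, batch_col, celltype_col) {
  tmp <- tempfile("h5ad_bridge_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  script <- paste(
    "import sys, anndata, pandas as pd, scipy.io, scipy.sparse, numpy as np",
    "src, d = sys.argv[1], sys.argv[2]",
    "a = anndata.read_h5ad(src)",
    "x = scipy.sparse.csr_matrix(a.X).T",  # genes x cells
    "scipy.io.mmwrite(d + '/matrix.mtx', x)",
    "pd.Series(a.var_names).to_csv(d + '/genes.tsv', sep='\\t', index=False, header=False)",
    "pd.Series(a.obs_names).to_csv(d + '/barcodes.tsv', sep='\\t', index=False, header=False)",
    "meta = a.obs.copy(); meta.insert(0, 'cell_id', a.obs_names)",
    "meta.to_csv(d + '/metadata.tsv', sep='\\t', index=False)",
    sep = "\n")
  run_python(script, c(path, tmp))
  load_mtx(file.path(tmp, "matrix.mtx"), file.path(tmp, "genes.tsv"),
           file.path(tmp, "barcodes.tsv"), file.path(tmp, "metadata.tsv"),
           batch_col, celltype_col)
}

run_python <- function(script, args) {
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  on.exit(unlink(sf))
  out <- suppressWarnings(system2(python_bin(), c(sf, args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    stop("python H5AD bridge failed:\n", paste(out, collapse = "\n"))
  }
  invisible(out)
}
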