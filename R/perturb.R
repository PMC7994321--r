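#' Partially permute batch labels
#'
#' Selects `round(fraction * n)` cells uniformly at random and permutes the
#' batch labels among the selected positions, leaving the remaining labels
#' untouched. The global label multiset is preserved for every fraction, so
#' full permutation (`fraction = 1`) is a negative control with unchanged
#' batch composition.
#'
#' @param batch factor (or vector) of per-cell batch labels.
#' @param fraction fraction of positions to permute, in \[0, 1\].
#' @param seed integer seed.
#' @return permuted label factor of the same length.
#' @export
permute_batch_labels <- function(batch, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  batch <- factor(batch)
  n <- length(batch)
  n_sel <- round(fraction * n)
  if (n_sel < 2) return(batch)
  with_seed(seed, {
    sel <- sample.int(n, n_sel)
    batch[sel] <- batch[sel][sample.int(n_sel)]
  })
  batch
}

#' Down-sample one (cell type, batch) stratum
#'
#' Removes `round(remove_fraction * stratum size)` cells, sampled uniformly
#' at random, from the cells carrying the given cell-type and batch labels.
#' All other cells are untouched. Used by the imbalance benchmark task.
#'
#' @param ds a [cell_dataset()] with celltype labels.
#' @param celltype,batch labels identifying the stratum.
#' @param remove_fraction fraction of the stratum to remove, in \[0, 1\].
#' @param seed integer seed.
#' @return a `cell_dataset` without the removed cells.
#' @export
downsample_batch <- function(ds, celltype, batch, remove_fraction, seed) {
  stopifnot(remove_fraction >= 0, remove_fraction <= 1)
  if (is.null(ds$celltype)) stop("dataset has no celltype labels")
  stratum <- which(ds$celltype == celltype & ds$batch == batch)
  if (length(stratum) == 0) {
    stop("stratum (", celltype, ", ", batch, ") is empty")
  }
  n_rm <- round(remove_fraction * length(stratum))
  if (n_rm == 0) return(ds)
  drop <- with_seed(seed, sample(stratum, n_rm))
  subset_cells(ds, setdiff(seq_len(n_cells(ds)), drop))
}
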