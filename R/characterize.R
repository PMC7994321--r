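#' Per-gene variance partitioning into batch, cell type and interaction
#'
#' For each gene, fits the crossed random-intercept model
#' `y = mu + u_celltype + u_batch + u_interaction + e` to the log-normalized
#' expression by REML (via `lme4::lmer`) and returns the four variance
#' components and their shares of the total (PVE). Genes where the REML fit
#' fails or does not converge fall back to a non-negative method-of-moments
#' estimate and are flagged. Constant genes get all components 0 and a
#' residual PVE share of 1 by convention.
#'
#' @param ds a [cell_dataset()] with `logexpr`, batch and celltype labels
#'   (at least 2 levels each).
#' @return a `variance_partition`: list with `components` and `pve` (genes x
#'   4 matrices: celltype, batch, interaction, residual) and a logical
#'   `mom_fallback` flag per gene.
#' @export
variance_partition <- function(ds) {
  if (is.null(ds$logexpr)) stop("variance_partition needs logexpr")
  if (is.null(ds$celltype)) stop("variance_partition needs celltype labels")
  batch <- factor(ds$batch)
  ct <- factor(ds$celltype)
  if (nlevels(batch) < 2 || nlevels(ct) < 2) {
    stop("need at least 2 batch and 2 celltype levels")
  }
  G <- n_genes(ds)
  comp <- matrix(0, G, 4,
                 dimnames = list(ds$gene_ids,
                                 c("celltype", "batch", "interaction",
                                   "residual")))
  fallback <- logical(G)
  df <- data.frame(ct = ct, b = batch, int = interaction(ct, batch))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  for (g in seq_len(G)) {
    y <- ds$logexpr[g, ]
    if (stats::var(y) == 0) next
    df$y <- y
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ (1 | ct) + (1 | b) + (1 | int), data = df,
                   REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    if (is.null(fit)) {
      comp[g, ] <- mom_varcomp(y, ct, batch)
      fallback[g] <- TRUE
    } else {
      vc <- as.data.frame(lme4::VarCorr(fit))
      get1 <- function(nm) vc$vcov[match(nm, vc$grp)]
      comp[g, ] <- c(get1("ct"), get1("b"), get1("int"), get1("Residual"))
    }
  }
  tot <- rowSums(comp)
  pve <- comp / ifelse(tot > 0, tot, 1)
  pve[tot == 0, ] <- rep(c(0, 0, 0, 1), each = sum(tot == 0))
  structure(list(components = comp, pve = pve, mom_fallback = fallback),
            class = "variance_partition")
}

# non-negative method-of-moments variance components for the crossed design;
# crude but only used when REML fails
mom_varcomp <- function(y, ct, batch) {
  cell <- interaction(ct, batch, drop = TRUE)
  n_cell <- tabulate(cell)
  within <- tapply(y, cell, stats::var)
  s_e <- stats::weighted.mean(within, w = pmax(n_cell - 1, 0), na.rm = TRUE)
  if (!is.finite(s_e)) s_e <- stats::var(y)
  m_tb <- tapply(y, list(ct, batch), mean)
  m_t <- rowMeans(m_tb, na.rm = TRUE)
  m_b <- colMeans(m_tb, na.rm = TRUE)
  mu <- mean(m_tb, na.rm = TRUE)
  inter <- sweep(sweep(m_tb, 1, m_t), 2, m_b) + mu
  nbar <- mean(n_cell)
  s_t <- max(stats::var(m_t) - s_e / nbar, 0)
  s_b <- max(stats::var(m_b) - s_e / nbar, 0)
  s_i <- max(stats::var(as.vector(inter), na.rm = TRUE) - s_e / nbar, 0)
  c(s_t, s_b, s_i, s_e)
}

#' Cell-type-specific batch log fold changes and differential expression
#'
#' Per (gene, cell type, non-reference batch): the log2 fold change of
#' size-factor-normalized mean counts against the reference batch (the first
#' level), shrunk with `pseudocount`; a Welch t-test on log-expression
#' between the two batch groups; and Benjamini-Hochberg adjustment per
#' (cell type, batch pair), flagging genes with adjusted p <= 0.05 as
#' differentially expressed. Summaries: the overall DE proportion, the mean
#' between-cell-type Pearson correlation of logFC vectors, and the mean
#' pairwise Jaccard overlap of DE gene sets between cell types.
#'
#' @param ds a [cell_dataset()] with counts, `logexpr`, batch and celltype.
#' @param pseudocount added to the normalized means inside the ratio;
#'   `pseudocount = 0` gives the unshrunk ratio, with genes lacking a
#'   positive mean in either stratum set to `NA` (used for simulator
#'   fidelity checks).
#' @param alpha adjusted-p threshold for the DE flag.
#' @return a `batch_logfc`: list with `table` (data.frame gene, celltype,
#'   batch, logfc, pval, padj, de) and `summary` (de_prop, lfc_cor,
#'   de_overlap).
#' @export
estimate_batch_logfc <- function(ds, pseudocount = 1, alpha = 0.05) {
  if (is.null(ds$counts)) stop("estimate_batch_logfc needs counts")
  if (is.null(ds$logexpr)) stop("estimate_batch_logfc needs logexpr")
  if (is.null(ds$celltype)) stop("estimate_batch_logfc needs celltype labels")
  batch <- factor(ds$batch)
  ct <- factor(ds$celltype)
  if (nlevels(batch) < 2) stop("need at least 2 batches")
  lib <- colSums(ds$counts)
  lam <- lib / mean(lib)
  norm <- sweep(ds$counts, 2, lam, "/")
  ref <- levels(batch)[1]
  rows <- list()
  for (t in levels(ct)) for (b in levels(batch)[-1]) {
    ref_cells <- which(ct == t & batch == ref)
    b_cells <- which(ct == t & batch == b)
    G <- n_genes(ds)
    if (length(ref_cells) < 2 || length(b_cells) < 2) {
      warning("stratum (", t, ", ", b, " vs ", ref,
              ") has fewer than 2 cells; p set to 1")
      lfc <- rep(NA_real_, G); p <- rep(1, G)
    } else {
      m_ref <- rowMeans(norm[, ref_cells, drop = FALSE])
      m_b <- rowMeans(norm[, b_cells, drop = FALSE])
      lfc <- if (pseudocount > 0) {
        log2((m_b + pseudocount) / (m_ref + pseudocount))
      } else {
        ifelse(m_b > 0 & m_ref > 0, log2(m_b / m_ref), NA_real_)
      }
      p <- welch_rows(ds$logexpr[, b_cells, drop = FALSE],
                      ds$logexpr[, ref_cells, drop = FALSE])
    }
    padj <- stats::p.adjust(p, method = "BH")
    rows[[paste(t, b)]] <- data.frame(
      gene = ds$gene_ids, celltype = t, batch = b, logfc = lfc, pval = p,
      padj = padj, de = padj <= alpha, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(list(table = tab, summary = logfc_summaries(tab)),
            class = "batch_logfc")
}

# vectorized two-sided Welch t-test across matrix rows
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- row_vars(x); vy <- row_vars(y)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  p[!is.finite(tt)] <- 1   # zero-variance, zero-difference rows
  p
}

logfc_summaries <- function(tab) {
  de_prop <- mean(tab$de, na.rm = TRUE)
  pairs_cor <- c(); pairs_ov <- c()
  for (b in unique(tab$batch)) {
    sub <- tab[tab$batch == b, ]
    types <- unique(sub$celltype)
    if (length(types) < 2) next
    lmat <- sapply(types, function(t) sub$logfc[sub$celltype == t])
    dmat <- sapply(types, function(t) sub$de[sub$celltype == t])
    for (i in seq_len(length(types) - 1)) for (j in (i + 1):length(types)) {
      ok <- stats::complete.cases(lmat[, i], lmat[, j])
      if (sum(ok) > 2 && stats::sd(lmat[ok, i]) > 0 &&
          stats::sd(lmat[ok, j]) > 0) {
        pairs_cor <- c(pairs_cor, stats::cor(lmat[ok, i], lmat[ok, j]))
      }
      un <- sum(dmat[, i] | dmat[, j], na.rm = TRUE)
      if (un > 0) {
        pairs_ov <- c(pairs_ov,
                      sum(dmat[, i] & dmat[, j], na.rm = TRUE) / un)
      }
    }
  }
  list(de_prop = de_prop,
       lfc_cor = if (length(pairs_cor)) mean(pairs_cor) else NA_real_,
       de_overlap = if (length(pairs_ov)) mean(pairs_ov) else NA_real_)
}
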