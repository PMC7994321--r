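#' Simulation parameter set for the NB batch-effect simulator
#'
#' Holds per-gene dispersions `phi`, gene x cell-type log baselines `beta0`
#' (natural log of the normalized mean in the reference batch), a gene x
#' cell-type x batch array of batch log2 fold changes `lfc` (reference batch
#' identically 0), per-cell size factors and the cell-type / batch sampling
#' proportions. Counts are drawn as
#' `Y ~ NB(mean = exp(beta0) * lambda_c * 2^(lfc * theta), dispersion phi)`
#' with variance `mu + phi * mu^2`.
#'
#' @param phi per-gene dispersion, positive.
#' @param beta0 genes x cell-types matrix of log baselines.
#' @param lfc genes x cell-types x batches array of log2 fold changes.
#' @param size_factors positive per-cell size factors (a reference pool that
#'   new cells are resampled from).
#' @param celltype_props,batch_props sampling probabilities (sum to 1).
#' @param gene_ids optional gene identifiers.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(phi, beta0, lfc, size_factors, celltype_props,
                       batch_props, gene_ids = NULL) {
  beta0 <- as.matrix(beta0)
  stopifnot(all(phi > 0), all(size_factors > 0),
            length(phi) == nrow(beta0),
            dim(lfc)[1] == nrow(beta0), dim(lfc)[2] == ncol(beta0),
            dim(lfc)[3] == length(batch_props))
  if (any(lfc[, , 1] != 0)) stop("reference-batch lfc must be identically 0")
  stopifnot(abs(sum(celltype_props) - 1) < 1e-8,
            abs(sum(batch_props) - 1) < 1e-8)
  structure(list(phi = phi, beta0 = beta0, lfc = lfc,
                 size_factors = size_factors,
                 celltype_props = celltype_props, batch_props = batch_props,
                 gene_ids = gene_ids %||% sprintf("gene%d", seq_along(phi))),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:", length(x$phi), "genes,", ncol(x$beta0), "cell types,",
      length(x$batch_props), "batches\n")
  invisible(x)
}

#' Estimate simulator parameters from a reference dataset
#'
#' Size factors are library sizes scaled to mean one. Per (gene, cell type)
#' the baseline `beta0` is the natural log of the size-factor-normalized mean
#' count in the reference batch (the first batch level), floored at a small
#' positive constant; batch log2 fold changes are ratios of normalized
#' stratum means shrunk with a pseudocount of one normalized count. The
#' dispersion `phi` is estimated by the method of moments
#' (`var = mu + phi mu^2`) on normalized counts within each
#' (cell type, batch) stratum and combined across strata by a size-weighted
#' mean, floored at 1e-4.
#'
#' @param ref a [cell_dataset()] with counts, batch and celltype labels.
#' @param base_floor floor for the normalized baseline mean.
#' @return a [sim_params()].
#' @export
estimate_params <- function(ref, base_floor = 1e-4) {
  if (is.null(ref$counts)) stop("estimate_params needs counts")
  if (is.null(ref$celltype)) stop("estimate_params needs celltype labels")
  batch <- factor(ref$batch)
  ct <- factor(ref$celltype)
  G <- n_genes(ref)
  lib <- colSums(ref$counts)
  lam <- lib / mean(lib)
  norm <- sweep(ref$counts, 2, lam, "/")
  Tn <- nlevels(ct); Bn <- nlevels(batch)
  means <- array(0, c(G, Tn, Bn))
  sizes <- matrix(0L, Tn, Bn)
  phi_num <- phi_den <- rep(0, G)
  for (t in seq_len(Tn)) for (b in seq_len(Bn)) {
    cells <- which(ct == levels(ct)[t] & batch == levels(batch)[b])
    sizes[t, b] <- length(cells)
    if (length(cells) == 0) next
    m <- rowMeans(norm[, cells, drop = FALSE])
    means[, t, b] <- m
    if (length(cells) >= 2) {
      v <- row_vars(norm[, cells, drop = FALSE])
      est <- ifelse(m > 0, (v - m) / m^2, NA)
      w <- length(cells)
      use <- !is.na(est)
      phi_num[use] <- phi_num[use] + w * est[use]
      phi_den[use] <- phi_den[use] + w
    }
  }
  phi <- pmax(ifelse(phi_den > 0, phi_num / phi_den, 1e-4), 1e-4)
  beta0 <- log(pmax(means[, , 1, drop = TRUE], base_floor))
  beta0 <- matrix(beta0, G, Tn)
  lfc <- array(0, c(G, Tn, Bn))
  for (t in seq_len(Tn)) for (b in seq(2, length.out = Bn - 1)) {
    if (sizes[t, b] == 0 || sizes[t, 1] == 0) {
      warning("empty stratum (", levels(ct)[t], ", ",
              levels(batch)[b], "); lfc left at 0")
      next
    }
    # all-zero gene rows in both strata fall out at exactly lfc = 0
    lfc[, t, b] <- log2((means[, t, b] + 1) / (means[, t, 1] + 1))
  }
  sim_params(phi = phi, beta0 = beta0, lfc = lfc, size_factors = lam,
             celltype_props = as.numeric(table(ct)) / length(ct),
             batch_props = as.numeric(table(batch)) / length(batch),
             gene_ids = ref$gene_ids)
}

#' Draw a synthetic dataset from the NB simulator
#'
#' Assigns every cell a cell type and batch (independent draws from the
#' stored proportions), a size factor resampled from the reference pool, and
#' draws counts gene-wise from
#' `NB(mean = exp(beta0) * lambda_c * 2^(lfc * theta), dispersion phi)`.
#' `theta = 0` gives a batch-free dataset; `theta = 1` reproduces the
#' reference batch strength; larger values amplify it. Fully reproducible
#' from the seed.
#'
#' @param params a [sim_params()].
#' @param theta batch-strength multiplier, `>= 0`.
#' @param n_cells number of cells to draw.
#' @param seed integer seed.
#' @return a [cell_dataset()] with counts and true batch/celltype labels.
#' @export
simulate_counts <- function(params, theta, n_cells, seed) {
  if (n_cells <= 0) stop("n_cells must be positive")
  if (theta < 0) stop("theta must be >= 0")
  assign <- with_seed(seed, sim_assign(params, n_cells))
  sim_draw(params, assign, theta, derive_seed(seed, 1L))
}

sim_assign <- function(params, n_cells) {
  Tn <- ncol(params$beta0); Bn <- length(params$batch_props)
  list(ct = sample.int(Tn, n_cells, replace = TRUE,
                       prob = params$celltype_props),
       b = sample.int(Bn, n_cells, replace = TRUE,
                      prob = params$batch_props),
       lambda = sample(params$size_factors, n_cells, replace = TRUE))
}

sim_draw <- function(params, assign, theta, seed) {
  G <- length(params$phi)
  n <- length(assign$ct)
  mu <- matrix(0, G, n)
  for (t in seq_len(ncol(params$beta0))) {
    for (b in seq_along(params$batch_props)) {
      cols <- which(assign$ct == t & assign$b == b)
      if (length(cols) == 0) next
      base <- exp(params$beta0[, t]) * 2^(params$lfc[, t, b] * theta)
      mu[, cols] <- outer(base, assign$lambda[cols])
    }
  }
  counts <- with_seed(seed, {
    matrix(stats::rnbinom(G * n, mu = as.vector(mu),
                          size = rep(1 / params$phi, times = n)),
           G, n)
  })
  cell_dataset(counts = counts,
               batch = paste0("batch", assign$b),
               celltype = paste0("type", assign$ct),
               gene_ids = params$gene_ids)
}

#' Simulate a batch-strength series
#'
#' One dataset per `theta`, sharing the cell assignments (cell type, batch,
#' size factor) across the series so datasets differ only through the batch
#' strength. The default grid has 13 values spanning \[0, 4\] including 0
#' (batch-free) and 1 (reference strength).
#'
#' @param params a [sim_params()].
#' @param thetas vector of batch-strength multipliers.
#' @param n_cells number of cells per dataset.
#' @param seed integer seed.
#' @return list of [cell_dataset()]s, named by theta.
#' @export
simulate_series <- function(params, thetas = default_theta_grid(),
                            n_cells = 1500L, seed = 1L) {
  stopifnot(length(thetas) > 0, all(thetas >= 0))
  assign <- with_seed(seed, sim_assign(params, n_cells))
  out <- lapply(seq_along(thetas), function(i) {
    sim_draw(params, assign, thetas[i], derive_seed(seed, i + 1L))
  })
  names(out) <- as.character(thetas)
  out
}

#' @rdname simulate_series
#' @export
default_theta_grid <- function() {
  c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 2.5, 3, 3.5, 4)
}

#' Random simulator parameters for a synthetic reference world
#'
#' Builds a [sim_params()] de novo, emulating an HVG-filtered droplet
#' dataset: log-normal baseline expression (median around `mean_count`
#' counts), log-normal gene-wise dispersions around 0.4, moderate cell-type
#' structure on all genes, and cell-type-specific batch log2 fold changes on
#' a `prob_de` fraction of genes (a shared gene-level effect of sd `lfc_sd`
#' plus a cell-type-specific component of sd `ct_lfc_sd`).
#'
#' @param n_genes,n_celltypes,n_batches dimensions of the world.
#' @param prob_de fraction of genes carrying a batch effect.
#' @param lfc_sd sd of the shared batch log2 fold change.
#' @param ct_lfc_sd sd of its cell-type-specific component.
#' @param mean_count median baseline expression in counts.
#' @param seed integer seed.
#' @return a [sim_params()].
#' @export
random_sim_params <- function(n_genes = 400L, n_celltypes = 3L,
                              n_batches = 2L, prob_de = 0.3, lfc_sd = 1,
                              ct_lfc_sd = 0.5, mean_count = 4, seed = 1L) {
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = log(mean_count), sdlog = 1)
    ctfx <- matrix(stats::rnorm(n_genes * n_celltypes, sd = 0.5),
                   n_genes, n_celltypes)
    beta0 <- log(base) + ctfx
    phi <- pmin(pmax(stats::rlnorm(n_genes, log(0.4), 0.5), 0.05), 3)
    lfc <- array(0, c(n_genes, n_celltypes, n_batches))
    de <- stats::runif(n_genes) < prob_de
    for (b in seq(2, length.out = n_batches - 1)) {
      shared <- stats::rnorm(n_genes, sd = lfc_sd)
      for (t in seq_len(n_celltypes)) {
        lfc[de, t, b] <- shared[de] + stats::rnorm(sum(de), sd = ct_lfc_sd)
      }
    }
    sf <- stats::rlnorm(2000, 0, 0.3)
    sim_params(phi = phi, beta0 = beta0, lfc = lfc,
               size_factors = sf / mean(sf),
               celltype_props = rep(1 / n_celltypes, n_celltypes),
               batch_props = rep(1 / n_batches, n_batches))
  })
}
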