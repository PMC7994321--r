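#' Metric direction registry
#'
#' +1 means larger scores indicate better batch mixing (cms, isi/wisi/lisi,
#' entropy, graph, asw); -1 means larger scores indicate a stronger batch
#' effect (mm, kbet rejection rate, pcr).
#'
#' @return named integer vector of directions.
#' @export
metric_directions <- function() {
  c(cms = 1L, cms_kmin = 1L, cms_bmin = 1L, isi = 1L, wisi = 1L, lisi = 1L,
    entropy = 1L, mm = -1L, kbet = -1L, graph = 1L, asw = 1L, pcr = -1L)
}

#' Aggregate a metric result to a single global score
#'
#' Cell-level results are averaged over cells; cell-type-level results are
#' averaged with cell-count weights; global results pass through.
#'
#' @param result a `metric_result`.
#' @return a single number.
#' @export
aggregate_scores <- function(result) {
  switch(result$level,
         cell = {
           s <- result$per_cell[!is.na(result$per_cell)]
           if (length(s) == 0) stop("empty score vector")
           mean(s)
         },
         celltype = {
           if (length(result$per_group) == 0) stop("empty score vector")
           stats::weighted.mean(result$per_group, result$group_sizes)
         },
         global = result$global_score)
}

#' Standardize a score series
#'
#' `minmax` maps to \[0, 1\] by subtracting the minimum and dividing by the
#' range; `zscore` centres by the mean and scales by the sd. The result is
#' then multiplied by `-direction` so that the standardized series increases
#' with batch strength for every metric. A constant series returns zeros
#' with a warning.
#'
#' @param scores numeric series (one value per perturbation factor).
#' @param mode `"minmax"` or `"zscore"`.
#' @param direction +1 or -1 (see [metric_directions()]).
#' @return standardized numeric series.
#' @export
standardize_scores <- function(scores, mode = c("minmax", "zscore"),
                               direction = 1L) {
  mode <- match.arg(mode)
  rng <- range(scores)
  if (diff(rng) == 0) {
    warning("constant score series; returning zeros")
    return(rep(0, length(scores)))
  }
  out <- switch(mode,
                minmax = (scores - rng[1]) / diff(rng),
                zscore = (scores - mean(scores)) / stats::sd(scores))
  out * (-direction)
}

#' Spearman rank correlation with midranks
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return rho in \[-1, 1\]; `NA` with a warning when either vector is
#'   constant (undefined ranks).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Batch-strength detection limit
#'
#' The smallest theta at which the score departs from the batch-free score
#' by more than `frac` of the series' overall range. Returns the largest
#' theta with attribute `reached = FALSE` when the threshold is never
#' exceeded (or the series is constant).
#'
#' @param scores aggregated scores, one per theta.
#' @param thetas increasing factors; the first must be 0 (batch-free).
#' @param frac threshold fraction of the score range (default 0.10).
#' @return the limiting theta, with attribute `reached`.
#' @export
detection_limit <- function(scores, thetas, frac = 0.10) {
  stopifnot(length(scores) == length(thetas), thetas[1] == 0,
            !is.unsorted(thetas, strictly = TRUE))
  rng <- diff(range(scores))
  hit <- which(abs(scores - scores[1]) > frac * rng)
  if (rng == 0 || length(hit) == 0) {
    return(structure(max(thetas), reached = FALSE))
  }
  structure(thetas[min(hit)], reached = TRUE)
}

#' Batch-imbalance limit
#'
#' The smallest removed fraction at which the score departs from the
#' balanced score by more than `frac` of the series' range; 1 (with
#' attribute `reached = FALSE`) when the score stays stable until all cells
#' of the stratum are removed.
#'
#' @param scores aggregated scores, one per removed fraction.
#' @param fractions increasing removed fractions; the first must be 0.
#' @param frac threshold fraction of the score range (default 0.05).
#' @param score_range width of the score range the threshold refers to;
#'   defaults to the observed series range. [run_imbalance_task()] passes
#'   each metric's nominal range (e.g. 1 for unit-interval scores) so that a
#'   stable metric whose series is pure noise is not flagged as diverging.
#' @return the limiting fraction, with attribute `reached`.
#' @export
imbalance_limit <- function(scores, fractions, frac = 0.05,
                            score_range = NULL) {
  stopifnot(length(scores) == length(fractions), fractions[1] == 0,
            !is.unsorted(fractions, strictly = TRUE))
  rng <- score_range %||% diff(range(scores))
  hit <- which(abs(scores - scores[1]) > frac * rng)
  if (rng == 0 || length(hit) == 0) {
    return(structure(max(fractions), reached = FALSE))
  }
  structure(fractions[min(hit)], reached = TRUE)
}

# nominal width of a metric's score range, used to anchor the imbalance
# threshold; unit-interval scores have width 1
metric_nominal_range <- function(metric, n_batches, params) {
  switch(metric,
         isi = , wisi = , lisi = n_batches - 1,
         mm = params$k_mm - params$k_pos,
         1)
}

# ---- metric dispatch over a cached per-dataset context --------------------

# precompute the expensive label-independent pieces (embedding, kNN graphs,
# PC scores) once per dataset so perturbation series only redo cheap parts
metric_context <- function(ds, metrics, params = metric_params()) {
  needs_graph <- any(metrics %in% c("cms", "cms_kmin", "isi", "wisi", "lisi",
                                    "entropy"))
  needs_mm <- "mm" %in% metrics
  needs_emb <- needs_graph || needs_mm ||
    any(metrics %in% c("cms_bmin", "kbet", "graph", "asw"))
  ctx <- list(ds = ds, params = params)
  if (needs_emb) {
    ctx$embedding <- ds$embedding %||%
      compute_pca(ds, n_pcs = params$n_pcs)$embedding
  }
  if (needs_graph) ctx$graph <- knn_search(ctx$embedding, params$k)
  if (needs_mm) ctx$graph_mm <- knn_search(ctx$embedding, params$k_mm)
  if ("pcr" %in% metrics) {
    genes <- select_hvg(ds, min(params$n_hvg, n_genes(ds)))
    n_pc <- min(params$n_pcs_pcr, length(genes) - 1L, n_cells(ds) - 1L)
    ctx$pcr_pca <- compute_pca(ds, n_pcs = n_pc, genes = genes)
  }
  ctx
}

compute_metric <- function(name, ctx, batch, seed = 1L) {
  params <- ctx$params
  ds <- ctx$ds
  switch(name,
    cms = cms(ctx$graph, batch, "default", params),
    cms_kmin = cms(ctx$graph, batch, "kmin", params),
    cms_bmin = cms(NULL, batch, "bmin", params, embedding = ctx$embedding),
    isi = simpson_index(ctx$graph, batch, "none", params),
    wisi = simpson_index(ctx$graph, batch, "inverse_square", params),
    lisi = simpson_index(ctx$graph, batch, "gaussian", params),
    entropy = entropy(ctx$graph, batch, params),
    mm = mixing_metric(ctx$graph_mm, batch, params),
    kbet = kbet(ctx$embedding, batch, ds$celltype, params, seed = seed),
    graph = graph_connectivity(ctx$embedding, ds$celltype, params),
    asw = asw_batch(ctx$embedding, batch, ds$celltype),
    pcr = {
      r2 <- pc_batch_r2(ctx$pcr_pca$embedding, batch)
      new_metric_result("pcr", "global",
                        global_score = sum(ctx$pcr_pca$var * r2) /
                          sum(ctx$pcr_pca$var),
                        direction = -1L, params = params)
    },
    stop("unknown metric: ", name))
}

new_benchmark_series <- function(task, factor_values, scores, rho, limits,
                                 limit_frac = NULL) {
  structure(list(task = task, factor_values = factor_values, scores = scores,
                 rho = rho, limits = limits, limit_frac = limit_frac),
            class = "benchmark_series")
}

#' @export
print.benchmark_series <- function(x, ...) {
  cat("benchmark_series (", x$task, " task): ",
      length(x$factor_values), " factors x ",
      ncol(x$scores), " metrics\n", sep = "")
  print(round(x$scores, 4))
  cat("abs Spearman rho vs factor:\n")
  print(round(x$rho, 3))
  if (!is.null(x$limits)) { cat("limits:\n"); print(unlist(x$limits)) }
  invisible(x)
}

#' Benchmark task: scaling with batch label permutation
#'
#' Permutes an increasing fraction of the batch labels (expression,
#' embedding and cell types fixed), recomputes each metric's aggregated
#' score per fraction and reports the absolute Spearman correlation of the
#' score with the permuted fraction. Randomly permuted labels are a negative
#' control: every label-dependent metric should decay towards its null value
#' as the fraction grows.
#'
#' @param ds a [cell_dataset()] (embedding or logexpr present).
#' @param metrics metric names (see [metric_directions()]).
#' @param fractions permuted fractions; default 0..1 in steps of 0.1.
#' @param seed integer seed.
#' @param params a [metric_params()].
#' @return a `benchmark_series` with the per-fraction score matrix and
#'   per-metric absolute Spearman rho.
#' @export
run_permutation_task <- function(ds, metrics, fractions = seq(0, 1, 0.1),
                                 seed = 1L, params = metric_params()) {
  if (nlevels(factor(ds$batch)) < 2) stop("need at least 2 batches")
  ctx <- metric_context(ds, metrics, params)
  scores <- matrix(NA_real_, length(fractions), length(metrics),
                   dimnames = list(as.character(fractions), metrics))
  for (i in seq_along(fractions)) {
    lab <- permute_batch_labels(ds$batch, fractions[i], derive_seed(seed, i))
    for (m in metrics) {
      scores[i, m] <- aggregate_scores(
        compute_metric(m, ctx, lab, seed = derive_seed(seed, i)))
    }
  }
  rho <- vapply(metrics, function(m) {
    r <- tryCatch(suppressWarnings(spearman_rho(fractions, scores[, m])),
                  error = function(e) NA_real_)
    abs(r)
  }, 0)
  new_benchmark_series("permutation", fractions, scores, rho, limits = NULL)
}

#' Benchmark task: scaling with batch strength and detection limits
#'
#' Simulates a series of datasets over a theta grid (shared cell
#' assignments, increasing batch logFC multiplier), scores every dataset
#' with every metric, and reports per metric the absolute Spearman
#' correlation with theta and the batch detection limit (smallest theta
#' whose score departs from the batch-free score by more than `limit_frac`
#' of the score range).
#'
#' @param sim a [sim_params()].
#' @param metrics metric names.
#' @param thetas theta grid including 0.
#' @param n_cells cells per simulated dataset.
#' @param seed integer seed.
#' @param params a [metric_params()].
#' @param limit_frac detection-limit threshold fraction (default 0.10).
#' @return a `benchmark_series` with scores, rho and detection limits.
#' @export
run_scaling_task <- function(sim, metrics, thetas = default_theta_grid(),
                             n_cells = 1500L, seed = 1L,
                             params = metric_params(), limit_frac = 0.10) {
  stopifnot(thetas[1] == 0)
  series <- simulate_series(sim, thetas, n_cells, seed)
  scores <- matrix(NA_real_, length(thetas), length(metrics),
                   dimnames = list(as.character(thetas), metrics))
  for (i in seq_along(series)) {
    dsi <- normalize_log(series[[i]])
    ctx <- metric_context(dsi, metrics, params)
    for (m in metrics) {
      scores[i, m] <- aggregate_scores(
        compute_metric(m, ctx, dsi$batch, seed = derive_seed(seed, i)))
    }
  }
  rho <- vapply(metrics, function(m) {
    abs(tryCatch(suppressWarnings(spearman_rho(thetas, scores[, m])),
                 error = function(e) NA_real_))
  }, 0)
  limits <- lapply(stats::setNames(metrics, metrics), function(m) {
    detection_limit(scores[, m], thetas, limit_frac)
  })
  new_benchmark_series("scaling", thetas, scores, rho, limits, limit_frac)
}

#' Benchmark task: stability under batch imbalance
#'
#' Removes an increasing fraction of cells from one (cell type, batch)
#' stratum, rescoring the dataset at every fraction, and reports per metric
#' the imbalance limit (smallest removed fraction whose score departs from
#' the balanced score by more than `limit_frac` of the score range). Scores
#' are also returned centred by the balanced score and scaled by the range.
#'
#' @param ds a [cell_dataset()] with celltype labels.
#' @param metrics metric names.
#' @param celltype,batch the down-sampled stratum.
#' @param fractions removed fractions including 0 and 1.
#' @param seed integer seed.
#' @param params a [metric_params()].
#' @param limit_frac imbalance-limit threshold fraction (default 0.05).
#' @return a `benchmark_series` with scores, centred scores (`$centred`)
#'   and imbalance limits.
#' @export
run_imbalance_task <- function(ds, metrics, celltype, batch,
                               fractions = seq(0, 1, 0.1), seed = 1L,
                               params = metric_params(), limit_frac = 0.05) {
  stopifnot(fractions[1] == 0)
  scores <- matrix(NA_real_, length(fractions), length(metrics),
                   dimnames = list(as.character(fractions), metrics))
  for (i in seq_along(fractions)) {
    dsi <- downsample_batch(ds, celltype, batch, fractions[i],
                            derive_seed(seed, i))
    ctx <- metric_context(dsi, metrics, params)
    for (m in metrics) {
      scores[i, m] <- aggregate_scores(
        compute_metric(m, ctx, dsi$batch, seed = derive_seed(seed, i)))
    }
  }
  B <- nlevels(factor(ds$batch))
  limits <- lapply(stats::setNames(metrics, metrics), function(m) {
    imbalance_limit(scores[, m], fractions, limit_frac,
                    score_range = metric_nominal_range(m, B, params))
  })
  out <- new_benchmark_series("imbalance", fractions, scores, rho = NULL,
                              limits, limit_frac)
  rngs <- apply(scores, 2, function(s) diff(range(s)))
  out$centred <- sweep(sweep(scores, 2, scores[1, ]), 2,
                       ifelse(rngs > 0, rngs, 1), "/")
  out
}

#' Categorize per-task metric statistics
#'
#' Applies the benchmark's published thresholds: correlation-based tasks
#' (`"random"` for label permutation, `"characteristics"` for batch-strength
#' surrogates) are good at rho >= 0.75 and intermediate at >= 0.5; the
#' synthetic `"scaling"` correlation is good at >= 0.9 / intermediate at
#' >= 0.8; `"detection_limit"` good at <= 0.6 / intermediate <= 0.7;
#' `"imbalance_limit"` good at >= 0.9 / intermediate >= 0.75. Missing values
#' categorize as NA (encoded 0).
#'
#' @param value statistic value(s).
#' @param task one of `"random"`, `"characteristics"`, `"scaling"`,
#'   `"detection_limit"`, `"imbalance_limit"`.
#' @return factor with levels poor/intermediate/good and attribute
#'   `encoding` (good = 2, intermediate = 1, poor/NA = 0).
#' @export
categorize <- function(value, task = c("random", "characteristics",
                                       "scaling", "detection_limit",
                                       "imbalance_limit")) {
  task <- match.arg(task)
  cat1 <- function(v) {
    if (is.na(v)) return(NA_character_)
    switch(task,
      random = ,
      characteristics = if (v >= 0.75) "good" else if (v >= 0.5)
        "intermediate" else "poor",
      scaling = if (v >= 0.9) "good" else if (v >= 0.8)
        "intermediate" else "poor",
      detection_limit = if (v <= 0.6) "good" else if (v <= 0.7)
        "intermediate" else "poor",
      imbalance_limit = if (v >= 0.9) "good" else if (v >= 0.75)
        "intermediate" else "poor")
  }
  out <- factor(vapply(as.numeric(value), cat1, ""),
                levels = c("poor", "intermediate", "good"))
  enc <- c(poor = 0L, intermediate = 1L, good = 2L)[as.character(out)]
  enc[is.na(enc)] <- 0L
  attr(out, "encoding") <- unname(enc)
  out
}
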