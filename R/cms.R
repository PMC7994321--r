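#' Cell-specific mixing score (cms)
#'
#' For every cell, the distances to its k nearest neighbours are partitioned
#' by the neighbours' batch and a k-sample Anderson-Darling test is applied
#' to the batch-wise distance distributions; the score is the test's
#' asymptotic p-value. High scores (flat distance distributions across
#' batches) indicate a well-mixed neighbourhood; an enrichment of low scores
#' indicates batch bias. Batches contributing fewer than two neighbours are
#' dropped from the test; a neighbourhood reduced to fewer than two batches
#' scores 0 (maximal evidence of batch bias).
#'
#' Variants: `"default"` uses the fixed k-neighbourhood; `"kmin"` truncates
#' each neighbourhood at the first local minimum of its smoothed distance
#' density (floored at `params$k_min`, see [find_kmin()]); `"bmin"` expands
#' the neighbourhood until every batch contributes at least `params$b_min`
#' cells (see [extend_bmin()]).
#'
#' @param graph a `neighbor_graph` built with `k = params$k` on the embedding
#'   (ignored by the `"bmin"` variant).
#' @param batch per-cell batch labels (at least 2 levels).
#' @param variant `"default"`, `"kmin"` or `"bmin"`.
#' @param params a [metric_params()].
#' @param embedding cells x D matrix; required for the `"bmin"` variant.
#' @return a `metric_result` with per-cell scores in \[0, 1\], direction +1.
#' @export
cms <- function(graph, batch, variant = c("default", "kmin", "bmin"),
                params = metric_params(), embedding = NULL) {
  variant <- match.arg(variant)
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("cms needs at least 2 batches")
  n <- length(batch)
  if (variant == "bmin") {
    if (is.null(embedding)) stop("variant 'bmin' needs the embedding")
    small <- table(batch) < params$b_min
    if (any(small)) {
      stop("batch '", names(which(small))[1], "' has fewer than b_min = ",
           params$b_min, " cells")
    }
  } else {
    if (is.null(graph)) stop("cms needs a neighbor_graph")
    if (nrow(graph$indices) != n) stop("graph does not match label length")
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (variant == "bmin") {
      nb <- extend_bmin(embedding, batch, i, params$b_min)
      d <- nb$distances
      b <- batch[nb$indices]
    } else {
      d <- graph$distances[i, ]
      b <- batch[graph$indices[i, ]]
      if (variant == "kmin") {
        keff <- find_kmin(d, params$k_min)
        d <- d[seq_len(keff)]
        b <- b[seq_len(keff)]
      }
    }
    scores[i] <- cms_score_one(d, b)
  }
  new_metric_result(paste0("cms", switch(variant, default = "",
                                         kmin = "_kmin", bmin = "_bmin")),
                    "cell", per_cell = scores, direction = 1L,
                    params = params)
}

cms_score_one <- function(d, b) {
  groups <- split(d, droplevels(b))
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2) return(0)
  ad_ksample(groups)$pvalue
}

#' Density-adaptive neighbourhood size
#'
#' Smooths the neighbour-distance profile with a Gaussian kernel density
#' (Silverman bandwidth, 512-point grid over \[0, max distance\]) and returns
#' the number of neighbours closer than the first local minimum after the
#' global mode, floored at `k_min` and capped at the neighbourhood size. When
#' the smoothed density has no interior minimum (a unimodal profile), the
#' full neighbourhood is kept.
#'
#' @param dist ascending neighbour distances.
#' @param k_min lower bound on the returned size.
#' @return effective neighbourhood size, in `[min(k_min, k), k]`.
#' @export
find_kmin <- function(dist, k_min) {
  k <- length(dist)
  dens <- tryCatch(
    stats::density(dist, bw = "nrd0", n = 512, from = 0, to = max(dist)),
    error = function(e) NULL)
  if (is.null(dens)) return(k)
  y <- dens$y
  mode_i <- which.max(y)
  if (mode_i >= length(y) - 1) return(k)
  after <- (mode_i + 1):length(y)
  turn <- after[which(diff(y[(mode_i):length(y)]) > 0)]  # rising again
  if (length(turn) == 0) return(k)
  valley <- turn[1] - 1
  keff <- sum(dist < dens$x[valley])
  min(max(keff, min(k_min, k)), k)
}

#' Batch-extended neighbourhood
#'
#' Walks the distance-ordered neighbour list of a cell outward until every
#' batch contributes at least `b_min` cells, and returns that neighbourhood.
#'
#' @param embedding cells x D matrix.
#' @param batch per-cell batch labels.
#' @param cell index of the anchor cell.
#' @param b_min minimum number of cells required per batch.
#' @return list with `indices` and `distances` of the expanded neighbourhood.
#' @export
extend_bmin <- function(embedding, batch, cell, b_min) {
  batch <- factor(batch)
  counts <- table(batch[-cell])
  short <- counts < b_min
  if (any(short)) {
    stop("batch '", names(which(short))[1], "' has fewer than b_min = ",
         b_min, " cells")
  }
  nb <- all_neighbors(embedding, cell)
  b <- batch[nb$indices]
  # prefix length = max over batches of the position of the b_min-th member
  cutoff <- max(vapply(levels(batch), function(lv) {
    which(b == lv)[b_min]
  }, 0))
  list(indices = nb$indices[seq_len(cutoff)],
       distances = nb$distances[seq_len(cutoff)])
}
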