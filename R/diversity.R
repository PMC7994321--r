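#' Inverse Simpson index of neighbourhood batch diversity
#'
#' For every cell, per-batch probabilities `p(b)` are the (weighted) shares
#' of its neighbours belonging to each batch, and the score is
#' `1 / sum_b p(b)^2` -- the effective number of batches present in the
#' neighbourhood, between 1 (one batch) and the number of batches (uniform).
#'
#' Weighting schemes: `"none"` (isi) uses uniform weights over the k
#' neighbours; `"inverse_square"` (wisi) weights neighbours by
#' `1 / (d^2 + eps)` with `eps = .Machine$double.eps * median(d)^2` so that
#' duplicated points dominate without dividing by zero; `"gaussian"` (lisi)
#' restricts to the nearest `3 * perplexity` neighbours and calibrates a
#' per-cell Gaussian kernel bandwidth by bisection so the Shannon entropy of
#' the weights equals `log(perplexity)`.
#'
#' @param graph a `neighbor_graph` with `k = params$k`.
#' @param batch per-cell batch labels.
#' @param weighting `"none"`, `"inverse_square"` or `"gaussian"`.
#' @param params a [metric_params()].
#' @return a `metric_result` with per-cell scores in
#'   \[1, number of batches\], direction +1. A single-batch dataset scores
#'   exactly 1 everywhere (documented, not an error).
#' @export
simpson_index <- function(graph, batch,
                          weighting = c("none", "inverse_square", "gaussian"),
                          params = metric_params()) {
  weighting <- match.arg(weighting)
  batch <- factor(batch)
  n <- length(batch)
  if (nrow(graph$indices) != n) stop("graph does not match label length")
  metric <- switch(weighting, none = "isi", inverse_square = "wisi",
                   gaussian = "lisi")
  idx <- graph$indices
  dst <- graph$distances
  if (weighting == "gaussian") {
    m <- min(3L * params$perplexity, ncol(idx))
    idx <- idx[, seq_len(m), drop = FALSE]
    dst <- dst[, seq_len(m), drop = FALSE]
    w <- gaussian_weights(dst, params$perplexity)
  } else if (weighting == "inverse_square") {
    med2 <- apply(dst, 1, stats::median)^2
    eps <- pmax(.Machine$double.eps * med2, .Machine$double.eps)
    w <- 1 / (dst^2 + eps)
    w <- w / rowSums(w)
  } else {
    w <- matrix(1 / ncol(idx), n, ncol(idx))
  }
  bmat <- matrix(as.integer(batch)[idx], n, ncol(idx))
  p2 <- numeric(n)
  for (lv in seq_len(nlevels(batch))) {
    p2 <- p2 + rowSums(w * (bmat == lv))^2
  }
  new_metric_result(metric, "cell", per_cell = 1 / p2, direction = 1L,
                    params = params)
}

# per-row Gaussian kernel weights with entropy calibrated to log(perplexity)
# by vectorized bisection on the precision beta (w ~ exp(-beta d^2))
gaussian_weights <- function(dst, perplexity) {
  d2 <- dst^2
  n <- nrow(d2)
  target <- log(perplexity)
  beta <- rep(1, n)
  lo <- rep(0, n)
  hi <- rep(Inf, n)
  for (iter in seq_len(64L)) {
    w <- exp(-d2 * beta)
    sw <- rowSums(w)
    sw[sw == 0] <- .Machine$double.xmin
    # H = log(sum w) + beta * sum(w d2)/sum(w)
    H <- log(sw) + beta * rowSums(w * d2) / sw
    too_high <- H > target     # too diffuse -> increase beta
    lo[too_high] <- beta[too_high]
    hi[!too_high] <- beta[!too_high]
    beta <- ifelse(is.infinite(hi), beta * 2, (lo + hi) / 2)
  }
  w <- exp(-d2 * beta)
  sw <- rowSums(w)
  flat <- sw < .Machine$double.eps | !is.finite(sw)
  w[flat, ] <- 1
  w / rowSums(w)
}

#' Neighbourhood Shannon entropy of the batch variable
#'
#' Per cell, `p(b)` is the fraction of its k nearest neighbours in batch `b`
#' and the score is the Shannon entropy `-sum p log2 p`, normalized so a
#' neighbourhood with the dataset's batches in equal shares scores exactly 1.
#' The default normalization divides by `log2(B)` (B = number of batch
#' levels), which honours the documented \[0, 1\] range; `"batch_count"`
#' divides by `B` instead (the printed-formula variant, whose maximum is
#' below 1 for more than two batches).
#'
#' @param graph a `neighbor_graph` with `k = params$k`.
#' @param batch per-cell batch labels.
#' @param params a [metric_params()].
#' @param normalization `"log_batches"` (default) or `"batch_count"`.
#' @return a `metric_result` with per-cell scores in \[0, 1\], direction +1.
#'   A single-batch dataset scores 0 everywhere.
#' @export
entropy <- function(graph, batch, params = metric_params(),
                    normalization = c("log_batches", "batch_count")) {
  normalization <- match.arg(normalization)
  batch <- factor(batch)
  n <- length(batch)
  if (nrow(graph$indices) != n) stop("graph does not match label length")
  B <- nlevels(batch)
  if (B < 2) {
    return(new_metric_result("entropy", "cell", per_cell = numeric(n),
                             direction = 1L, params = params))
  }
  k <- ncol(graph$indices)
  bmat <- matrix(as.integer(batch)[graph$indices], n, k)
  h <- numeric(n)
  for (lv in seq_len(B)) {
    p <- rowSums(bmat == lv) / k
    h <- h - ifelse(p > 0, p * log2(p), 0)
  }
  norm <- if (normalization == "log_batches") log2(B) else B
  new_metric_result("entropy", "cell", per_cell = h / norm, direction = 1L,
                    params = params)
}

#' Mixing metric (median batch-representation rank)
#'
#' Per cell, for every batch, the 1-based rank within the distance-ordered
#' neighbour list at which that batch's `k_pos`-th representative appears
#' (or `k_mm` when the batch contributes fewer than `k_pos` neighbours);
#' the score is the median of these ranks across batches. Low scores mean
#' well-interleaved batches; with `k_pos = 5` the best case is 10 for three
#' batches and 15 for five.
#'
#' @param graph a `neighbor_graph` built with `k = params$k_mm`.
#' @param batch per-cell batch labels.
#' @param params a [metric_params()].
#' @return a `metric_result` with per-cell scores in
#'   \[`k_pos`, `k_mm`\], direction -1 (low = mixed).
#' @export
mixing_metric <- function(graph, batch, params = metric_params()) {
  batch <- factor(batch)
  n <- length(batch)
  if (nrow(graph$indices) != n) stop("graph does not match label length")
  k_mm <- ncol(graph$indices)
  k_pos <- params$k_pos
  bmat <- matrix(as.integer(batch)[graph$indices], n, k_mm)
  ranks <- matrix(k_mm, n, nlevels(batch))
  for (lv in seq_len(nlevels(batch))) {
    cum <- t(apply(bmat == lv, 1, cumsum))
    hit <- cum >= k_pos
    has <- rowSums(hit) > 0
    ranks[has, lv] <- max.col(hit[has, , drop = FALSE], ties.method = "first")
  }
  scores <- apply(ranks, 1, stats::median)
  new_metric_result("mm", "cell", per_cell = scores, direction = -1L,
                    params = params)
}
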