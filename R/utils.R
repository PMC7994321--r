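# internal helpers shared across modules

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code has no RNG side effects
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# derive a child seed from (seed, i), kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1003L + as.numeric(i) * 7919) %% 2147483587)
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(0, nrow(x)))
  m <- rowMeans(x)
  (rowSums(x^2) - n * m^2) / (n - 1)
}

# mean absolute deviation outlier flag; infinite nmads disables the filter
mad_outlier <- function(x, nmads) {
  if (is.infinite(nmads)) return(rep(FALSE, length(x)))
  med <- stats::median(x)
  dev <- stats::mad(x)
  abs(x - med) > nmads * dev
}

`%||%` <- function(a, b) if (is.null(a)) b else a
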