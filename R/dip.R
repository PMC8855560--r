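#' Hartigan dip statistic for unimodality
#'
#' The dip is the smallest sup-norm distance between the empirical CDF and
#' any unimodal CDF (a CDF that is convex left of its mode and concave right
#' of it, possibly with an atom at the mode). It is at most 0.25 (attained
#' in the limit by two equal point masses), at least `1/(2n)` for samples
#' with distinct values, and invariant under affine transforms of the data.
#' Large values indicate multimodality.
#'
#' The computation scans all candidate mode positions (between two adjacent
#' distinct values, or at a value with an atom). For each mode and tolerance
#' `e`, a convex fit exists left of the mode iff the greatest convex
#' minorant of the ECDF's upper band stays above the lower band
#' (symmetrically via the least concave majorant on the right), and the two
#' sides join monotonically iff the chord-forced minimal end value of the
#' convex part does not exceed the chord-forced maximal start value of the
#' concave part. The dip is found by bisection on `e` (compiled code;
#' absolute accuracy far below 1e-12).
#'
#' @param x Numeric vector, length at least 4.
#' @return The dip statistic `D`.
#' @export
dip_statistic <- function(x) {
  n <- length(x)
  if (n < 4L) stop("dip statistic requires at least 4 observations")
  if (!all(is.finite(x))) stop("non-finite values")
  x <- sort(x)
  r <- rle(x)
  v <- r$values
  if (length(v) == 1L) return(0)  # point mass: matched by a degenerate CDF
  b <- cumsum(r$lengths)
  a <- b - r$lengths + 1L
  .dip_cpp(v, (a - 1) / n, b / n)
}

# memoized Monte-Carlo null dips (uniform samples of size n)
.dip_cache <- new.env(parent = emptyenv())

#' Null distribution of the dip statistic under a uniform sample
#'
#' Draws `B` seeded iid uniform(0,1) samples of size `n` and returns their
#' dip statistics. Results are memoized per `(n, B, seed)` within a session
#' so that screening many genes at the same sample size costs one table.
#'
#' @param n Sample size.
#' @param B Number of Monte-Carlo replicates (at least 100).
#' @param seed Integer seed; the table is reproducible given `(n, B, seed)`.
#' @return Numeric vector of `B` null dip values.
#' @export
dip_null_dips <- function(n, B = 2000L, seed = 1L) {
  if (B < 100L) stop("B must be at least 100")
  key <- paste(n, B, seed, sep = "_")
  if (!is.null(.dip_cache[[key]])) return(.dip_cache[[key]])
  d <- with_seed(seed, {
    vapply(seq_len(B), function(b) dip_statistic(stats::runif(n)), numeric(1))
  })
  .dip_cache[[key]] <- d
  d
}

#' Monte-Carlo p-value for the dip statistic
#'
#' `p = (1 + #\{b : D_b >= D\}) / (B + 1)` where the `D_b` are dips of iid
#' uniform(0,1) samples of size `n` (the classical unimodal null).
#'
#' @param D Observed dip statistic.
#' @param n Sample size the dip was computed from.
#' @inheritParams dip_null_dips
#' @return A p-value in (0, 1].
#' @export
dip_pvalue <- function(D, n, B = 2000L, seed = 1L) {
  null <- dip_null_dips(n, B = B, seed = seed)
  (1 + sum(null >= D)) / (B + 1)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL uses the
# current stream unchanged.
with_seed <- function(seed, expr) {
  expr <- substitute(expr)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  eval(expr, envir = parent.frame())
}
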