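#' Tertile bins of a conditioning gene
#'
#' Samples are sorted by the expression of the conditioning (switch) gene
#' X3; the bottom `floor(n/3)` form the low bin, the top `floor(n/3)` the
#' high bin, and the remainder the middle bin. Ties are broken by original
#' sample order (stable sort).
#'
#' @param x3 Numeric vector of X3 expression, length at least 9.
#' @return A list with integer index vectors `low`, `mid`, `high`.
#' @export
tertile_bins <- function(x3) {
  n <- length(x3)
  if (n < 9L) stop("tertile binning requires at least 9 samples")
  k <- n %/% 3L
  ord <- order(x3)
  list(low = sort(ord[seq_len(k)]),
       mid = sort(ord[(k + 1L):(n - k)]),
       high = sort(ord[(n - k + 1L):n]))
}

#' Correlation difference between outer X3 tertiles
#'
#' Pearson correlation of X1 and X2 within the bottom and top tertile bins
#' of X3; `rhodiff = rho_high - rho_low`. A cross-shaped triplet has a
#' large `|rhodiff|` (opposite correlation signs in the two outer bins).
#'
#' @param x1,x2,x3 Numeric vectors of equal length (transformed scale).
#' @return A list with `rho_low`, `rho_high` and `rhodiff`. When a bin has
#'   zero variance in X1 or X2 the correlations are `NA`.
#' @export
rhodiff <- function(x1, x2, x3) {
  n <- length(x3)
  if (length(x1) != n || length(x2) != n) stop("length mismatch")
  bins <- tertile_bins(x3)
  rl <- suppressWarnings(stats::cor(x1[bins$low], x2[bins$low]))
  rh <- suppressWarnings(stats::cor(x1[bins$high], x2[bins$high]))
  list(rho_low = rl, rho_high = rh, rhodiff = rh - rl)
}

#' Product-moment liquid association statistic
#'
#' `LA(X1, X2 | X3) = mean(x1 * x2 * x3)`: the third-order moment measuring
#' how the X1-X2 co-expression varies with the level of X3. Inputs are
#' expected on the transformed scale (normal scores, standardized), where
#' the statistic equals `E[X1 X2 X3]` and is symmetric in X1 and X2.
#'
#' @param x1,x2,x3 Numeric vectors of equal length.
#' @return The liquid association value.
#' @export
la_statistic <- function(x1, x2, x3) {
  n <- length(x1)
  if (length(x2) != n || length(x3) != n) stop("length mismatch")
  mean(x1 * x2 * x3)
}

#' Bootstrap Wald statistic for a liquid association value
#'
#' Draws `B` seeded nonparametric bootstrap resamples of the sample indices,
#' recomputes the LA statistic on each, and forms
#' `wald = (la / se)^2` with `se` the standard deviation of the bootstrap
#' replicates.
#'
#' @inheritParams la_statistic
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A list with `la_value`, `se` and `wald` (`wald` is `NA` when the
#'   bootstrap standard error is zero).
#' @export
bootstrap_wald <- function(x1, x2, x3, B = 500L, seed = NULL) {
  if (B < 100L) stop("B must be at least 100")
  n <- length(x1)
  if (length(x2) != n || length(x3) != n) stop("length mismatch")
  prods <- x1 * x2 * x3
  la <- mean(prods)
  las <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colMeans(matrix(prods[idx], nrow = n, ncol = B))
  })
  se <- stats::sd(las)
  list(la_value = la, se = se,
       wald = if (se > 0) (la / se)^2 else NA_real_)
}

#' Two-sided normal p-value from a Wald statistic
#'
#' `p = 2 * (1 - Phi(sqrt(wald)))`.
#'
#' @param wald Non-negative Wald statistic (vectorized).
#' @return p-value(s) in `[0, 1]`.
#' @export
wald_to_p <- function(wald) {
  if (any(wald < 0)) stop("wald statistic must be non-negative")
  2 * stats::pnorm(sqrt(wald), lower.tail = FALSE)
}

#' Top-K Bonferroni correction
#'
#' `min(1, p * M)` with `M` the number of retained top-ranked triplets.
#'
#' @param p Raw p-value(s).
#' @param M Multiplier (number of retained triplets, at least 1).
#' @return Corrected p-value(s), capped at 1.
#' @export
bonferroni_topk <- function(p, M) {
  if (any(M < 1)) stop("M must be at least 1")
  pmin(1, p * M)
}

#' Screening configuration
#'
#' @param top_k Number of top-ranked triplets retained; the retained count
#'   is also the Bonferroni multiplier. The published screen used 300,000;
#'   desk-scale runs use much smaller values.
#' @param alpha Significance threshold on the Bonferroni-corrected p-value.
#' @param bootstrap_B Bootstrap resamples for the Wald statistic.
#' @param screen_fraction Fraction of triplets (ranked by `|rhodiff|`)
#'   advanced to the full LA + bootstrap Wald stage.
#' @param seed Integer master seed for the bootstrap.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(top_k = 300000L, alpha = 0.05, bootstrap_B = 500L,
                          screen_fraction = 1, seed = 1L) {
  stopifnot(top_k >= 1, alpha > 0, alpha < 1, bootstrap_B >= 100,
            screen_fraction > 0, screen_fraction <= 1)
  structure(list(top_k = as.integer(top_k), alpha = alpha,
                 bootstrap_B = as.integer(bootstrap_B),
                 screen_fraction = screen_fraction, seed = as.integer(seed)),
            class = "screen_config")
}

#' Screen all (X1, X2 | X3) triplets for cross-shaped co-expression
#'
#' For every candidate switch gene X3 and every unordered pair of other
#' genes, computes the tertile correlation difference; the top
#' `screen_fraction` by `|rhodiff|` advance to the liquid association
#' statistic and seeded bootstrap Wald test. Evaluated triplets are ranked
#' by p-value (ties by `(x3, x1, x2)`), the top `top_k` retained, and
#' Bonferroni-corrected with multiplier equal to the retained count.
#'
#' @param m An [expr_matrix] on the raw scale (the transform is applied
#'   internally).
#' @param candidates Character vector of candidate switch gene ids.
#' @param cfg A [screen_config].
#' @return A data.frame with columns `x1`, `x2`, `x3`, `rho_low`,
#'   `rho_high`, `rhodiff`, `la_value`, `wald`, `p`, `bonferroni`,
#'   `significant`, canonical with `x1 < x2`; attribute `n_skipped` counts
#'   triplets dropped for undefined within-bin correlations or zero
#'   bootstrap standard error, attribute `n_evaluated` the number advanced
#'   past the rhodiff screen.
#' @export
screen_triplets <- function(m, candidates, cfg = screen_config()) {
  stopifnot(inherits(m, "expr_matrix"), inherits(cfg, "screen_config"))
  genes <- rownames(m$values)
  if (!all(candidates %in% genes))
    stop("candidate(s) not in matrix: ",
         paste(setdiff(candidates, genes), collapse = ", "))
  empty <- data.frame(x1 = character(), x2 = character(), x3 = character(),
                      rho_low = numeric(), rho_high = numeric(),
                      rhodiff = numeric(), la_value = numeric(),
                      wald = numeric(), p = numeric(),
                      bonferroni = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (!length(candidates)) {
    message("screen_triplets: no candidate switch genes, empty screen")
    attr(empty, "n_skipped") <- 0L
    attr(empty, "n_evaluated") <- 0L
    return(empty)
  }
  tm <- transform_matrix(m)
  tv <- tm$values
  parts <- vector("list", length(candidates))
  n_skipped <- 0L
  for (ci in seq_along(sort(candidates))) {
    x3 <- sort(candidates)[ci]
    others <- sort(setdiff(genes, x3))
    bins <- tertile_bins(tv[x3, ])
    cl <- suppressWarnings(stats::cor(t(tv[others, bins$low, drop = FALSE])))
    ch <- suppressWarnings(stats::cor(t(tv[others, bins$high, drop = FALSE])))
    ut <- which(upper.tri(cl), arr.ind = TRUE)
    d <- data.frame(x1 = others[ut[, 1L]], x2 = others[ut[, 2L]], x3 = x3,
                    rho_low = cl[ut], rho_high = ch[ut],
                    stringsAsFactors = FALSE)
    bad <- is.na(d$rho_low) | is.na(d$rho_high)
    if (any(bad)) {
      n_skipped <- n_skipped + sum(bad)
      message(sprintf(
        "screen_triplets: %d pair(s) with undefined within-bin correlation for X3=%s skipped",
        sum(bad), x3))
      d <- d[!bad, , drop = FALSE]
    }
    parts[[ci]] <- d
  }
  trip <- do.call(rbind, parts)
  if (!nrow(trip)) {
    attr(empty, "n_skipped") <- n_skipped
    attr(empty, "n_evaluated") <- 0L
    return(empty)
  }
  trip$rhodiff <- trip$rho_high - trip$rho_low
  # rhodiff screen: advance the top fraction by |rhodiff|
  n_adv <- max(1L, ceiling(cfg$screen_fraction * nrow(trip)))
  ord <- order(-abs(trip$rhodiff), trip$x3, trip$x1, trip$x2)
  trip <- trip[ord[seq_len(n_adv)], , drop = FALSE]
  # full stage, deterministic order and per-triplet derived seeds
  trip <- trip[order(trip$x3, trip$x1, trip$x2), , drop = FALSE]
  trip$la_value <- NA_real_
  trip$wald <- NA_real_
  for (t in seq_len(nrow(trip))) {
    bw <- bootstrap_wald(tv[trip$x1[t], ], tv[trip$x2[t], ], tv[trip$x3[t], ],
                         B = cfg$bootstrap_B,
                         seed = (cfg$seed + t) %% .Machine$integer.max)
    trip$la_value[t] <- bw$la_value
    trip$wald[t] <- bw$wald
  }
  if (anyNA(trip$wald)) {
    n_skipped <- n_skipped + sum(is.na(trip$wald))
    message(sprintf("screen_triplets: %d triplet(s) with zero bootstrap se skipped",
                    sum(is.na(trip$wald))))
    trip <- trip[!is.na(trip$wald), , drop = FALSE]
  }
  trip$p <- wald_to_p(trip$wald)
  n_evaluated <- nrow(trip)
  trip <- trip[order(trip$p, trip$x3, trip$x1, trip$x2), , drop = FALSE]
  trip <- trip[seq_len(min(cfg$top_k, nrow(trip))), , drop = FALSE]
  trip$bonferroni <- bonferroni_topk(trip$p, nrow(trip))
  trip$significant <- trip$bonferroni < cfg$alpha
  rownames(trip) <- NULL
  attr(trip, "n_skipped") <- n_skipped
  attr(trip, "n_evaluated") <- n_evaluated
  trip
}
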