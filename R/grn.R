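#' Mutual information by equal-frequency binning of ranks
#'
#' Discretizes each vector into `bins` equal-frequency bins of its ranks
#' (ties broken by position) and computes the plug-in mutual information of
#' the joint histogram, in nats:
#' `sum p(a,b) * log(p(a,b) / (p(a) p(b)))`, clamped at 0.
#'
#' @param x,y Numeric vectors of equal length, at least 10.
#' @param bins Number of bins (default `ceiling(sqrt(n))`).
#' @return Mutual information in nats (non-negative).
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 10L) stop("need at least 10 observations")
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  if (bins < 2L) stop("bins must be at least 2")
  cx <- .ef_bins(x, bins)
  cy <- .ef_bins(y, bins)
  joint <- tabulate(cx + bins * (cy - 1L), nbins = bins * bins) / n
  px <- tabulate(cx, nbins = bins) / n
  py <- tabulate(cy, nbins = bins) / n
  ep <- outer(px, py)
  pos <- joint > 0
  max(0, sum(joint[pos] * log(joint[pos] / as.vector(ep)[pos])))
}

# equal-frequency bin codes of ranks (first-occurrence tie-break)
.ef_bins <- function(x, bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / n))
}

#' Permutation threshold for mutual-information edges
#'
#' Computes MI between `n_perm` independently permuted random gene pairs
#' and returns the `(1 - alpha)` quantile, the significance cutoff below
#' which an edge is considered noise.
#'
#' @param m An [expr_matrix].
#' @param n_perm Number of permuted pairs (at least 100).
#' @param alpha Acceptance rate for null edges (default 0.05).
#' @param bins Passed to [mutual_information()].
#' @param seed Integer seed.
#' @return The MI threshold (numeric scalar).
#' @export
mi_threshold <- function(m, n_perm = 500L, alpha = 0.05, bins = NULL, seed = 1L) {
  stopifnot(inherits(m, "expr_matrix"))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (alpha >= 1) return(0)  # keep everything
  vals <- m$values
  ng <- nrow(vals)
  n <- ncol(vals)
  mis <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ij <- sample.int(ng, 2L)
      mutual_information(vals[ij[1L], ], vals[ij[2L], sample.int(n)], bins = bins)
    }, numeric(1))
  })
  stats::quantile(mis, 1 - alpha, names = FALSE)
}

#' Build a mutual-information network
#'
#' Computes MI for every gene pair and keeps edges with MI at or above the
#' threshold.
#'
#' @param m An [expr_matrix].
#' @param threshold Minimum MI for an edge (e.g. from [mi_threshold()]).
#' @param bins Passed to [mutual_information()].
#' @return An object of class `mi_network`: list with `nodes` (character)
#'   and `edges` (data.frame `gene_a`, `gene_b`, `mi` with
#'   `gene_a < gene_b`).
#' @export
build_mi_network <- function(m, threshold = 0, bins = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  genes <- sort(rownames(m$values))
  ng <- length(genes)
  n <- ncol(m$values)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  codes <- t(apply(m$values[genes, , drop = FALSE], 1L, .ef_bins, bins = bins))
  px <- tabulate(codes[1L, ], nbins = bins) / n  # identical per gene by construction
  lp_marg <- log(outer(px, px))
  M <- matrix(0, ng, ng)
  for (i in seq_len(ng - 1L)) {
    ci <- codes[i, ]
    for (j in (i + 1L):ng) {
      joint <- tabulate(ci + bins * (codes[j, ] - 1L), nbins = bins * bins) / n
      pos <- joint > 0
      M[i, j] <- max(0, sum(joint[pos] * (log(joint[pos]) - as.vector(lp_marg)[pos])))
    }
  }
  keep <- which(upper.tri(M) & M >= threshold, arr.ind = TRUE)
  mi_network(genes,
             data.frame(gene_a = genes[keep[, 1L]], gene_b = genes[keep[, 2L]],
                        mi = M[keep], stringsAsFactors = FALSE))
}

#' Construct an `mi_network` object
#'
#' @param nodes Character vector of gene ids.
#' @param edges Data.frame with columns `gene_a`, `gene_b`, `mi`.
#' @return An `mi_network`.
#' @export
mi_network <- function(nodes, edges) {
  stopifnot(is.character(nodes),
            all(c("gene_a", "gene_b", "mi") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) stop("self-edges are not allowed")
  if (any(edges$mi < 0)) stop("negative MI weight")
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges), class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Data-processing-inequality pruning (ARACNE)
#'
#' For every triangle (i, j, k) in the network, the edge (i, j) is removed
#' when `mi_ij < min(mi_ik, mi_jk) * (1 - epsilon)`: the weakest edge of a
#' triangle is presumed an indirect interaction. All removals are decided
#' on the pre-pruning graph (no cascade), so the operation is idempotent.
#'
#' @param net An [mi_network()].
#' @param epsilon DPI tolerance in `[0, 1)` (default 0.1).
#' @return The pruned `mi_network`.
#' @export
dpi_prune <- function(net, epsilon = 0.1) {
  stopifnot(inherits(net, "mi_network"), epsilon >= 0, epsilon < 1)
  ed <- net$edges
  if (nrow(ed) < 3L) return(net)
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  W <- matrix(0, length(net$nodes), length(net$nodes))
  W[cbind(idx[ed$gene_a], idx[ed$gene_b])] <- ed$mi
  W <- W + t(W)
  A <- W > 0
  drop <- logical(nrow(ed))
  for (e in seq_len(nrow(ed))) {
    i <- idx[[ed$gene_a[e]]]
    j <- idx[[ed$gene_b[e]]]
    ks <- which(A[i, ] & A[j, ])
    if (length(ks) &&
        any(ed$mi[e] < pmin(W[i, ks], W[j, ks]) * (1 - epsilon)))
      drop[e] <- TRUE
  }
  mi_network(net$nodes, ed[!drop, , drop = FALSE])
}

#' Short-path support of a triplet in the regulatory network
#'
#' A triplet is GRN-supported when its X1 and X2 genes are connected in the
#' (pruned) network by a path of at most `max_intermediates + 1` edges. The
#' returned path is the shortest one, with lexicographic tie-breaks.
#'
#' @param net An [mi_network()].
#' @param x1,x2 Gene ids of the triplet pair.
#' @param max_intermediates Maximum intermediate genes on the path
#'   (default 7).
#' @return A list with `supported` (flag), `path` (character vector from
#'   `x1` to `x2`, or `NULL`) and `n_intermediates` (`NA` if unsupported).
#' @export
triplet_path_support <- function(net, x1, x2, max_intermediates = 7L) {
  stopifnot(inherits(net, "mi_network"), max_intermediates >= 0)
  unsupported <- list(supported = FALSE, path = NULL,
                      n_intermediates = NA_integer_)
  if (!(x1 %in% net$nodes) || !(x2 %in% net$nodes)) {
    message(sprintf("triplet_path_support: %s absent from network",
                    paste(setdiff(c(x1, x2), net$nodes), collapse = ", ")))
    return(unsupported)
  }
  if (!nrow(net$edges)) return(unsupported)
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  d2 <- igraph::distances(g, v = x2)[1L, ]
  len <- d2[[x1]]
  if (!is.finite(len) || len > max_intermediates + 1L) return(unsupported)
  # reconstruct the lexicographically smallest shortest path from x1
  path <- x1
  cur <- x1
  while (cur != x2) {
    nb <- names(igraph::neighbors(g, cur))
    nxt <- sort(nb[d2[nb] == d2[[cur]] - 1L])[1L]
    path <- c(path, nxt)
    cur <- nxt
  }
  list(supported = TRUE, path = path,
       n_intermediates = length(path) - 2L)
}
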