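#' Read gene sets from a GMT file with a term-level table
#'
#' Standard GMT lines (`term_id<TAB>description<TAB>gene1<TAB>gene2...`)
#' plus a companion TSV mapping `term_id` to its depth (`level`) in the
#' term hierarchy.
#'
#' @param path Path to the GMT file.
#' @param levels_path Path to the TSV with columns `term_id`, `level`.
#' @return A list of term sets; each element is a list with `term_id`,
#'   `name`, `level` (integer) and `genes` (character vector). Class
#'   `term_sets`.
#' @export
read_gmt <- function(path, levels_path) {
  lines <- readLines(path)
  lev <- utils::read.delim(levels_path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "level") %in% names(lev)))
    stop("levels file must have columns 'term_id' and 'level'")
  levels_map <- stats::setNames(as.integer(lev$level), lev$term_id)
  terms <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("malformed GMT line %d: term '%s' has no genes", i, f[1L]))
    if (!f[1L] %in% names(levels_map))
      stop(sprintf("term '%s' (GMT line %d) missing from levels file", f[1L], i))
    terms[[i]] <- list(term_id = f[1L], name = f[2L],
                       level = levels_map[[f[1L]]], genes = genes)
  }
  structure(terms, class = "term_sets")
}

#' Write gene sets to GMT + levels TSV
#'
#' @param terms A `term_sets` list as returned by [read_gmt()].
#' @param path Output GMT path.
#' @param levels_path Output levels TSV path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(terms, path, levels_path) {
  writeLines(vapply(terms, function(tt)
    paste(c(tt$term_id, tt$name, tt$genes), collapse = "\t"), character(1)),
    path)
  utils::write.table(
    data.frame(term_id = vapply(terms, `[[`, character(1), "term_id"),
               level = vapply(terms, `[[`, integer(1), "level")),
    levels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hypergeometric over-representation of terms in a query gene set
#'
#' For each term at depth `min_level` or deeper, tests over-representation
#' of the query in the term with the upper-tail hypergeometric probability
#' `P(X >= hits)` for `X ~ Hypergeom(N = |population|,
#' K = |term & population|, n = |query|)`, followed by Holm step-down
#' adjustment (Bonferroni step-down) across all tested terms.
#'
#' @param query Character vector of query gene ids (subset of
#'   `population`).
#' @param terms A `term_sets` list.
#' @param population Character vector: the gene universe.
#' @param min_level Minimum term depth tested (default 5; shallower terms
#'   are too general and are excluded).
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A data.frame (`term_id`, `name`, `level`, `term_size`, `hits`,
#'   `query_size`, `population`, `p_hyper`, `p_adj`, `enriched`) sorted by
#'   `p_hyper` with ties by `term_id`.
#' @export
hypergeom_enrich <- function(query, terms, population, min_level = 5L,
                             alpha = 0.05) {
  query <- unique(query)
  population <- unique(population)
  if (!length(query)) stop("empty query")
  if (!all(query %in% population))
    stop("query gene(s) outside the population: ",
         paste(utils::head(setdiff(query, population), 5L), collapse = ", "))
  keep <- vapply(terms, function(tt) tt$level >= min_level, logical(1))
  terms <- terms[keep]
  N <- length(population)
  n <- length(query)
  rows <- lapply(terms, function(tt) {
    tg <- intersect(tt$genes, population)
    K <- length(tg)
    hits <- length(intersect(tg, query))
    p <- if (K == 0L) 1 else
      stats::phyper(hits - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tt$term_id, name = tt$name, level = tt$level,
               term_size = K, hits = hits, query_size = n, population = N,
               p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), name = character(),
                      level = integer(), term_size = integer(),
                      hits = integer(), query_size = integer(),
                      population = integer(), p_hyper = numeric(),
                      p_adj = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$p_adj <- stats::p.adjust(out$p_hyper, method = "holm")
  out$enriched <- out$p_adj < alpha
  out <- out[order(out$p_hyper, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two gene sets
#'
#' Agreement of the two membership indicators over the union of the two
#' sets: with `a = |A & B|`, `b = |A \ B|`, `c = |B \ A|` (and an empty
#' "neither" cell), `kappa = (po - pe) / (1 - pe)` for the observed and
#' chance agreement of the 2x2 table. Identical sets give 1; disjoint sets
#' give a value at or below 0.
#'
#' @param a,b Character vectors (gene sets).
#' @return Cohen's kappa.
#' @export
kappa_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  nu <- length(u)
  if (!nu) stop("both sets empty")
  n11 <- length(intersect(a, b))
  n10 <- length(setdiff(a, b))
  n01 <- length(setdiff(b, a))
  po <- n11 / nu
  pe <- (length(a) / nu) * (length(b) / nu) +
    ((nu - length(a)) / nu) * ((nu - length(b)) / nu)
  if (pe == 1) return(1)  # identical sets
  (po - pe) / (1 - pe)
}

#' Group enriched terms by kappa similarity
#'
#' Computes Cohen's kappa between every pair of enriched terms and groups
#' terms by single linkage over pairs with `kappa >= kappa_min` (connected
#' components). Groups are numbered deterministically in order of their
#' smallest `term_id`.
#'
#' @param enriched Data.frame from [hypergeom_enrich()] (rows with
#'   `enriched == TRUE` are grouped; others get `NA`).
#' @param terms The `term_sets` list the enrichment was computed from.
#' @param kappa_min Kappa threshold for linking two terms (default 0.4).
#' @return The `enriched` data.frame with an added integer column
#'   `kappa_group`.
#' @export
kappa_group <- function(enriched, terms, kappa_min = 0.4) {
  stopifnot(kappa_min > 0, kappa_min <= 1)
  genes_of <- stats::setNames(lapply(terms, `[[`, "genes"),
                              vapply(terms, `[[`, character(1), "term_id"))
  enriched$kappa_group <- NA_integer_
  ids <- sort(enriched$term_id[enriched$enriched])
  if (!length(ids)) return(enriched)
  k <- length(ids)
  adj <- matrix(FALSE, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        adj[i, j] <- adj[j, i] <-
          kappa_score(genes_of[[ids[i]]], genes_of[[ids[j]]]) >= kappa_min
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber components by smallest member term_id (ids are sorted)
  first_seen <- !duplicated(comp)
  renum <- stats::setNames(seq_len(sum(first_seen)), comp[first_seen])
  enriched$kappa_group[match(ids, enriched$term_id)] <-
    as.integer(renum[as.character(comp)])
  enriched
}

#' Flag triplets whose gene pair shares an enriched term
#'
#' A triplet is "enrichment-supported" when at least one enriched term
#' contains both its X1 and X2 genes (the pair is expected to act in a
#' common biological process).
#'
#' @param triplets Data.frame with columns `x1`, `x2` (e.g. from
#'   [screen_triplets()]).
#' @param enriched Data.frame from [hypergeom_enrich()].
#' @param terms The `term_sets` list.
#' @return Logical vector, one flag per triplet row.
#' @export
relevant_triplets <- function(triplets, enriched, terms) {
  genes_of <- stats::setNames(lapply(terms, `[[`, "genes"),
                              vapply(terms, `[[`, character(1), "term_id"))
  enr_sets <- genes_of[enriched$term_id[enriched$enriched]]
  if (!nrow(triplets)) return(logical(0))
  vapply(seq_len(nrow(triplets)), function(i) {
    any(vapply(enr_sets, function(gs)
      triplets$x1[i] %in% gs && triplets$x2[i] %in% gs, logical(1)))
  }, logical(1))
}
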