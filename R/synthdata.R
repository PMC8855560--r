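#' Generate an expression matrix with planted switch genes and triplets
#'
#' Emulates the study design of a two-group (case/control) expression
#' experiment with cross-shaped three-way interactions:
#'
#' * Each planted triplet has a switch gene X3 drawn `N(+delta, 1)` in
#'   controls and `N(-delta, 1)` in cases — hence strongly differentially
#'   expressed and, with the default `delta = 1.5` (group separation
#'   `2*delta = 3` sd), bimodal across the pooled samples. Its pair
#'   (X1, X2) is drawn bivariate normal with correlation `+rho` for samples
#'   whose X3 value lies above the X3 median and `-rho` otherwise (the
#'   cross-shaped pattern; the switch is keyed to the median at generation
#'   time, so the analysis-side tertile binning is not presupposed).
#' * `n_de_only` decoy genes are differentially expressed but unimodal:
#'   mean shift `delta` between groups, which stays below the `2` sd
#'   separation at which an equal two-component normal mixture becomes
#'   bimodal.
#' * `n_bimodal_only` decoy genes are symmetric `+/-delta` mixtures with no
#'   group association.
#' * All remaining genes are iid `N(0, 1)` noise.
#'
#' @param n_genes Total number of genes (at least `3*n_triplets + 10`).
#' @param n_per_group Samples per group (default 45, i.e. 90 in total).
#' @param n_triplets Number of planted triplets (default 3).
#' @param rho Within-stratum correlation of the planted pairs (default
#'   0.7, giving an expected outer-tertile correlation contrast near
#'   `2*rho = 1.4`).
#' @param delta Mean shift of switch and decoy genes (default 1.5).
#' @param n_de_only,n_bimodal_only Number of decoy genes of each kind
#'   (default 5).
#' @param seed Integer seed; the output is fully reproducible.
#' @return A list with `matrix` (an [expr_matrix]) and `truth` (a list:
#'   `planted_triplets` data.frame with columns `x1`, `x2`, `x3`, `rho`,
#'   `delta`; `de_only`, `bimodal_only`, `null_genes` id vectors;
#'   `seed`, `n_per_group`).
#' @export
generate_synthetic <- function(n_genes = 200L, n_per_group = 45L,
                               n_triplets = 3L, rho = 0.7, delta = 1.5,
                               n_de_only = 5L, n_bimodal_only = 5L,
                               seed = 1L) {
  if (n_genes < 3L * n_triplets + 10L)
    stop("n_genes must be at least 3*n_triplets + 10")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (delta < 0) stop("delta must be non-negative")
  if (n_per_group < 5L) stop("need at least 5 samples per group")
  if (3L * n_triplets + n_de_only + n_bimodal_only > n_genes)
    stop("too many planted genes for n_genes")
  n <- 2L * n_per_group
  group <- rep(c("case", "control"), each = n_per_group)
  samples <- sprintf("s%03d", seq_len(n))
  wd <- max(nchar("1"), nchar(as.character(n_genes)))
  genes <- sprintf(paste0("g%0", wd, "d"), seq_len(n_genes))
  vals <- with_seed(seed, {
    v <- matrix(stats::rnorm(n_genes * n), nrow = n_genes,
                dimnames = list(genes, samples))
    gi <- 0L
    for (t in seq_len(n_triplets)) {
      x3 <- gi + 1L; x1 <- gi + 2L; x2 <- gi + 3L; gi <- gi + 3L
      mu3 <- ifelse(group == "case", -delta, +delta)
      v[x3, ] <- stats::rnorm(n, mean = mu3)
      hi <- v[x3, ] > stats::median(v[x3, ])
      z1 <- stats::rnorm(n)
      z2 <- stats::rnorm(n)
      r <- ifelse(hi, rho, -rho)
      v[x1, ] <- z1
      v[x2, ] <- r * z1 + sqrt(1 - r^2) * z2
    }
    for (d in seq_len(n_de_only)) {
      gi <- gi + 1L
      v[gi, ] <- stats::rnorm(n, mean = ifelse(group == "case",
                                               -delta / 2, +delta / 2))
    }
    for (d in seq_len(n_bimodal_only)) {
      gi <- gi + 1L
      v[gi, ] <- stats::rnorm(n, mean = sample(c(-delta, delta), n,
                                               replace = TRUE))
    }
    v
  })
  tri_idx <- seq_len(n_triplets)
  truth <- list(
    planted_triplets = data.frame(
      x1 = genes[3L * (tri_idx - 1L) + 2L],
      x2 = genes[3L * (tri_idx - 1L) + 3L],
      x3 = genes[3L * (tri_idx - 1L) + 1L],
      rho = rep(rho, n_triplets), delta = rep(delta, n_triplets),
      stringsAsFactors = FALSE),
    de_only = genes[3L * n_triplets + seq_len(n_de_only)],
    bimodal_only = genes[3L * n_triplets + n_de_only + seq_len(n_bimodal_only)],
    null_genes = genes[(3L * n_triplets + n_de_only + n_bimodal_only + 1L):n_genes],
    seed = seed, n_per_group = n_per_group)
  list(matrix = expr_matrix(vals, stats::setNames(group, samples)),
       truth = truth)
}

#' Write a complete synthetic fixture to a directory
#'
#' Emits every input the pipeline consumes: expression TSV, groups TSV, a
#' probe-to-symbol map (with a few deliberately duplicated probes whose
#' values are shrunk towards the gene median, so the max-IQR collapse rule
#' is exercised), a GMT annotation in which each planted pair shares a deep
#' term (plus decoy terms and one shallow term), the term-level TSV, and
#' the ground-truth manifest as JSON.
#'
#' @param sim Output of [generate_synthetic()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- sim$matrix
  truth <- sim$truth
  genes <- rownames(m$values)
  paths <- list(
    expr = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    id_map = file.path(dir, "id_map.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    levels = file.path(dir, "term_levels.tsv"),
    truth = file.path(dir, "truth.json"))
  # probe-level matrix: one probe per gene plus duplicate low-IQR probes
  # for the first three genes
  probes <- paste0("p_", genes)
  pv <- m$values
  rownames(pv) <- probes
  dup_genes <- utils::head(genes, 3L)
  dup <- m$values[dup_genes, , drop = FALSE]
  med <- apply(dup, 1L, stats::median)
  dup <- sweep(sweep(dup, 1L, med) * 0.5, 1L, med, `+`)
  rownames(dup) <- paste0("p_", dup_genes, "_dup")
  pv <- rbind(pv, dup)
  pm <- expr_matrix(pv, stats::setNames(m$groups, colnames(pv)),
                    case_level = m$case_level)
  write_matrix(pm, paths$expr, groups_path = paths$groups)
  utils::write.table(
    data.frame(probe_id = c(probes, rownames(dup)),
               gene_symbol = c(genes, dup_genes)),
    paths$id_map, sep = "\t", quote = FALSE, row.names = FALSE)
  # annotations: one deep term per planted pair + decoys + one shallow term
  terms <- list()
  null_pool <- truth$null_genes
  take <- function(k, offset) {  # deterministic wrapped slice of the null pool
    unique(null_pool[((offset + seq_len(k) - 1L) %% length(null_pool)) + 1L])
  }
  for (t in seq_len(nrow(truth$planted_triplets))) {
    terms[[length(terms) + 1L]] <- list(
      term_id = sprintf("SYN:%04d", t),
      name = sprintf("synthetic process %d (planted pair %d)", t, t),
      level = 6L,
      genes = c(truth$planted_triplets$x1[t], truth$planted_triplets$x2[t],
                truth$planted_triplets$x3[t], take(2L, (t - 1L) * 2L)))
  }
  n_decoy <- 4L
  for (d in seq_len(n_decoy)) {
    terms[[length(terms) + 1L]] <- list(
      term_id = sprintf("SYN:9%03d", d),
      name = sprintf("synthetic decoy term %d", d),
      level = 5L + d %% 3L,
      genes = take(5L, 12L + (d - 1L) * 5L))
  }
  terms[[length(terms) + 1L]] <- list(
    term_id = "SYN:0000", name = "synthetic shallow (general) term",
    level = 2L, genes = utils::head(genes, 10L))
  class(terms) <- "term_sets"
  write_gmt(terms, paths$gmt, paths$levels)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
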