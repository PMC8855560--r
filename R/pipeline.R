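#' Pipeline run configuration
#'
#' Collects every input path and stage parameter of the end-to-end screen.
#' Each stochastic stage derives its own seed deterministically from the
#' master seed (offset by a fixed per-stage hash of the stage name), so
#' stages are independently reproducible.
#'
#' @param expr,groups,id_map,gmt,levels Input file paths (`id_map`, `gmt`
#'   and `levels` may be `NULL` to skip probe collapsing / enrichment).
#' @param outdir Output directory.
#' @param case_level Group label treated as case (`NULL`: auto-detect
#'   `"case"`).
#' @param alpha_de,alpha_fdr,alpha_dip Switch-gene selection thresholds.
#' @param dip_B Dip-test Monte-Carlo replicates.
#' @param top_k,alpha,bootstrap_B,screen_fraction Screening parameters
#'   (see [screen_config()]).
#' @param mi_alpha,n_perm,epsilon GRN parameters: permutation level and
#'   count for the MI threshold, DPI tolerance.
#' @param max_intermediates Maximum intermediates for GRN path support.
#' @param min_level,kappa_min Enrichment parameters.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(expr, groups, outdir,
                       id_map = NULL, gmt = NULL, levels = NULL,
                       case_level = NULL,
                       alpha_de = 0.05, alpha_fdr = 0.05, alpha_dip = 0.05,
                       dip_B = 2000L,
                       top_k = 1000L, alpha = 0.05, bootstrap_B = 500L,
                       screen_fraction = 0.01,
                       mi_alpha = 0.05, n_perm = 500L, epsilon = 0.1,
                       max_intermediates = 7L,
                       min_level = 5L, kappa_min = 0.4,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("expr", "groups")) {
    if (!file.exists(cfg[[p]])) stop("input file missing: ", cfg[[p]])
  }
  for (p in c("id_map", "gmt", "levels")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input file missing: ", cfg[[p]])
  }
  structure(cfg, class = "run_config")
}

# deterministic per-stage seed below 2^31
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 10007 + h) %% 2147483647)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are passed to [run_config()] with numeric conversion where the
#' default is numeric.
#'
#' @param path Path to the config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  args <- stats::setNames(as.list(vals), keys)
  defaults <- formals(run_config)
  for (k in names(args)) {
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    if (is.numeric(defaults[[k]]) || is.integer(defaults[[k]]))
      args[[k]] <- as.numeric(args[[k]])
  }
  do.call(run_config, args)
}

#' Run the full liquid-association pipeline
#'
#' Executes, in order: matrix input (+ optional probe collapse), switch
#' candidate selection, triplet screening, MI network construction with
#' DPI pruning and path support, and gene-set enrichment with kappa
#' grouping and pair-level relevance flags. Each stage writes its TSV to
#' `outdir`; a run report (per-stage counts, config, derived seeds) is
#' written to `report.json`. Re-running with the same config reproduces
#' every output byte for byte. Empty intermediate results downgrade
#' downstream stages to no-ops with warnings.
#'
#' @param cfg A [run_config()].
#' @return The run report, invisibly (a named list).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg[setdiff(names(cfg), "case_level")])
  seeds <- list(select = stage_seed(cfg$seed, "select"),
                screen = stage_seed(cfg$seed, "screen"),
                grn = stage_seed(cfg$seed, "grn"))
  report$seeds <- seeds
  tsv <- function(d, f) utils::write.table(
    d, file.path(cfg$outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 1: input
  m <- read_matrix(cfg$expr, cfg$groups, case_level = cfg$case_level)
  if (!is.null(cfg$id_map)) {
    id_map <- utils::read.delim(cfg$id_map, stringsAsFactors = FALSE)
    m <- collapse_duplicates(m, id_map)
  }
  report$n_genes <- nrow(m$values)
  report$n_samples <- ncol(m$values)
  message(sprintf("[expr_io] %d genes x %d samples", nrow(m$values),
                  ncol(m$values)))

  ## stage 2: switch candidates
  cand <- select_candidates(m, alpha_de = cfg$alpha_de,
                            alpha_fdr = cfg$alpha_fdr,
                            alpha_dip = cfg$alpha_dip,
                            dip_B = cfg$dip_B, seed = seeds$select)
  tsv(cand, "switch_candidates.tsv")
  candidates <- cand$gene_id[cand$selected]
  report$n_candidates <- length(candidates)
  message(sprintf("[switch_select] %d candidate switch gene(s)",
                  length(candidates)))

  ## stage 3: triplet screen
  scfg <- screen_config(top_k = cfg$top_k, alpha = cfg$alpha,
                        bootstrap_B = cfg$bootstrap_B,
                        screen_fraction = cfg$screen_fraction,
                        seed = seeds$screen)
  if (length(candidates)) {
    trip <- screen_triplets(m, candidates, scfg)
  } else {
    warning("no switch candidates; triplet screen skipped")
    trip <- screen_triplets(m, character(0), scfg)
  }
  tsv(trip, "triplets.tsv")
  report$n_triplets_evaluated <- attr(trip, "n_evaluated")
  report$n_triplets_retained <- nrow(trip)
  report$n_triplets_significant <- sum(trip$significant)
  message(sprintf("[liquid_assoc] %d evaluated, %d retained, %d significant",
                  report$n_triplets_evaluated, nrow(trip),
                  sum(trip$significant)))
  sig <- trip[trip$significant, , drop = FALSE]

  ## stage 4: GRN
  thr <- mi_threshold(m, n_perm = cfg$n_perm, alpha = cfg$mi_alpha,
                      seed = seeds$grn)
  net <- dpi_prune(build_mi_network(m, threshold = thr),
                   epsilon = cfg$epsilon)
  tsv(net$edges, "grn_edges.tsv")
  report$mi_threshold <- thr
  report$n_grn_nodes <- length(net$nodes)
  report$n_grn_edges <- nrow(net$edges)
  if (nrow(sig)) {
    support <- lapply(seq_len(nrow(sig)), function(i)
      triplet_path_support(net, sig$x1[i], sig$x2[i],
                           max_intermediates = cfg$max_intermediates))
    sig$grn_supported <- vapply(support, `[[`, logical(1), "supported")
    sig$grn_path <- vapply(support, function(s)
      if (s$supported) paste(s$path, collapse = ">") else "", character(1))
  } else {
    sig$grn_supported <- logical(0)
    sig$grn_path <- character(0)
  }
  report$n_grn_supported <- sum(sig$grn_supported)
  message(sprintf("[grn] %d edges (threshold %.4g); %d triplet(s) path-supported",
                  nrow(net$edges), thr, sum(sig$grn_supported)))

  ## stage 5: enrichment
  if (!is.null(cfg$gmt) && nrow(sig)) {
    terms <- read_gmt(cfg$gmt, cfg$levels)
    query <- unique(c(sig$x1, sig$x2, sig$x3))
    enr <- hypergeom_enrich(query, terms, population = rownames(m$values),
                            min_level = cfg$min_level, alpha = cfg$alpha)
    enr <- kappa_group(enr, terms, kappa_min = cfg$kappa_min)
    tsv(enr, "enrichment.tsv")
    sig$gsea_supported <- relevant_triplets(sig, enr, terms)
    report$n_enriched_terms <- sum(enr$enriched)
    report$n_gsea_supported <- sum(sig$gsea_supported)
    message(sprintf("[enrich] %d enriched term(s); %d triplet(s) supported",
                    sum(enr$enriched), sum(sig$gsea_supported)))
  } else {
    if (!is.null(cfg$gmt)) warning("no significant triplets; enrichment skipped")
    sig$gsea_supported <- logical(nrow(sig))
    report$n_enriched_terms <- 0L
    report$n_gsea_supported <- 0L
  }
  tsv(sig, "significant_triplets.tsv")
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
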