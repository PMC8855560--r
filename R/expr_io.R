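#' Expression matrix with two-group sample labels
#'
#' Lightweight container for a genes x samples log2-scale expression matrix
#' together with a case/control group label per sample. This is the substrate
#' of every stage of the liquid-association pipeline.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique, non-empty rownames (gene ids) and colnames (sample ids). All
#'   values must be finite; the matrix is assumed to be on the log2 scale and
#'   already normalized.
#' @param groups Named character vector (or factor) mapping every sample id to
#'   one of exactly two group labels. Both groups must be non-empty.
#' @param case_level Which group label plays the role of "case" (tumour) when
#'   computing log fold changes (case minus control). Defaults to `"case"`
#'   when that label is present; otherwise it must be given explicitly.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix), `groups` (character vector aligned with the columns) and
#'   `case_level`.
#' @export
expr_matrix <- function(values, groups, case_level = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("'values' must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(gid)) stop("duplicate gene ids: ",
                               paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid)) stop("duplicate sample ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values))) stop("non-finite expression values")
  groups <- stats::setNames(as.character(groups), names(groups))
  missing <- setdiff(sid, names(groups))
  if (length(missing))
    stop("sample(s) missing from groups: ", paste(missing, collapse = ", "))
  groups <- groups[sid]
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop("exactly two distinct groups required, found: ",
         paste(lev, collapse = ", "))
  if (is.null(case_level)) {
    if ("case" %in% lev) case_level <- "case"
    else stop("no group named 'case'; specify 'case_level' (one of: ",
              paste(lev, collapse = ", "), ")")
  }
  if (!case_level %in% lev) stop("case_level '", case_level, "' not a group label")
  if (min(table(groups)) < 1L) stop("both groups must be non-empty")
  structure(list(values = values, groups = groups, case_level = case_level),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("case level: %s\n", x$case_level))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample groups from TSV files
#'
#' The expression file has a header row of sample ids, a first column of
#' gene/probe ids and tab-separated numeric cells ("." decimal, no thousands
#' separators). The groups file has columns `sample_id` and `group`.
#' Row and column order are preserved from the files.
#'
#' @param path Path to the expression TSV.
#' @param groups_path Path to the groups TSV.
#' @inheritParams expr_matrix
#' @return An [expr_matrix] object.
#' @export
read_matrix <- function(path, groups_path, case_level = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sid <- header[-1L]
  if (anyDuplicated(sid))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  dat <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = c("character", rep("character", length(sid))),
                           stringsAsFactors = FALSE)
  gid <- dat[[1L]]
  vals <- suppressWarnings(
    vapply(seq_along(sid) + 1L, function(j) as.numeric(dat[[j]]), numeric(nrow(dat))))
  if (nrow(dat) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals) & !is.na(as.matrix(dat[, -1L, drop = FALSE])), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' in %s",
                 gid[bad[1L, 1L]], sid[bad[1L, 2L]], path))
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' in %s",
                 gid[idx[1L, 1L]], sid[idx[1L, 2L]], path))
  }
  dimnames(vals) <- list(gid, sid)
  grp <- utils::read.delim(groups_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(grp)))
    stop("groups file must have columns 'sample_id' and 'group'")
  expr_matrix(vals, stats::setNames(as.character(grp$group), grp$sample_id),
              case_level = case_level)
}

#' Write an expression matrix (and optionally its groups) to TSV
#'
#' Values are printed at full precision (17 significant digits) so that a
#' write/read round trip is bit-identical.
#'
#' @param m An [expr_matrix].
#' @param path Output path for the expression TSV.
#' @param groups_path Optional output path for the groups TSV.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path, groups_path = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample_id = colnames(m$values), group = m$groups),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Collapse duplicate probes to one row per gene symbol
#'
#' Among probes mapping to the same symbol, the probe with the largest
#' interquartile range across samples is kept (the conventional
#' variance-preserving collapse rule). Probes absent from `id_map` are
#' dropped.
#'
#' @param m An [expr_matrix] whose rownames are probe ids.
#' @param id_map Named character vector `probe_id -> gene_symbol` (or a
#'   two-column data.frame `probe_id`, `gene_symbol`).
#' @return An [expr_matrix] with one row per gene symbol.
#' @export
collapse_duplicates <- function(m, id_map) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.data.frame(id_map))
    id_map <- stats::setNames(as.character(id_map[[2L]]), id_map[[1L]])
  probes <- intersect(rownames(m$values), names(id_map))
  if (!length(probes)) stop("no probes left after applying id_map")
  sym <- id_map[probes]
  iqr <- apply(m$values[probes, , drop = FALSE], 1L, stats::IQR)
  keep <- vapply(split(seq_along(probes), sym), function(ix) {
    ix[which.max(iqr[ix])]
  }, integer(1))
  # preserve original row order of the kept probes
  keep <- keep[order(match(probes[keep], rownames(m$values)))]
  vals <- m$values[probes[keep], , drop = FALSE]
  rownames(vals) <- unname(sym[keep])
  expr_matrix(vals, m$groups, case_level = m$case_level)
}

#' Rank-based inverse normal (van der Waerden style) scores
#'
#' Maps a vector to normal quantiles of its ranks,
#' `qnorm((r - 0.5) / n)` with average ranks for ties. The output is a
#' strictly monotone transform of the ranks, so any monotone re-scaling of
#' the input yields identical scores.
#'
#' @param x Numeric vector, length at least 3, not constant.
#' @return Numeric vector of normal scores.
#' @export
normal_scores <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x))) stop("non-finite values")
  if (max(x) == min(x)) stop("constant vector: normal scores undefined")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.5) / n)
}

#' Standardize to mean 0 and unit sample standard deviation
#'
#' Uses the n-1 denominator for the standard deviation.
#'
#' @param x Numeric vector with positive sample variance.
#' @return Standardized vector.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) stop("zero-variance input: cannot standardize")
  (x - mean(x)) / s
}

#' Apply the liquid-association pre-processing to every gene
#'
#' Each row is transformed to normal scores and then standardized, the two
#' transforms required before computing liquid association.
#'
#' @param m An [expr_matrix].
#' @return An [expr_matrix] of transformed values.
#' @export
transform_matrix <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  vals <- t(apply(m$values, 1L, function(r) standardize(normal_scores(r))))
  dimnames(vals) <- dimnames(m$values)
  expr_matrix(vals, m$groups, case_level = m$case_level)
}
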