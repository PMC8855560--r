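#' Empirical-Bayes moderated t-test between the two sample groups
#'
#' Fits a two-group linear model per gene and moderates the residual
#' variances by empirical-Bayes shrinkage: the gene-wise pooled variances
#' `s^2_g` (with `d_g = n1 + n2 - 2` df) are shrunk towards a common prior
#' `s0^2` with prior df `d0`, both estimated by moment-matching on
#' `log s^2_g` (digamma/trigamma method). The moderated statistic is
#' `t_mod = log_fc / (s_tilde * sqrt(1/n1 + 1/n2))` with
#' `s_tilde^2 = (d0*s0^2 + d_g*s^2_g) / (d0 + d_g)`, referred to a t
#' distribution on `d0 + d_g` df. The fit is delegated to limma
#' (`lmFit`/`eBayes`), whose variance shrinkage implements exactly this
#' moment-matching scheme.
#'
#' @param m An [expr_matrix] with at least 2 samples per group.
#' @return A data.frame with columns `gene_id`, `log_fc` (case minus
#'   control, log2 units), `t_mod`, `p_de` (two-sided) and `df_total`;
#'   attributes `d0` and `s0_2` carry the estimated hyperparameters.
#' @export
moderated_t <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (min(table(m$groups)) < 2L)
    stop("need at least 2 samples per group")
  if (all(apply(m$values, 1L, stats::var) == 0))
    stop("all genes have zero variance")
  is_case <- as.numeric(m$groups == m$case_level)
  design <- cbind(Intercept = 1, case = is_case)
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  out <- data.frame(
    gene_id = rownames(m$values),
    log_fc = fit$coefficients[, "case"],
    t_mod = fit$t[, "case"],
    p_de = fit$p.value[, "case"],
    df_total = fit$df.total,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- fit$df.prior
  attr(out, "s0_2") <- fit$s2.prior
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone-enforced, capped at 1).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select candidate switch genes
#'
#' A candidate switch gene must be (1) differentially expressed between the
#' two groups — raw moderated-t p-value and BH false discovery rate both
#' below their thresholds — and (2) bimodally distributed across all
#' samples — Hartigan dip test Monte-Carlo p-value below its threshold.
#' The dip is only computed for genes that pass the differential-expression
#' filter; other genes carry `NA` dip columns.
#'
#' @param m An [expr_matrix].
#' @param alpha_de Threshold on the raw DE p-value (default 0.05).
#' @param alpha_fdr Threshold on the BH-adjusted DE p-value (default 0.05).
#' @param alpha_dip Threshold on the dip p-value (default 0.05).
#' @param dip_B Monte-Carlo replicates for the dip null (default 2000).
#' @param seed Integer seed for the dip null table.
#' @return A data.frame of per-gene statistics (`gene_id`, `log_fc`,
#'   `t_mod`, `p_de`, `fdr_de`, `dip_D`, `p_dip`, `selected`), sorted by
#'   `p_de` ascending with ties broken by `gene_id`.
#' @export
select_candidates <- function(m, alpha_de = 0.05, alpha_fdr = 0.05,
                              alpha_dip = 0.05, dip_B = 2000L, seed = 1L) {
  stopifnot(alpha_de > 0, alpha_de < 1, alpha_fdr > 0, alpha_fdr < 1,
            alpha_dip > 0, alpha_dip < 1)
  de <- moderated_t(m)
  de$fdr_de <- bh_fdr(de$p_de)
  de$dip_D <- NA_real_
  de$p_dip <- NA_real_
  pass_de <- de$p_de < alpha_de & de$fdr_de < alpha_fdr
  if (any(pass_de)) {
    n <- ncol(m$values)
    null_dips <- dip_null_dips(n, B = dip_B, seed = seed)
    for (i in which(pass_de)) {
      D <- dip_statistic(m$values[de$gene_id[i], ])
      de$dip_D[i] <- D
      de$p_dip[i] <- (1 + sum(null_dips >= D)) / (dip_B + 1)
    }
  }
  de$selected <- pass_de & !is.na(de$p_dip) & de$p_dip < alpha_dip
  de <- de[order(de$p_de, de$gene_id), , drop = FALSE]
  rownames(de) <- NULL
  if (!any(de$selected))
    message("select_candidates: no gene passed both filters")
  de
}
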