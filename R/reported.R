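#' Reference triplet statistics from a published PDAC screen
#'
#' Seven cross-shaped triplets reported by a pancreatic ductal
#' adenocarcinoma liquid-association screen (90 samples; switch genes NQO1,
#' AOX1, TSPAN1 and CXCL12), with the published tertile correlation
#' difference, modified-LA value, Wald statistic, p-value and top-300,000
#' Bonferroni correction. Used as an internal-consistency reference: the
#' printed p-values must equal `2*(1 - pnorm(sqrt(wald)))` and the printed
#' Bonferroni values `p * 300000`, to the printed precision.
#'
#' @return A data.frame with columns `x1`, `x2`, `x3`, `rhodiff`,
#'   `mla_value`, `wald`, `p`, `bonferroni`.
#' @export
reported_triplets <- function() {
  utils::read.delim(
    system.file("extdata", "reported_triplets.tsv", package = "laswitch"),
    stringsAsFactors = FALSE)
}
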