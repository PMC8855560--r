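# small in-code fixtures shared across test files

# deterministic toy expression matrix
toy_matrix <- function(ng = 6L, n1 = 5L, n2 = 5L, seed = 1L) {
  set.seed(seed)
  vals <- matrix(rnorm(ng * (n1 + n2)), nrow = ng,
                 dimnames = list(sprintf("g%02d", seq_len(ng)),
                                 sprintf("s%02d", seq_len(n1 + n2))))
  grp <- setNames(rep(c("case", "control"), c(n1, n2)), colnames(vals))
  expr_matrix(vals, grp)
}

# canonical triplet key for comparing screen output with planted truth
triplet_key <- function(d) {
  paste(pmin(d$x1, d$x2), pmax(d$x1, d$x2), d$x3, sep = "|")
}

# term_sets fixture built in code
toy_terms <- function() {
  structure(list(
    list(term_id = "T:001", name = "deep term A", level = 6L,
         genes = c("g1", "g2", "g3")),
    list(term_id = "T:002", name = "deep term B", level = 5L,
         genes = c("g2", "g3", "g4")),
    list(term_id = "T:003", name = "shallow term", level = 2L,
         genes = c("g1", "g5"))),
    class = "term_sets")
}
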