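test_that("tertile bins follow the floor rule with stable ties", {
  b <- tertile_bins(seq_len(90))
  expect_length(b$low, 30); expect_length(b$mid, 30); expect_length(b$high, 30)
  b <- tertile_bins(seq_len(10))
  expect_length(b$low, 3); expect_length(b$mid, 4); expect_length(b$high, 3)
  # sign flip swaps the outer bins
  x <- rnorm(12)
  b1 <- tertile_bins(x); b2 <- tertile_bins(-x)
  expect_identical(b1$low, b2$high)
  expect_identical(b1$high, b2$low)
  # ties broken by original sample order
  b3 <- tertile_bins(rep(1, 9))
  expect_identical(b3$low, 1:3)
  expect_identical(b3$high, 7:9)
  expect_error(tertile_bins(1:8), "at least 9")
})

test_that("rhodiff is zero for identical pair and recovers a planted contrast", {
  set.seed(2)
  x3 <- rnorm(30)
  x1 <- rnorm(30)
  r <- rhodiff(x1, x1, x3)
  expect_equal(r$rho_low, 1); expect_equal(r$rho_high, 1)
  expect_equal(r$rhodiff, 0)
  # planted +-0.7 within-bin correlation, n = 300: rhodiff near 1.4
  set.seed(3)
  rds <- vapply(1:10, function(i) {
    n <- 300
    x3 <- rnorm(n); hi <- x3 > median(x3)
    z1 <- rnorm(n); z2 <- rnorm(n)
    rr <- ifelse(hi, 0.7, -0.7)
    x2 <- rr * z1 + sqrt(1 - rr^2) * z2
    rhodiff(z1, x2, x3)$rhodiff
  }, numeric(1))
  expect_lt(abs(mean(rds) - 1.4), 0.15)
  # independent normals, n = 90: |rhodiff| rarely near the planted scale
  set.seed(4)
  null_rd <- vapply(1:200, function(i)
    rhodiff(rnorm(90), rnorm(90), rnorm(90))$rhodiff, numeric(1))
  expect_gte(mean(abs(null_rd) < 0.8), 0.99)
})

test_that("liquid association is the symmetric product moment", {
  x1 <- c(0.3, -1.2, 0.5, 2.0, -0.7, 0.1)
  x2 <- c(1.0, 0.4, -0.2, -1.5, 0.8, 0.6)
  x3 <- c(-0.5, 0.9, 1.1, 0.2, -1.3, 0.4)
  # brute-force summation oracle
  expect_equal(la_statistic(x1, x2, x3),
               sum(x1 * x2 * x3) / 6, tolerance = 1e-12)
  expect_identical(la_statistic(x1, x2, x3), la_statistic(x2, x1, x3))
  expect_identical(la_statistic(rep(0, 6), x2, x3), 0)
  expect_error(la_statistic(x1, x2, x3[-1]), "length mismatch")
})

test_that("bootstrap Wald is seeded and consistent with its definition", {
  set.seed(6)
  x1 <- rnorm(40); x2 <- rnorm(40); x3 <- rnorm(40)
  b1 <- bootstrap_wald(x1, x2, x3, B = 200, seed = 9)
  b2 <- bootstrap_wald(x1, x2, x3, B = 200, seed = 9)
  expect_identical(b1, b2)
  expect_equal(b1$wald, (b1$la_value / b1$se)^2)
  expect_equal(b1$la_value, mean(x1 * x2 * x3))
  expect_error(bootstrap_wald(x1, x2, x3, B = 50), "at least 100")
  # planted strong triplet typically scores a large Wald statistic
  set.seed(8)
  walds <- vapply(1:20, function(i) {
    n <- 90
    x3 <- rnorm(n); hi <- x3 > median(x3)
    z1 <- rnorm(n); z2 <- rnorm(n)
    rr <- ifelse(hi, 0.7, -0.7)
    tr <- function(v) standardize(normal_scores(v))
    bootstrap_wald(tr(z1), tr(rr * z1 + sqrt(1 - rr^2) * z2), tr(x3),
                   B = 300, seed = i)$wald
  }, numeric(1))
  expect_gte(median(walds), 12)
})

test_that("Wald to p-value mapping reproduces the published table rows", {
  rep_tab <- reported_triplets()
  p <- wald_to_p(rep_tab$wald)
  expect_equal(signif(p, 3), rep_tab$p)
  expect_identical(wald_to_p(0), 1)
  # strictly decreasing in wald
  w <- seq(0, 40, by = 0.5)
  expect_true(all(diff(wald_to_p(w)) < 0))
  expect_error(wald_to_p(-1), "non-negative")
})

test_that("top-K Bonferroni reproduces the published corrections and caps", {
  rep_tab <- reported_triplets()
  expect_equal(signif(bonferroni_topk(rep_tab$p, 300000), 3), rep_tab$bonferroni)
  expect_identical(bonferroni_topk(0.5, 3), 1)
  # non-decreasing in M
  expect_true(all(diff(bonferroni_topk(1e-6, c(10, 100, 1000))) > 0))
  expect_error(bonferroni_topk(0.1, 0), "at least 1")
})

test_that("degenerate screens behave per contract", {
  m <- toy_matrix(ng = 3L, n1 = 5L, n2 = 5L)
  # one candidate among 3 genes: exactly C(2,2) = 1 triplet
  trip <- suppressMessages(screen_triplets(m, "g01",
    screen_config(top_k = 10, bootstrap_B = 100, seed = 1)))
  expect_identical(nrow(trip), 1L)
  expect_identical(trip$x3, "g01")
  expect_true(trip$x1 < trip$x2)
  # no candidates: empty result, not an error
  expect_message(trip0 <- screen_triplets(m, character(0),
    screen_config(top_k = 10, bootstrap_B = 100)), "no candidate")
  expect_identical(nrow(trip0), 0L)
  expect_error(screen_triplets(m, "nope", screen_config()), "not in matrix")
})

test_that("screen agrees with exhaustive brute-force enumeration", {
  sim <- generate_synthetic(n_genes = 14, n_triplets = 1, n_de_only = 1,
                            n_bimodal_only = 1, n_per_group = 30, seed = 9)
  m <- sim$matrix
  cands <- c(sim$truth$planted_triplets$x3, "g10")
  cfg <- screen_config(top_k = 10000, screen_fraction = 1, bootstrap_B = 100,
                       seed = 4)
  trip <- screen_triplets(m, cands, cfg)
  # brute force: enumerate every candidate x pair, recompute rho and LA
  tv <- transform_matrix(m)$values
  n_pairs <- choose(nrow(tv) - 1L, 2L)
  expect_identical(nrow(trip), as.integer(2 * n_pairs))
  expect_identical(anyDuplicated(triplet_key(trip)), 0L)
  for (i in sample.int(nrow(trip), 25)) {
    x1 <- trip$x1[i]; x2 <- trip$x2[i]; x3 <- trip$x3[i]
    expect_true(x1 < x2 && x1 != x3 && x2 != x3)
    rd <- rhodiff(tv[x1, ], tv[x2, ], tv[x3, ])
    expect_equal(trip$rho_low[i], rd$rho_low, tolerance = 1e-12)
    expect_equal(trip$rho_high[i], rd$rho_high, tolerance = 1e-12)
    expect_equal(trip$la_value[i], la_statistic(tv[x1, ], tv[x2, ], tv[x3, ]),
                 tolerance = 1e-12)
    expect_equal(trip$p[i], wald_to_p(trip$wald[i]), tolerance = 1e-12)
    expect_equal(trip$bonferroni[i], min(1, trip$p[i] * nrow(trip)),
                 tolerance = 1e-12)
  }
  # ranked by p with deterministic tie-break
  expect_false(is.unsorted(trip$p))
  # the planted triplet tops the ranking
  expect_identical(triplet_key(trip)[1],
                   triplet_key(sim$truth$planted_triplets))
})

test_that("screen output is invariant to monotone per-gene transforms", {
  sim <- generate_synthetic(n_genes = 13, n_triplets = 1, n_de_only = 0,
                            n_bimodal_only = 0, n_per_group = 15, seed = 5)
  m <- sim$matrix
  cfg <- screen_config(top_k = 50, screen_fraction = 1, bootstrap_B = 100,
                       seed = 2)
  t1 <- screen_triplets(m, sim$truth$planted_triplets$x3, cfg)
  warped <- m$values
  set.seed(10)
  for (g in seq_len(nrow(warped))) {
    a <- runif(1, 0.5, 2); b <- runif(1, -1, 1)
    warped[g, ] <- exp(a * warped[g, ]) + b  # strictly monotone per gene
  }
  m2 <- expr_matrix(warped, m$groups)
  t2 <- screen_triplets(m2, sim$truth$planted_triplets$x3, cfg)
  expect_equal(t1, t2, tolerance = 1e-10, ignore_attr = TRUE)
})
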