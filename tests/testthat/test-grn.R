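test_that("mutual information matches histogram arithmetic on itself", {
  # y = x with n divisible by bins: diagonal joint, MI = ln(bins)
  x <- as.numeric(sample(1:100))
  expect_equal(mutual_information(x, x, bins = 10), log(10), tolerance = 1e-12)
  expect_equal(mutual_information(x, -x, bins = 10), log(10), tolerance = 1e-12)
})

test_that("mutual information is symmetric and near zero for independent data", {
  set.seed(31)
  x <- rnorm(200); y <- rnorm(200)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # plug-in MI carries a positive bias near (bins-1)^2/(2n); at a modest
  # bin count the independent-pair values stay small
  mis <- vapply(1:40, function(i)
    mutual_information(runif(1000), runif(1000), bins = 8), numeric(1))
  expect_gte(mean(mis < 0.05), 0.95)
  expect_true(all(mis >= 0))
  # at the default bin count the bias is larger but bounded by its theory
  mis_def <- vapply(1:20, function(i)
    mutual_information(runif(1000), runif(1000)), numeric(1))
  b <- ceiling(sqrt(1000))
  expect_true(all(mis_def < 2 * (b - 1)^2 / (2 * 1000)))
  expect_error(mutual_information(1:20, 1:21), "length mismatch")
  expect_error(mutual_information(1:5, 1:5), "at least 10")
})

test_that("the permutation threshold is seeded and calibrated", {
  sim <- generate_synthetic(n_genes = 30, n_triplets = 0, n_de_only = 0,
                            n_bimodal_only = 0, rho = 0, delta = 0, seed = 77)
  m <- sim$matrix
  t1 <- mi_threshold(m, n_perm = 200, alpha = 0.05, seed = 3)
  t2 <- mi_threshold(m, n_perm = 200, alpha = 0.05, seed = 3)
  expect_identical(t1, t2)
  expect_identical(mi_threshold(m, n_perm = 200, alpha = 1, seed = 3), 0)
  # null edge acceptance near alpha: fraction of independent-pair MIs
  # exceeding the threshold
  set.seed(4)
  null_mi <- vapply(1:300, function(i)
    mutual_information(rnorm(90), rnorm(90)), numeric(1))
  acc <- mean(null_mi > t1)
  expect_gt(acc, 0.005)
  expect_lt(acc, 0.15)
})

test_that("DPI removes the indirect edge of a Markov chain", {
  set.seed(41)
  n <- 2000
  x <- rnorm(n); y <- x + rnorm(n, sd = 0.5); z <- y + rnorm(n, sd = 0.5)
  vals <- rbind(gx = x, gy = y, gz = z)
  colnames(vals) <- sprintf("s%04d", 1:n)
  m <- expr_matrix(vals, setNames(rep(c("case", "control"), each = n / 2),
                                  colnames(vals)))
  net <- build_mi_network(m, threshold = 0)
  expect_identical(nrow(net$edges), 3L)  # full triangle before pruning
  pruned <- dpi_prune(net, epsilon = 0)
  expect_identical(nrow(pruned$edges), 2L)
  gone <- setdiff(paste(net$edges$gene_a, net$edges$gene_b),
                  paste(pruned$edges$gene_a, pruned$edges$gene_b))
  expect_identical(gone, "gx gz")
  # epsilon -> 1 removes nothing
  expect_identical(nrow(dpi_prune(net, epsilon = 0.999)$edges), 3L)
})

test_that("DPI tie rule, idempotence and subgraph property hold", {
  eq <- mi_network(c("a", "b", "c"),
                   data.frame(gene_a = c("a", "a", "b"),
                              gene_b = c("b", "c", "c"), mi = c(1, 1, 1)))
  expect_identical(nrow(dpi_prune(eq, epsilon = 0)$edges), 3L)  # strict min only
  set.seed(43)
  sim <- generate_synthetic(n_genes = 15, n_triplets = 0, n_de_only = 0,
                            n_bimodal_only = 0, rho = 0, delta = 0, seed = 8)
  net <- build_mi_network(sim$matrix, threshold = 0.1)
  p1 <- dpi_prune(net, epsilon = 0.1)
  p2 <- dpi_prune(p1, epsilon = 0.1)
  expect_identical(p1$edges, p2$edges)
  expect_true(all(paste(p1$edges$gene_a, p1$edges$gene_b) %in%
                    paste(net$edges$gene_a, net$edges$gene_b)))
})

test_that("a tree-structured network is recovered without triangles", {
  # balanced binary tree over 15 genes, child = 0.8*parent + noise
  set.seed(47)
  n <- 1000
  vals <- matrix(0, 15, n, dimnames = list(sprintf("g%02d", 1:15),
                                           sprintf("s%04d", 1:n)))
  vals[1, ] <- rnorm(n)
  true_edges <- character(0)
  for (child in 2:15) {
    parent <- child %/% 2
    vals[child, ] <- 0.8 * vals[parent, ] + rnorm(n, sd = 0.6)
    true_edges <- c(true_edges,
                    paste(sort(c(sprintf("g%02d", parent),
                                 sprintf("g%02d", child))), collapse = " "))
  }
  m <- expr_matrix(vals, setNames(rep(c("case", "control"), each = n / 2),
                                  colnames(vals)))
  thr <- mi_threshold(m, n_perm = 200, alpha = 0.05, seed = 5)
  net <- dpi_prune(build_mi_network(m, threshold = thr), epsilon = 0)
  got <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_gte(mean(true_edges %in% got), 0.9)
  # no triangles survive DPI at epsilon = 0
  adj <- matrix(FALSE, 15, 15, dimnames = list(rownames(vals), rownames(vals)))
  adj[cbind(net$edges$gene_a, net$edges$gene_b)] <- TRUE
  adj <- adj | t(adj)
  expect_equal(sum(diag(adj %*% adj %*% adj)), 0)
})

test_that("path support honours the intermediate budget with deterministic paths", {
  chain <- sprintf("n%02d", 1:11)  # x1 - 9 intermediates - x2
  net <- mi_network(chain,
                    data.frame(gene_a = chain[-11], gene_b = chain[-1],
                               mi = 1))
  s7 <- triplet_path_support(net, "n01", "n11", max_intermediates = 7)
  expect_false(s7$supported)
  s9 <- triplet_path_support(net, "n01", "n11", max_intermediates = 9)
  expect_true(s9$supported)
  expect_identical(s9$path, chain)
  expect_identical(s9$n_intermediates, 9L)
  # direct edge: zero intermediates
  d <- triplet_path_support(net, "n03", "n04")
  expect_true(d$supported)
  expect_identical(d$n_intermediates, 0L)
  # disconnected nodes are unsupported
  net2 <- mi_network(c(chain, "iso"),
                     data.frame(gene_a = chain[-11], gene_b = chain[-1],
                                mi = 1))
  expect_false(triplet_path_support(net2, "n01", "iso")$supported)
  # absent gene: unsupported with a log message
  expect_message(out <- triplet_path_support(net, "n01", "zz"), "absent")
  expect_false(out$supported)
  # lexicographic tie-break between equal-length paths
  diamond <- mi_network(c("a", "m1", "m2", "z"),
                        data.frame(gene_a = c("a", "a", "m1", "m2"),
                                   gene_b = c("m1", "m2", "z", "z"),
                                   mi = 1))
  expect_identical(triplet_path_support(diamond, "a", "z")$path,
                   c("a", "m1", "z"))
})

test_that("network constructor canonicalizes and validates edges", {
  net <- mi_network(c("b", "a", "c"),
                    data.frame(gene_a = "c", gene_b = "a", mi = 0.5))
  expect_identical(net$nodes, c("a", "b", "c"))
  expect_identical(net$edges$gene_a, "a")
  expect_identical(net$edges$gene_b, "c")
  expect_error(mi_network("a", data.frame(gene_a = "a", gene_b = "a", mi = 1)),
               "self-edges")
  expect_error(mi_network(c("a", "b"),
                          data.frame(gene_a = "a", gene_b = "b", mi = -1)),
               "negative")
})
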