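test_that("partial correlation matches its closed-form and residual oracles", {
  set.seed(7)
  # k = 2: nothing to control for -> plain Pearson
  x2 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(partial_correlation(x2)[1, 2], cor(x2)[1, 2], tolerance = 1e-12)
  # k = 3: recursion formula, 100 random datasets
  for (i in 1:100) {
    x <- matrix(rnorm(3 * 15), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
    expect_equal(unname(partial_correlation(x)), pcor_recursion_3(x),
                 tolerance = 1e-10)
  }
  # k up to 6: regression-residual oracle
  for (k in 3:6) {
    x <- matrix(rnorm(k * 30), 30, k,
                dimnames = list(NULL, paste0("v", 1:k)))
    expect_equal(unname(partial_correlation(x)), pcor_residuals(x),
                 tolerance = 1e-8)
  }
  expect_true(all(diag(partial_correlation(x2)) == 1))
})

test_that("degenerate similarity inputs raise informative errors", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  dup <- cbind(x, d = x[, "a"])
  expect_error(partial_correlation(dup), "singular")
  expect_error(partial_correlation(dup), "a ~ d")   # names the collinear pair
  xc <- x; xc[, 2] <- 5
  expect_error(partial_correlation(xc), "constant")
  expect_error(partial_correlation(t(x)), "observations")
})

test_that("the permutation null is reproducible and correctly shaped", {
  studies <- lapply(1:4, function(i)
    toy_study(sprintf("D%02d", i), genes = sprintf("g%02d", 1:40),
              n_per_arm = 5, seed = i))
  p <- reg_t_params(window = 5, confidence = 0)
  n1 <- permutation_null(studies, p, n_perm = 7, seed = 3)
  n2 <- permutation_null(studies, p, n_perm = 7, seed = 3)
  expect_identical(n1, n2)
  expect_equal(dim(n1$values), c(7L, choose(4, 2)))
  n3 <- permutation_null(studies, p, n_perm = 7, seed = 4)
  expect_false(identical(n1$values, n3$values))
  expect_error(permutation_null(studies, p, 5, 1, statistic = "bogus"),
               "statistic")
  # module statistic needs modules
  expect_error(permutation_null(studies, p, 5, 1,
                                statistic = "module-activity"),
               "modules")
  nm <- permutation_null(studies, p, 5, 1, statistic = "module-activity",
                         modules = list(m1 = c("g01", "g02", "g03")))
  expect_equal(dim(nm$values), c(5L, 1L, 4L))
})

test_that("pair p-values follow the exceedance definition", {
  ns <- structure(
    list(statistic = "pairwise-pcor",
         values = matrix(seq(-0.5, 0.5, length.out = 100), 10, 10),
         n_perm = 10, seed = 1, disease_ids = letters[1:2]),
    class = "perm_null"
  )
  pc <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  pv <- pair_pvalues(pc, ns)
  expect_equal(pv["a", "b"], 1 / 101)          # above every null value
  pc2 <- pc; pc2["a", "b"] <- pc2["b", "a"] <- -0.9
  expect_equal(pair_pvalues(pc2, ns)["a", "b"], 1)  # below every null value
  # raw variant can reach 0
  expect_equal(pair_pvalues(pc, ns, smooth = FALSE)["a", "b"], 0)
  # monotone decreasing in the observed correlation
  obs <- seq(-0.6, 0.6, by = 0.1)
  ps <- vapply(obs, function(v) {
    m <- matrix(c(1, v, v, 1), 2, 2, dimnames = dimnames(pc))
    pair_pvalues(m, ns)["a", "b"]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # exact count check against a brute-force sum
  v <- 0.12
  m <- matrix(c(1, v, v, 1), 2, 2, dimnames = dimnames(pc))
  expect_equal(pair_pvalues(m, ns)["a", "b"],
               (1 + sum(ns$values >= v)) / (length(ns$values) + 1))
})

test_that("complete linkage agrees with hclust on random instances", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    d <- matrix(runif(n * n), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
    link <- dganet:::complete_linkage(d)
    h <- hclust(as.dist(d), method = "complete")
    expect_equal(link$height, h$height, tolerance = 1e-12)
    expect_true(all(diff(link$height) >= -1e-12))  # monotone heights
    # partitions agree at a random cut
    cut <- runif(1, min(h$height), max(h$height))
    mine <- dganet:::cut_linkage(link, rownames(d), cut)
    ref <- cutree(h, h = cut - 1e-12)
    expect_equal(adjusted_rand_index(mine$cluster, ref), 1)
  }
})

test_that("disease clustering recovers block structure and respects alpha", {
  # two blocks of mutually perfectly-correlated diseases
  pc <- diag(6)
  pc[1:3, 1:3] <- 1
  pc[4:6, 4:6] <- 1
  dimnames(pc) <- list(paste0("D", 1:6), paste0("D", 1:6))
  ns <- structure(
    list(statistic = "pairwise-pcor",
         values = matrix(rnorm(1000, sd = 0.1), 100, 10),
         n_perm = 100, seed = 1, disease_ids = paste0("D", 1:6)),
    class = "perm_null"
  )
  cl <- cluster_diseases(pc, ns, alpha = 0.05)
  expect_equal(length(unique(cl$clusters$cluster)), 2L)
  expect_true(all(cl$clusters$clustered))
  expect_equal(cl$clusters$cluster[1], cl$clusters$cluster[2])
  expect_false(cl$clusters$cluster[1] == cl$clusters$cluster[4])
  expect_error(cluster_diseases(pc, ns, alpha = 0), "alpha")
  # shrinking alpha never merges more: cluster count is non-decreasing
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  counts <- vapply(alphas, function(a)
    length(unique(cluster_diseases(pc, ns, a)$clusters$cluster)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("significant pairs and tidiers expose the similarity result", {
  cfg <- synthetic_config(n_diseases = 5, cluster_partition = list(1:2),
                          n_genes = 200, effect_genes_per_cluster = 30,
                          shared_effect_genes = 0, seed = 31)
  studies <- generate_compendium(cfg)$studies
  res <- disease_similarity(studies, reg_t_params(), n_perm = 40,
                            alpha = 0.05, seed = 2)
  td <- tidy(res)
  expect_equal(nrow(td), choose(5, 2))
  expect_true(all(td$p_value > 0 & td$p_value <= 1))
  gl <- glance(res)
  expect_equal(gl$n_significant, sum(td$significant))
  sp <- significant_pairs(res)
  expect_true(all(sp$p_value < 0.05))
  # the planted pair is the top association
  expect_setequal(c(sp$disease_a[1], sp$disease_b[1]), c("D01", "D02"))
  # pcor invariants
  expect_equal(res$pcor, t(res$pcor))
  expect_true(all(res$pcor >= -1 - 1e-9 & res$pcor <= 1 + 1e-9))
})
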