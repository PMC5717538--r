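edge_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("edge loading applies the strict score filter and dedup rules", {
  f <- edge_file(c("a\tb\t0.84", "a\tc\t0.86", "b\ta\t0.90",
                   "c\td\t0.95", "d\tc\t0.91", "e\te\t0.99"))
  net <- load_edges(f, threshold = 0.85)
  # 0.84 dropped (strict >), self-loop e-e dropped, c-d deduped to max
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$edges$score[net$edges$node1 == "c"], 0.95)
  expect_equal(net$edges$score[net$edges$node1 == "a" &
                                 net$edges$node2 == "b"], 0.90)
  expect_setequal(net$nodes, c("a", "b", "c", "d"))
  # 0-1000 scale auto-detection
  f2 <- edge_file(c("protein1\tprotein2\tcombined_score",
                    "a\tb\t900", "a\tc\t840"))
  net2 <- load_edges(f2, threshold = 0.85)
  expect_equal(net2$edges$score, 0.9)
  expect_equal(nrow(net2$edges), 1L)
  # malformed rows carry the line number
  expect_error(load_edges(edge_file(c("a\tb\t0.9", "broken"))), "line 2")
  expect_error(load_edges(edge_file(c("a\tb\tnot_a_number"))), "line 1")
  expect_error(load_edges(edge_file("a\tb\t0.2")), "no edges")
})

test_that("MCL resolves obvious cluster structure exactly", {
  tri2 <- tibble::tibble(
    node1 = c("a", "a", "b", "x", "x", "y"),
    node2 = c("b", "c", "c", "y", "z", "z"),
    score = 0.9
  )
  ms <- mcl_cluster(as_protein_network(tri2, 0.85))
  expect_length(ms$modules, 2L)
  expect_setequal(ms$modules[[1]], c("a", "b", "c"))
  expect_setequal(ms$modules[[2]], c("x", "y", "z"))
  expect_true(ms$converged)
  # a single clique is a single module
  cl5 <- t(combn(letters[1:5], 2))
  ms5 <- mcl_cluster(as_protein_network(
    tibble::tibble(node1 = cl5[, 1], node2 = cl5[, 2], score = 0.9), 0.85))
  expect_length(ms5$modules, 1L)
  expect_setequal(ms5$modules[[1]], letters[1:5])
})

test_that("MCL output is always a partition of the node set", {
  for (seed in 1:5) {
    cfg <- synthetic_config(n_diseases = 2, cluster_partition = list(1:2),
                            n_genes = 200, effect_genes_per_cluster = 15,
                            shared_effect_genes = 0,
                            network_n_nodes = 40,
                            network_module_sizes = c(12, 12),
                            p_within = 0.8, p_between = 0.1, seed = seed)
    truth <- generate_compendium(cfg)$truth
    net <- generate_network(cfg, truth)
    ms <- mcl_cluster(as_protein_network(net$edges, 0.85))
    assigned <- unlist(ms$modules)
    pn <- as_protein_network(net$edges, 0.85)
    expect_setequal(assigned, pn$nodes)
    expect_equal(anyDuplicated(assigned), 0L)
  }
})

test_that("module filtering enforces universe overlap and minimum size", {
  ms <- structure(
    list(modules = list(M1 = c("a", "b"), M2 = c("c", "d", "e"),
                        M3 = c("f", "g", "h"), M4 = c("i", "j", "k", "l"),
                        M5 = "m"),
         provenance = "mcl"),
    class = "module_set"
  )
  universe <- letters[1:13]
  out <- filter_modules(ms, universe, min_size = 3)
  expect_length(out$modules, 3L)
  expect_equal(attr(out, "n_original"), 5L)
  expect_equal(attr(out, "n_surviving"), 3L)
  # a module with a gene off the universe can fall under min_size
  out2 <- filter_modules(ms, setdiff(universe, "f"), min_size = 3)
  expect_false("M3" %in% names(out2$modules))
  # fully-covered size-3 module is retained
  expect_true("M2" %in% names(out2$modules))
})

test_that("module activity is the exact mean of member DGA scores", {
  dga <- structure(
    matrix(c(1, 2, 3, 0, 0, 0), 3, 2,
           dimnames = list(c("a", "b", "c"), c("d1", "d2"))),
    class = c("dga_matrix", "matrix", "array")
  )
  ms <- structure(list(modules = list(M1 = c("a", "b", "c")),
                       provenance = "mcl"),
                  class = "module_set")
  nullv <- array(0, c(5, 1, 2), dimnames = list(NULL, "M1", c("d1", "d2")))
  act <- module_activity(ms, dga, fake_module_null(nullv, "M1", c("d1", "d2")))
  expect_equal(unname(act$activity["M1", "d1"]), 2.0)
  expect_equal(unname(act$activity["M1", "d2"]), 0.0)
  # all-zero column: |null| >= |obs| always -> p = 1
  expect_equal(unname(act$pvals["M1", "d2"]), 1)
  # p-value follows the matched exceedance rule
  nullv2 <- array(c(1, 1.5, 2.5, 3, 0.5, rep(0, 5)), c(5, 1, 2),
                  dimnames = list(NULL, "M1", c("d1", "d2")))
  act2 <- module_activity(ms, dga, fake_module_null(nullv2, "M1", c("d1", "d2")))
  expect_equal(unname(act2$pvals["M1", "d1"]), (1 + 2) / 6)
  # unfiltered empty module is an error
  ms_bad <- structure(list(modules = list(M1 = "zz"), provenance = "mcl"),
                      class = "module_set")
  expect_error(module_activity(ms_bad, dga), "empty")
})

test_that("signature extraction applies the strict-majority and median rules", {
  mk_activity <- function(act, pv) {
    structure(list(activity = act, pvals = pv,
                   module_genes = setNames(vector("list", nrow(act)),
                                           rownames(act)),
                   provenance = "mcl"),
              class = "activity_matrix")
  }
  D <- 4
  act <- matrix(rep(c(1, 2, 3, 4, 9), each = D), 5, D, byrow = TRUE,
                dimnames = list(paste0("M", 1:5), paste0("d", 1:D)))
  pv <- matrix(0.01, 5, D, dimnames = dimnames(act))
  pv["M5", ] <- c(0.01, 0.01, 0.5, 0.5)   # significant in exactly D/2 -> out
  sig <- signature_modules(mk_activity(act, pv), alpha = 0.05)
  expect_setequal(sig$stage1, paste0("M", 1:4))   # strict majority only
  expect_equal(sig$expression_threshold, 2.5)     # median of 1,2,3,4
  expect_setequal(sig$signature, c("M3", "M4"))   # >= threshold
  # all summaries identical: every stage-1 module passes (>= comparison)
  act2 <- matrix(1, 3, D, dimnames = list(paste0("M", 1:3), paste0("d", 1:D)))
  pv2 <- matrix(0.01, 3, D, dimnames = dimnames(act2))
  sig2 <- signature_modules(mk_activity(act2, pv2))
  expect_setequal(sig2$signature, sig2$stage1)
  # |signature| >= ceil(|stage1| / 2) under the median rule
  expect_gte(length(sig$signature), ceiling(length(sig$stage1) / 2))
  # nothing significant -> empty with a warning
  pv3 <- matrix(0.9, 3, D, dimnames = dimnames(act2))
  expect_warning(s3 <- signature_modules(mk_activity(act2, pv3)), "majority")
  expect_length(s3$signature, 0L)
})

test_that("planted network modules light up in the diseases that carry them", {
  # one module aligned with the cluster program: significant activity in
  # the cluster diseases, null elsewhere (single-seed smoke version of the
  # power analysis in the acceptance suite)
  cfg <- synthetic_config(n_diseases = 4, cluster_partition = list(1:2),
                          n_genes = 300, effect_genes_per_cluster = 20,
                          shared_effect_genes = 0, effect_size = 2,
                          network_n_nodes = 30,
                          network_module_sizes = c(10, 10), seed = 17)
  comp <- generate_compendium(cfg)
  net <- generate_network(cfg, comp$truth)
  ig <- intersect_genes(lapply(comp$studies, ztransform))
  dga <- dga_matrix(ig$studies)
  ms <- structure(list(modules = net$truth$planted_modules,
                       provenance = "mcl"),
                  class = "module_set")
  nl <- permutation_null(ig$studies, reg_t_params(), n_perm = 60, seed = 5,
                         statistic = "module-activity",
                         modules = ms$modules)
  act <- module_activity(ms, dga, nl)
  expect_lt(act$pvals["planted_1", "D01"], 0.05)
  expect_lt(act$pvals["planted_1", "D02"], 0.05)
  expect_gt(min(act$pvals["planted_1", c("D03", "D04")]), 0.05)
})
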