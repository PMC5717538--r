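test_that("generators are pure functions of (config, seed)", {
  cfg <- synthetic_config(n_diseases = 4, cluster_partition = list(1:2),
                          n_genes = 120, effect_genes_per_cluster = 10,
                          shared_effect_genes = 5, network_n_nodes = 30,
                          network_module_sizes = c(8, 8), seed = 99)
  a <- generate_compendium(cfg)
  b <- generate_compendium(cfg)
  expect_identical(a, b)
  na <- generate_network(cfg, a$truth)
  nb <- generate_network(cfg, b$truth)
  expect_identical(na$edges, nb$edges)
  aa <- generate_annotations(cfg, na$truth)
  ab <- generate_annotations(cfg, nb$truth)
  expect_identical(aa[c("disease_genes", "functional_modules", "drug_table")],
                   ab[c("disease_genes", "functional_modules", "drug_table")])
  # different seed changes the draw
  cfg2 <- synthetic_config(n_diseases = 4, cluster_partition = list(1:2),
                           n_genes = 120, effect_genes_per_cluster = 10,
                           shared_effect_genes = 5, network_n_nodes = 30,
                           network_module_sizes = c(8, 8), seed = 100)
  expect_false(identical(generate_compendium(cfg2)$studies[[1]]$values,
                         a$studies[[1]]$values))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(cluster_partition = list(1:3, 3:5)),
               "disjoint")
  expect_error(synthetic_config(n_genes = 30, effect_genes_per_cluster = 40),
               "effect_genes_per_cluster")
  expect_error(synthetic_config(network_n_nodes = 10,
                                network_module_sizes = c(8, 8)),
               "exceeds")
  expect_error(synthetic_config(samples_per_arm = 0), "positive")
  expect_error(synthetic_config(edge_score_range = c(0, 1.5)),
               "edge_score_range")
  cfg <- synthetic_config(n_diseases = 4, cluster_partition = list(1:2),
                          n_genes = 200, seed = 1)
  truth <- generate_compendium(cfg)$truth
  expect_error(generate_annotations(cfg, truth, overlap_fraction = 1.2),
               "overlap_fraction")
})

test_that("planted truth satisfies its invariants", {
  cfg <- synthetic_config(n_diseases = 6, cluster_partition = list(1:2, 3:4),
                          n_genes = 300, effect_genes_per_cluster = 20,
                          shared_effect_genes = 10, network_n_nodes = 40,
                          network_module_sizes = c(10, 10), seed = 5)
  comp <- generate_compendium(cfg)
  truth <- comp$truth
  # programs disjoint: every effect gene in exactly one program
  all_eff <- unlist(lapply(truth$effect_gene_sets, `[[`, "gene"))
  expect_equal(anyDuplicated(all_eff), 0L)
  # one coherent sign per program
  for (s in truth$effect_gene_sets) expect_length(unique(s$sign), 1L)
  # cluster labels cover all diseases, clusters as configured
  expect_equal(sum(truth$cluster_labels$cluster_id == "C1"), 2L)
  expect_equal(sum(grepl("^solo", truth$cluster_labels$cluster_id)), 2L)
  # planted network modules disjoint and aligned with programs
  net <- generate_network(cfg, truth)
  mods <- net$truth$planted_modules
  expect_equal(anyDuplicated(unlist(mods)), 0L)
  expect_true(all(mods[[1]] %in% truth$effect_gene_sets[["shared"]]$gene))
  expect_true(all(mods[[2]] %in% truth$effect_gene_sets[["C1"]]$gene))
  # studies: arms sized as configured, batch labels present
  s <- comp$studies[[1]]
  expect_equal(unname(table(s$samples$arm)["disease"]), cfg$samples_per_arm)
  expect_equal(nrow(s$values), cfg$n_genes)
})

test_that("edge probabilities 0/1 give deterministic graph structure", {
  cfg <- synthetic_config(n_diseases = 2, cluster_partition = list(),
                          n_genes = 100, effect_genes_per_cluster = 5,
                          shared_effect_genes = 0,
                          network_n_nodes = 8, network_module_sizes = c(4, 4),
                          p_within = 1, p_between = 0, seed = 3)
  truth <- generate_compendium(cfg)$truth
  net <- generate_network(cfg, truth)
  # exactly two disjoint 4-cliques
  expect_equal(nrow(net$edges), 2 * choose(4, 2))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 2L)
  expect_equal(sort(comp$csize), c(4L, 4L))
  expect_true(all(net$edges$score >= cfg$edge_score_range[1] &
                    net$edges$score <= cfg$edge_score_range[2]))
  # p_between = 1 connects everything
  cfg2 <- synthetic_config(n_diseases = 2, cluster_partition = list(),
                           n_genes = 100, effect_genes_per_cluster = 5,
                           shared_effect_genes = 0,
                           network_n_nodes = 8, network_module_sizes = c(4, 4),
                           p_within = 1, p_between = 1, seed = 3)
  net2 <- generate_network(cfg2, truth)
  g2 <- igraph::graph_from_data_frame(net2$edges, directed = FALSE)
  expect_equal(igraph::components(g2)$no, 1L)
})

test_that("annotation overlap fractions control pairwise gene sharing", {
  cfg <- synthetic_config(n_diseases = 4, cluster_partition = list(1:2, 3:4),
                          n_genes = 400, effect_genes_per_cluster = 30,
                          shared_effect_genes = 0,
                          genes_per_disease_list = 20, seed = 8)
  truth <- generate_compendium(cfg)$truth
  # full overlap: intra-cluster lists identical -> minimal achievable p
  ann1 <- generate_annotations(cfg, truth, overlap_fraction = 1)
  l <- ann1$disease_genes
  expect_identical(l$D01, l$D02)
  h <- hypergeom_overlap(l$D01, l$D02, ann1$universe)
  p_min <- stats::phyper(length(l$D01) - 1, length(l$D01),
                         length(ann1$universe) - length(l$D01),
                         length(l$D02), lower.tail = FALSE)
  expect_equal(h$p_value, p_min)
  expect_equal(h$overlap, 20L)
  # zero overlap fraction: all pairwise overlaps are empty
  ann0 <- generate_annotations(cfg, truth, overlap_fraction = 0)
  tab <- pairwise_overlap_table(ann0$disease_genes, ann0$universe)
  expect_true(all(tab$overlap == 0))
  expect_true(all(tab$p_value == 1))
  # inter-cluster pairs never share genes at any fraction
  tab1 <- pairwise_overlap_table(ann1$disease_genes, ann1$universe)
  inter <- tab1$disease_a %in% c("D01", "D02") &
    tab1$disease_b %in% c("D03", "D04")
  expect_true(all(tab1$overlap[inter] == 0))
})

test_that("drug targets planted in modules are flagged as over-represented", {
  cfg <- synthetic_config(n_diseases = 2, cluster_partition = list(1:2),
                          n_genes = 200, effect_genes_per_cluster = 20,
                          shared_effect_genes = 0,
                          network_n_nodes = 30, network_module_sizes = c(10, 10),
                          n_drugs = 20, targets_per_drug = 3, seed = 21)
  comp <- generate_compendium(cfg)
  net <- generate_network(cfg, comp$truth)
  ann <- generate_annotations(cfg, net$truth, drug_target_pool = "modules")
  module_genes <- unlist(net$truth$planted_modules)
  expect_true(all(ann$drug_table$gene %in% module_genes))
  res <- druggable_overrep(module_genes, ann$truth$druggable_genes,
                           ann$universe)
  # cross-check against the direct hypergeometric computation
  k <- length(intersect(module_genes, ann$truth$druggable_genes))
  expect_equal(res$overlap, k)
  expect_equal(res$p_value,
               stats::phyper(k - 1, length(unique(module_genes)),
                             length(ann$universe) - length(unique(module_genes)),
                             length(ann$truth$druggable_genes),
                             lower.tail = FALSE))
  expect_lt(res$p_value, 0.05)
})

test_that("null worlds produce t statistics from the null distribution", {
  # effect_size = 0, one batch: the gene-wise statistic (no shrinkage at
  # n = 10 per arm with the default confidence) is Student-t with
  # n1 + n2 - 2 df under equal variances
  cfg <- synthetic_config(n_diseases = 1, cluster_partition = list(),
                          n_genes = 10000, effect_genes_per_cluster = 1,
                          shared_effect_genes = 0, effect_size = 0,
                          samples_per_arm = 10, seed = 77)
  comp <- generate_compendium(cfg)
  dga <- dga_matrix(comp$studies)
  ks <- stats::ks.test(as.vector(unclass(dga)), stats::pt, df = 18)
  expect_gt(ks$p.value, 0.01)
})
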