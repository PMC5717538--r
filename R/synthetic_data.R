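#' Configuration for the synthetic compendium generator
#'
#' Describes a multi-disease case/control expression world with known
#' ground truth: groups of diseases ("clusters") share a signed
#' differential program on a planted set of effect genes, an interaction
#' network carries planted modules aligned with those programs, and
#' annotation tables (disease genes, functional-module gene sets, a
#' drug-target table) are derived from the same truth. Every generator is
#' a pure function of (config, seed).
#'
#' @param n_diseases number of diseases.
#' @param cluster_partition list of disjoint integer vectors of disease
#'   indices; diseases not covered receive their own independent effect
#'   genes (true-negative pairs). The default emulates a 20-disease
#'   compendium with seven planted clusters.
#' @param n_genes genes in the expression universe.
#' @param samples_per_arm samples per disease per arm (disease/control).
#' @param n_batches_per_disease batches each disease's samples are split
#'   over; each batch contains both arms.
#' @param effect_size standardized mean shift (z-units) applied to effect
#'   genes in the disease arm.
#' @param effect_genes_per_cluster effect genes planted per cluster (and
#'   per unclustered disease).
#' @param shared_effect_genes size of an additional "common program": a
#'   signed effect-gene set applied to the disease arm of every disease,
#'   emulating a cross-disease signature; 0 disables it.
#' @param noise_sd residual noise standard deviation (z-units).
#' @param batch_sd standard deviation of additive per-batch per-gene
#'   offsets.
#' @param network_n_nodes,network_module_sizes node count and planted
#'   module sizes for the interaction network.
#' @param p_within,p_between edge probabilities inside / between planted
#'   modules; recoverable modules need `p_within > p_between`.
#' @param edge_score_range length-2 numeric in (0, 1]; edge confidence
#'   scores are drawn uniformly from it.
#' @param n_drugs,targets_per_drug drug-table dimensions.
#' @param genes_per_disease_list size of each disease-gene list.
#' @param cluster_gene_overlap fraction in \[0, 1\] of each list shared by
#'   all members of a cluster.
#' @param n_functional_modules gene sets in the synthetic functional-module
#'   catalog (first sets mirror the planted cluster programs).
#' @param seed integer master seed; stage generators derive child seeds
#'   from it, so each stage is reproducible in isolation.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_diseases = 20,
                             cluster_partition = list(1:4, 5:6, 7:8, 9:10,
                                                      11:12, 13:14, 15:16),
                             n_genes = 500,
                             samples_per_arm = 10,
                             n_batches_per_disease = 1,
                             effect_size = 2,
                             effect_genes_per_cluster = 20,
                             shared_effect_genes = 15,
                             noise_sd = 1,
                             batch_sd = 0.5,
                             network_n_nodes = 60,
                             network_module_sizes = c(10, 10, 10),
                             p_within = 0.9,
                             p_between = 0.05,
                             edge_score_range = c(0.86, 1),
                             n_drugs = 20,
                             targets_per_drug = 3,
                             genes_per_disease_list = 30,
                             cluster_gene_overlap = 0.8,
                             n_functional_modules = 23,
                             seed = 1L) {
  cfg <- list(
    n_diseases = n_diseases, cluster_partition = cluster_partition,
    n_genes = n_genes, samples_per_arm = samples_per_arm,
    n_batches_per_disease = n_batches_per_disease,
    effect_size = effect_size,
    effect_genes_per_cluster = effect_genes_per_cluster,
    shared_effect_genes = shared_effect_genes,
    noise_sd = noise_sd, batch_sd = batch_sd,
    network_n_nodes = network_n_nodes,
    network_module_sizes = network_module_sizes,
    p_within = p_within, p_between = p_between,
    edge_score_range = edge_score_range,
    n_drugs = n_drugs, targets_per_drug = targets_per_drug,
    genes_per_disease_list = genes_per_disease_list,
    cluster_gene_overlap = cluster_gene_overlap,
    n_functional_modules = n_functional_modules,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_diseases, cfg$n_genes, cfg$samples_per_arm,
              cfg$n_batches_per_disease, cfg$effect_genes_per_cluster,
              cfg$network_n_nodes, cfg$n_drugs, cfg$targets_per_drug,
              cfg$genes_per_disease_list)
  if (any(counts < 1)) abort_dganet("all counts must be positive", "bad_config")
  idx <- unlist(cfg$cluster_partition)
  if (length(idx) != length(unique(idx)))
    abort_dganet("cluster_partition blocks must be disjoint", "bad_config")
  if (length(idx) > 0 && (max(idx) > cfg$n_diseases || min(idx) < 1))
    abort_dganet("cluster_partition indexes outside 1..n_diseases", "bad_config")
  if (cfg$effect_genes_per_cluster > cfg$n_genes)
    abort_dganet("effect_genes_per_cluster exceeds n_genes", "bad_config")
  n_programs <- length(cfg$cluster_partition) +
    (cfg$n_diseases - length(idx))
  if (cfg$shared_effect_genes < 0)
    abort_dganet("shared_effect_genes must be >= 0", "bad_config")
  if (n_programs * cfg$effect_genes_per_cluster + cfg$shared_effect_genes >
      cfg$n_genes)
    abort_dganet("not enough genes for disjoint effect programs", "bad_config")
  if (cfg$p_within < 0 || cfg$p_within > 1 ||
      cfg$p_between < 0 || cfg$p_between > 1)
    abort_dganet("edge probabilities must lie in [0,1]", "bad_config")
  if (length(cfg$edge_score_range) != 2 ||
      cfg$edge_score_range[1] <= 0 || cfg$edge_score_range[2] > 1 ||
      diff(cfg$edge_score_range) < 0)
    abort_dganet("edge_score_range must be [low, high] within (0,1]", "bad_config")
  if (sum(cfg$network_module_sizes) > cfg$network_n_nodes)
    abort_dganet("network_module_sizes sum exceeds network_n_nodes", "bad_config")
  if (cfg$cluster_gene_overlap < 0 || cfg$cluster_gene_overlap > 1)
    abort_dganet("cluster_gene_overlap must lie in [0,1]", "bad_config")
  invisible(cfg)
}

gene_ids_for <- function(n) sprintf("g%0*d", nchar(n), seq_len(n))
disease_ids_for <- function(n) sprintf("D%02d", seq_len(n))

# Assigns disjoint signed effect-gene programs: one per cluster, one per
# unclustered disease. Pure given the current RNG state.
plant_programs <- function(cfg) {
  genes <- gene_ids_for(cfg$n_genes)
  diseases <- disease_ids_for(cfg$n_diseases)
  clustered <- unlist(cfg$cluster_partition)
  labels <- tibble::tibble(
    disease_id = diseases,
    cluster_id = NA_character_
  )
  for (k in seq_along(cfg$cluster_partition)) {
    labels$cluster_id[cfg$cluster_partition[[k]]] <- sprintf("C%d", k)
  }
  solo <- setdiff(seq_len(cfg$n_diseases), clustered)
  labels$cluster_id[solo] <- paste0("solo_", diseases[solo])

  programs <- unique(labels$cluster_id)
  pool <- sample(genes)
  sets <- list()
  # one coherent direction per program (whole gene set up or down), drawn
  # at random so two-sided statistics are exercised across programs
  draw <- function(k) {
    take <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    tibble::tibble(gene = sort(take),
                   sign = rep(sample(c(-1, 1), 1), length(take)))
  }
  if (cfg$shared_effect_genes > 0) sets[["shared"]] <- draw(cfg$shared_effect_genes)
  for (p in programs) sets[[p]] <- draw(cfg$effect_genes_per_cluster)
  list(genes = genes, labels = labels, effect_gene_sets = sets)
}

#' Generate a synthetic multi-disease expression compendium
#'
#' Draws one case/control study per disease. Disease arms of clustered
#' diseases share their cluster's signed mean shift on its effect genes;
#' control arms come from the noise model alone; additive per-batch
#' offsets are superimposed on both arms.
#'
#' @param config a [synthetic_config()].
#' @return list with `studies` (list of [expression_study()], one per
#'   disease) and `truth` (a `planted_truth` object carrying cluster
#'   labels and signed effect-gene sets).
#' @export
generate_compendium <- function(config) {
  validate_synthetic_config(config)
  out <- withr::with_seed(child_seed(config$seed, 1L), {
    plan <- plant_programs(config)
    n_s <- 2L * config$samples_per_arm
    studies <- vector("list", config$n_diseases)
    for (d in seq_len(config$n_diseases)) {
      did <- plan$labels$disease_id[d]
      prog <- plan$effect_gene_sets[[plan$labels$cluster_id[d]]]
      vals <- matrix(stats::rnorm(config$n_genes * n_s, sd = config$noise_sd),
                     nrow = config$n_genes,
                     dimnames = list(plan$genes,
                                     sprintf("%s_s%02d", did, seq_len(n_s))))
      arms <- rep(c("disease", "control"), each = config$samples_per_arm)
      vals[prog$gene, arms == "disease"] <-
        vals[prog$gene, arms == "disease"] + config$effect_size * prog$sign
      shared <- plan$effect_gene_sets[["shared"]]
      if (!is.null(shared)) {
        vals[shared$gene, arms == "disease"] <-
          vals[shared$gene, arms == "disease"] +
          config$effect_size * shared$sign
      }
      batch <- sprintf("b%d",
                       rep_len(seq_len(config$n_batches_per_disease),
                               config$samples_per_arm))
      batch <- c(batch, batch) # same layout in both arms
      for (b in unique(batch)) {
        offset <- stats::rnorm(config$n_genes, sd = config$batch_sd)
        vals[, batch == b] <- vals[, batch == b] + offset
      }
      studies[[d]] <- expression_study(
        did, vals,
        tibble::tibble(sample_id = colnames(vals), arm = arms, batch = batch)
      )
    }
    truth <- structure(
      list(cluster_labels = plan$labels,
           effect_gene_sets = plan$effect_gene_sets,
           planted_modules = NULL,
           druggable_genes = NULL,
           drug_targets = NULL),
      class = "planted_truth"
    )
    list(studies = studies, truth = truth)
  })
  out
}

#' Generate a planted-partition interaction network
#'
#' Planted modules are aligned with the compendium's effect-gene programs:
#' module *k* draws its nodes from cluster *k*'s effect genes (so module
#' activity scoring can find the planted dysregulation); extra modules and
#' background nodes use genes outside any program. Node pairs inside a
#' module are connected with probability `p_within`, all other pairs with
#' `p_between`; retained edges get confidence scores drawn uniformly from
#' `edge_score_range`.
#'
#' @param config a [synthetic_config()].
#' @param truth the `planted_truth` from [generate_compendium()].
#' @return list with `edges` (tibble `node1`, `node2`, `score`) and
#'   `truth` updated with `planted_modules`.
#' @export
generate_network <- function(config, truth) {
  validate_synthetic_config(config)
  sizes <- config$network_module_sizes
  withr::with_seed(child_seed(config$seed, 2L), {
    programs <- c(intersect("shared", names(truth$effect_gene_sets)),
                  grep("^C", names(truth$effect_gene_sets), value = TRUE))
    effect_pool <- lapply(truth$effect_gene_sets[programs], `[[`, "gene")
    free <- setdiff(gene_ids_for(config$n_genes),
                    unlist(lapply(truth$effect_gene_sets, `[[`, "gene")))
    free <- sample(free)
    modules <- list()
    for (k in seq_along(sizes)) {
      if (k <= length(effect_pool) && length(effect_pool[[k]]) >= sizes[k]) {
        modules[[k]] <- sort(sample(effect_pool[[k]], sizes[k]))
      } else {
        modules[[k]] <- sort(free[seq_len(sizes[k])])
        free <- free[-seq_len(sizes[k])]
      }
    }
    names(modules) <- sprintf("planted_%d", seq_along(modules))
    n_bg <- config$network_n_nodes - sum(sizes)
    background <- if (n_bg > 0) free[seq_len(n_bg)] else character(0)
    nodes <- c(unlist(modules), background)
    membership <- c(rep(seq_along(sizes), sizes), rep(0L, n_bg))

    n <- length(nodes)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- membership[pairs[, 1]] == membership[pairs[, 2]] &
      membership[pairs[, 1]] != 0L
    p <- ifelse(same, config$p_within, config$p_between)
    keep <- stats::runif(nrow(pairs)) < p
    i <- pairs[keep, 1]; j <- pairs[keep, 2]
    edges <- tibble::tibble(
      node1 = nodes[i], node2 = nodes[j],
      score = stats::runif(sum(keep),
                           config$edge_score_range[1],
                           config$edge_score_range[2])
    ) |>
      dplyr::arrange(.data$node1, .data$node2)
    truth$planted_modules <- modules
    list(edges = edges, truth = truth)
  })
}

#' Generate annotation tables aligned with the planted truth
#'
#' Builds (i) disease-gene lists in which members of one planted cluster
#' share a fixed "core" of genes (the configured overlap fraction of each
#' list, drawn from the cluster's effect genes where possible) while all
#' remaining list genes are disease-private, so intra-cluster overlap is
#' exactly the core size and inter-cluster overlap is 0; (ii) a
#' functional-module catalog whose first sets mirror the planted cluster
#' programs and whose remaining sets are null (drawn off the effect
#' genes); (iii) a drug-target table with an approval flag.
#'
#' @param config a [synthetic_config()].
#' @param truth a `planted_truth` (from [generate_compendium()], and
#'   through [generate_network()] if drug targets should be drawn from
#'   planted module genes).
#' @param overlap_fraction fraction in \[0, 1\] of each disease-gene list
#'   shared within a cluster; defaults to `config$cluster_gene_overlap`.
#' @param drug_target_pool `"all"` (targets drawn from the whole gene
#'   universe) or `"modules"` (targets drawn from planted module genes).
#' @return list with `disease_genes` (named list of gene vectors),
#'   `universe`, `functional_modules` (named list of gene vectors),
#'   `drug_table` (tibble `drug_id`, `gene`, `approved`), and updated
#'   `truth`.
#' @export
generate_annotations <- function(config, truth,
                                 overlap_fraction = config$cluster_gene_overlap,
                                 drug_target_pool = c("all", "modules")) {
  validate_synthetic_config(config)
  drug_target_pool <- match.arg(drug_target_pool)
  if (overlap_fraction < 0 || overlap_fraction > 1)
    abort_dganet("overlap_fraction must lie in [0,1]", "bad_config")
  withr::with_seed(child_seed(config$seed, 3L), {
    genes <- gene_ids_for(config$n_genes)
    labels <- truth$cluster_labels
    L <- config$genes_per_disease_list
    core_n <- round(overlap_fraction * L)
    effect_genes <- unlist(lapply(truth$effect_gene_sets, `[[`, "gene"))
    free <- sample(setdiff(genes, effect_genes))

    take_free <- function(k) {
      if (k == 0) return(character(0))
      if (k > length(free)) abort_dganet("gene universe too small for lists", "bad_config")
      out <- free[seq_len(k)]
      free <<- free[-seq_len(k)]
      out
    }
    cores <- list()
    for (cl in unique(labels$cluster_id)) {
      eff <- truth$effect_gene_sets[[cl]]$gene
      n_eff <- min(core_n, length(eff))
      cores[[cl]] <- c(sample(eff, n_eff), take_free(core_n - n_eff))
    }
    disease_genes <- list()
    for (d in seq_len(nrow(labels))) {
      cl <- labels$cluster_id[d]
      disease_genes[[labels$disease_id[d]]] <-
        sort(c(cores[[cl]], take_free(L - core_n)))
    }

    fm_size <- min(15L, config$effect_genes_per_cluster)
    fms <- list()
    programs <- names(truth$effect_gene_sets)
    for (i in seq_len(config$n_functional_modules)) {
      fms[[sprintf("FM%02d", i)]] <- if (i <= length(programs)) {
        eff <- truth$effect_gene_sets[[programs[i]]]$gene
        sort(sample(eff, min(fm_size, length(eff))))
      } else {
        sort(sample(setdiff(genes, effect_genes), fm_size))
      }
    }

    target_pool <- if (drug_target_pool == "modules") {
      if (is.null(truth$planted_modules))
        abort_dganet("truth has no planted modules; run generate_network()", "bad_config")
      unlist(truth$planted_modules)
    } else genes
    drug_ids <- sprintf("drug%03d", seq_len(config$n_drugs))
    drug_targets <- lapply(drug_ids, function(d)
      sort(sample(target_pool, config$targets_per_drug)))
    names(drug_targets) <- drug_ids
    drug_table <- tibble::tibble(
      drug_id = rep(drug_ids, each = config$targets_per_drug),
      gene = unlist(drug_targets),
      approved = rep(stats::rbinom(config$n_drugs, 1, 0.5),
                     each = config$targets_per_drug)
    )
    truth$druggable_genes <- sort(unique(drug_table$gene))
    truth$drug_targets <- drug_targets
    list(disease_genes = disease_genes, universe = genes,
         functional_modules = fms, drug_table = drug_table, truth = truth)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(
    "<planted_truth> %d diseases, %d effect programs%s%s\n",
    nrow(x$cluster_labels), length(x$effect_gene_sets),
    if (is.null(x$planted_modules)) ""
    else sprintf(", %d planted network modules", length(x$planted_modules)),
    if (is.null(x$drug_targets)) ""
    else sprintf(", %d drugs", length(x$drug_targets))
  ))
  invisible(x)
}
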