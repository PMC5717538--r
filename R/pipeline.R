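#' End-to-end pipeline configuration
#'
#' Exactly one input mode is active: `synthetic` (a [synthetic_config()],
#' everything generated in memory) or `paths` (a named list of files:
#' `studies` — a data frame/list with `matrix` and `sheet` paths, one row
#' per study —, `edges`, `gmt`, `disease_genes`, `drugs`).
#'
#' @param synthetic a [synthetic_config()], or NULL.
#' @param paths named list of input paths, or NULL.
#' @param alpha significance level used throughout.
#' @param n_perm label-shuffling permutations.
#' @param seed master seed; stages derive child seeds from it.
#' @param reg_t a [reg_t_params()].
#' @param mcl an [mcl_params()].
#' @param score_threshold strict edge-score cutoff.
#' @param min_module_size minimum surviving module size.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            alpha = 0.05, n_perm = 100L, seed = 1L,
                            reg_t = reg_t_params(), mcl = mcl_params(),
                            score_threshold = 0.85, min_module_size = 3L) {
  if (is.null(synthetic) == is.null(paths))
    abort_dganet("exactly one of `synthetic` or `paths` must be given",
                 "bad_config")
  if (alpha <= 0 || alpha >= 1) abort_dganet("alpha must lie in (0,1)", "bad_config")
  if (n_perm < 1) abort_dganet("n_perm must be >= 1", "bad_config")
  structure(
    list(synthetic = synthetic, paths = paths, alpha = alpha,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         reg_t = reg_t, mcl = mcl, score_threshold = score_threshold,
         min_module_size = as.integer(min_module_size)),
    class = "pipeline_config"
  )
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    # the pipeline seed governs every source of randomness, including the
    # synthetic world itself
    sc$seed <- child_seed(config$seed, 10L)
    comp <- generate_compendium(sc)
    net <- generate_network(sc, comp$truth)
    ann <- generate_annotations(sc, net$truth)
    list(studies = comp$studies, edges = net$edges,
         fms = structure(list(modules = ann$functional_modules,
                              provenance = "gmt"),
                         class = "module_set"),
         disease_genes = ann$disease_genes,
         drugs = as_drug_gene_map(ann$drug_table),
         truth = ann$truth)
  } else {
    p <- config$paths
    studies <- purrr::map2(p$studies$matrix, p$studies$sheet,
                           read_expression_study)
    list(studies = studies,
         edges = readr::read_tsv(p$edges, show_col_types = FALSE,
                                 col_names = c("node1", "node2", "score"),
                                 skip = 0),
         fms = load_gene_sets(p$gmt),
         disease_genes = {
           tbl <- readr::read_tsv(p$disease_genes, show_col_types = FALSE,
                                  col_names = c("disease", "gene"))
           lapply(split(tbl$gene, tbl$disease), unique)
         },
         drugs = read_drug_table(p$drugs),
         truth = NULL)
  }
}

#' Run the full disease-similarity pipeline
#'
#' Stages, in order: preprocessing (per-disease batch merge and
#' z-transformation, cross-disease gene intersection); DGA scoring;
#' partial-correlation similarity with a permutation null, pair p-values
#' and calibrated complete-linkage clustering; network module detection
#' (edge filter, MCL, size filter), PMA scoring and signature
#' extraction; FMA scoring and shared-FM reports; disease-gene overlap
#' and expression/gene concordance; druggable-target over-representation,
#' cluster-associated and cluster-unique modules, and per-cluster drug
#' candidates. The run manifest records the seed, parameters and a
#' content hash of every result (floats at 12 significant digits), so an
#' identical config yields identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return a `pipeline_result` list; see the elements in the examples of
#'   the package vignette.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      rlang::abort(sprintf("pipeline stage '%s' failed: %s",
                           name, conditionMessage(e)),
                   class = "dganet_stage_error", parent = e))
  }
  inputs <- stage("load", load_pipeline_inputs(config))
  say("preprocessing: %d studies", length(inputs$studies))
  prep <- stage("preprocessing", {
    studies <- lapply(inputs$studies, function(s) ztransform(merge_batches(s)))
    intersect_genes(studies)
  })
  say("dga: %d genes x %d diseases", length(prep$universe),
      length(prep$studies))
  dga <- stage("dga", dga_matrix(prep$studies, config$reg_t))
  say("similarity: %d permutations", config$n_perm)
  sim <- stage("similarity", disease_similarity(
    prep$studies, config$reg_t, n_perm = config$n_perm,
    alpha = config$alpha, seed = child_seed(config$seed, 11L)))
  say("modules: clustering interaction network")
  modules <- stage("modules", {
    net <- as_protein_network(inputs$edges, config$score_threshold)
    mcl <- mcl_cluster(net, config$mcl)
    filtered <- filter_modules(mcl, prep$universe, config$min_module_size)
    null_mod <- permutation_null(
      prep$studies, config$reg_t, config$n_perm,
      seed = child_seed(config$seed, 12L),
      statistic = "module-activity", modules = filtered$modules)
    pma <- module_activity(filtered, dga, null_mod)
    sig <- signature_modules(pma, config$alpha)
    list(network = net, module_set = filtered, pma = pma, signature = sig)
  })
  say("functional modules: %d sets", length(inputs$fms$modules))
  fms <- stage("fms", {
    kept <- filter_modules(inputs$fms, prep$universe, min_size = 1L)
    null_fm <- permutation_null(
      prep$studies, config$reg_t, config$n_perm,
      seed = child_seed(config$seed, 13L),
      statistic = "module-activity", modules = kept$modules)
    fma <- module_activity(kept, dga, null_fm)
    list(fma = fma, shared = shared_fms_all_pairs(fma, config$alpha))
  })
  say("associations: %d disease-gene lists", length(inputs$disease_genes))
  assoc <- stage("associations", {
    overlap <- pairwise_overlap_table(inputs$disease_genes,
                                      alpha = config$alpha)
    expr_sig <- significant_pairs(sim)
    gene_sig <- dplyr::filter(overlap, .data$significant)
    conc <- pair_concordance(expr_sig, gene_sig, sim$disease_ids)
    list(overlap = overlap, concordance = conc)
  })
  say("drugs: mapping targets")
  drugs <- stage("drugs", {
    sig_genes <- sort(unique(unlist(
      modules$pma$module_genes[modules$signature$signature])))
    overrep <- if (length(sig_genes) > 0) {
      druggable_overrep(sig_genes,
                        intersect(inputs$drugs$druggable_genes, prep$universe),
                        prep$universe)
    } else NULL
    cl_tbl <- dplyr::filter(sim$clusters, .data$clustered)
    cl_list <- split(cl_tbl$disease_id, cl_tbl$cluster)
    cl_modules <- lapply(cl_list, function(ds)
      cluster_associated_modules(modules$pma, ds, config$alpha))
    uniq <- if (length(cl_modules) >= 2) cluster_unique_modules(cl_modules)
            else NULL
    per_cluster_drugs <- if (!is.null(uniq)) {
      lapply(uniq$unique, function(ids)
        drugs_for_modules(modules$pma$module_genes[ids], inputs$drugs))
    } else NULL
    list(signature_genes = sig_genes, overrep = overrep,
         cluster_modules = cl_modules, unique = uniq,
         per_cluster_drugs = per_cluster_drugs)
  })
  result <- structure(
    list(config = config, universe = prep$universe, dga = dga,
         similarity = sim, modules = modules, fms = fms,
         associations = assoc, drugs = drugs, truth = inputs$truth),
    class = "pipeline_result"
  )
  result$manifest <- run_manifest(result)
  result
}

round_floats <- function(x) {
  if (is.double(x)) return(signif(x, 12))
  if (is.list(x)) return(lapply(x, round_floats))
  x
}

run_manifest <- function(result) {
  hash_of <- function(x) rlang::hash(round_floats(unclass(x)))
  list(
    seed = result$config$seed,
    alpha = result$config$alpha,
    n_perm = result$config$n_perm,
    hashes = list(
      universe = hash_of(result$universe),
      dga = hash_of(result$dga),
      pcor = hash_of(result$similarity$pcor),
      pvals = hash_of(result$similarity$pvals),
      clusters = hash_of(result$similarity$clusters),
      pma = hash_of(result$modules$pma$activity),
      signature = hash_of(result$modules$signature$signature),
      fma = hash_of(result$fms$fma$activity),
      overlap = hash_of(result$associations$overlap),
      drugs = hash_of(result$drugs$per_cluster_drugs)
    )
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    paste0("<pipeline_result> %d genes, %d diseases | %d significant pairs, ",
           "%d clusters | %d modules, %d signature | seed %d\n"),
    length(x$universe), length(x$similarity$disease_ids),
    nrow(significant_pairs(x$similarity)),
    length(unique(x$similarity$clusters$cluster[x$similarity$clusters$clustered])),
    length(x$modules$module_set$modules),
    length(x$modules$signature$signature),
    x$config$seed))
  invisible(x)
}

#' Export result graphs as SIF / GraphML
#'
#' Writes the disease-similarity graph (nodes = diseases, edges =
#' significant pairs, `pcor` edge attribute) and the signature
#' module-membership graph (module -- gene edges) for network viewers.
#'
#' @param result a `pipeline_result` or `similarity_result`.
#' @param dir output directory (created if missing).
#' @param format `"sif"` or `"graphml"`.
#' @return invisible character vector of the files written.
#' @export
export_networks <- function(result, dir, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       abort_dganet("unknown format", "bad_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (inherits(result, "pipeline_result")) result$similarity else result
  pairs <- significant_pairs(sim)
  files <- character(0)
  write_one <- function(edges, nodes, name, relation) {
    path <- file.path(dir, paste0(name, ".", format))
    if (format == "sif") {
      lines <- if (nrow(edges) > 0)
        sprintf("%s\t%s\t%s", edges[[1]], relation, edges[[2]])
      else character(0)
      readr::write_lines(lines, path)
    } else {
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = nodes))
      igraph::write_graph(g, path, format = "graphml")
    }
    path
  }
  files <- c(files, write_one(pairs[, c("disease_a", "disease_b", "pcor")],
                              sim$disease_ids, "disease_similarity",
                              "similar_to"))
  if (inherits(result, "pipeline_result")) {
    sig <- result$modules$signature$signature
    mem <- purrr::map_dfr(sig, function(m)
      tibble::tibble(module = m,
                     gene = result$modules$pma$module_genes[[m]],
                     weight = 1))
    if (nrow(mem) == 0) mem <- tibble::tibble(module = character(0),
                                              gene = character(0),
                                              weight = numeric(0))
    files <- c(files, write_one(
      mem, unique(c(mem$module, mem$gene)), "signature_modules", "contains"))
  }
  invisible(files)
}
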