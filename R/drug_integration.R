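#' Read a drug-gene interaction table
#'
#' @param path TSV with columns `drug_id`, `gene`, `approved` (0/1).
#' @return a `drug_gene_map`: list with `targets` (drug -> gene vector),
#'   `approved` (named logical), `druggable_genes` (union of targets),
#'   `table` (the tibble).
#' @export
read_drug_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  as_drug_gene_map(tbl)
}

#' Build a drug-gene map from a table
#'
#' @param table data frame with columns `drug_id`, `gene`, `approved`.
#' @param druggable_genes optional expert-curated druggable gene set;
#'   defaults to the union of all targets.
#' @return a `drug_gene_map`.
#' @export
as_drug_gene_map <- function(table, druggable_genes = NULL) {
  table <- tibble::as_tibble(table)
  req <- c("drug_id", "gene", "approved")
  if (!all(req %in% names(table)))
    abort_dganet("drug table needs columns drug_id, gene, approved", "bad_format")
  targets <- lapply(split(table$gene, table$drug_id), function(g) sort(unique(g)))
  if (any(lengths(targets) == 0))
    abort_dganet("a drug has no targets", "bad_input")
  appr <- vapply(split(as.logical(table$approved), table$drug_id),
                 function(x) {
                   if (length(unique(x)) != 1)
                     abort_dganet("inconsistent approval flag for a drug", "bad_input")
                   x[1]
                 }, logical(1))
  structure(
    list(targets = targets, approved = appr,
         druggable_genes = druggable_genes %||% sort(unique(table$gene)),
         table = table),
    class = "drug_gene_map"
  )
}

#' @export
print.drug_gene_map <- function(x, ...) {
  cat(sprintf("<drug_gene_map> %d drugs (%d approved), %d druggable genes\n",
              length(x$targets), sum(x$approved), length(x$druggable_genes)))
  invisible(x)
}

#' Druggable-target over-representation in signature genes
#'
#' Upper-tail hypergeometric test that druggable genes are enriched in a
#' signature gene set, via the shared exact code path of
#' [hypergeom_overlap()].
#'
#' @param signature_genes genes of the signature modules (non-empty).
#' @param druggable_genes druggable category gene set.
#' @param universe measured gene universe.
#' @return list with `overlap` (druggable genes in the signature) and
#'   `p_value`.
#' @export
druggable_overrep <- function(signature_genes, druggable_genes, universe) {
  overrepresentation(signature_genes, druggable_genes, universe)
}

#' Modules associated with a disease cluster
#'
#' The signature two-step rule restricted to one cluster's diseases:
#' stage 1 keeps modules significant (p < alpha) in every cluster member
#' (`rule = "all"`, default) or in a strict majority
#' (`rule = "majority"`); stage 2 keeps modules at or above the median
#' mean |activity| over the cluster's diseases among stage-1 modules.
#'
#' @param activity an `activity_matrix` with p-values.
#' @param diseases the cluster's disease ids.
#' @param alpha significance level.
#' @param rule `"all"` or `"majority"`.
#' @return character vector of module ids.
#' @export
cluster_associated_modules <- function(activity, diseases, alpha = 0.05,
                                       rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (is.null(activity$pvals))
    abort_dganet("activity matrix has no p-values", "bad_input")
  missing <- setdiff(diseases, colnames(activity$activity))
  if (length(missing) > 0)
    abort_dganet(paste("unknown disease(s):", paste(missing, collapse = ", ")),
                 "bad_input")
  sig <- activity$pvals[, diseases, drop = FALSE] < alpha
  n_needed <- if (rule == "all") length(diseases) else floor(length(diseases) / 2) + 1
  stage1 <- rownames(sig)[rowSums(sig) >= n_needed]
  if (length(stage1) == 0) return(character(0))
  summaries <- rowMeans(abs(activity$activity[stage1, diseases, drop = FALSE]))
  stage1[summaries >= stats::median(summaries)]
}

#' Cluster-unique and universally shared modules
#'
#' Set algebra over per-cluster associated-module sets: a module is
#' unique to a cluster when no other cluster lists it, and shared-by-all
#' when every cluster lists it.
#'
#' @param cluster_modules named list: cluster id -> module-id vector
#'   (>= 2 clusters).
#' @return list with `unique` (named list per cluster) and `shared_all`.
#' @export
cluster_unique_modules <- function(cluster_modules) {
  if (length(cluster_modules) < 2)
    abort_dganet("need >= 2 clusters", "bad_input")
  uniq <- lapply(seq_along(cluster_modules), function(i)
    sort(setdiff(cluster_modules[[i]],
                 unlist(cluster_modules[-i], use.names = FALSE))))
  names(uniq) <- names(cluster_modules)
  list(unique = uniq,
       shared_all = sort(Reduce(intersect, cluster_modules)))
}

#' Drugs targeting a set of modules
#'
#' A drug is listed when at least one of its targets falls in the union
#' of the given modules' genes; `approved_only` restricts to approved
#' drugs. Output is ordered by drug id.
#'
#' @param module_genes named list of gene vectors (the modules of
#'   interest), or a `module_set`.
#' @param drugs a `drug_gene_map`.
#' @param approved_only keep approved drugs only (default TRUE).
#' @return tibble `drug_id`, `approved`, `n_hits`, `hit_genes`
#'   (list-column).
#' @export
drugs_for_modules <- function(module_genes, drugs, approved_only = TRUE) {
  if (inherits(module_genes, "module_set")) module_genes <- module_genes$modules
  pool <- sort(unique(unlist(module_genes, use.names = FALSE)))
  ids <- sort(names(drugs$targets))
  out <- purrr::map_dfr(ids, function(d) {
    hits <- intersect(drugs$targets[[d]], pool)
    tibble::tibble(drug_id = d, approved = drugs$approved[[d]],
                   n_hits = length(hits), hit_genes = list(hits))
  }) |>
    dplyr::filter(.data$n_hits > 0)
  if (approved_only) out <- dplyr::filter(out, .data$approved)
  out
}
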