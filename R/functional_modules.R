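#' Load curated gene sets from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB gene TAB ...`.
#' Duplicate genes within a set are counted once; empty sets and
#' duplicate set names are rejected. Intended for the curated
#' functional-module catalog of skeletal-muscle physiology (neuromuscular
#' junction, excitation-contraction coupling, calcium homeostasis,
#' mitochondrial metabolism, ...), but any GMT works.
#'
#' @param path GMT file.
#' @return a `module_set` with `provenance = "gmt"` and a `descriptions`
#'   element (named character).
#' @export
load_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort_dganet("empty GMT file", "bad_format")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    abort_dganet(sprintf("malformed GMT line %d: need name, description, genes",
                         bad[1]), "bad_format")
  names_ <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names_))
    abort_dganet("duplicate set names in GMT", "bad_format")
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- which(lengths(genes) == 0 |
                   vapply(genes, function(g) all(!nzchar(g)), logical(1)))
  if (length(empty) > 0)
    abort_dganet(sprintf("empty gene set at GMT line %d", empty[1]),
                 "bad_format")
  names(genes) <- names_
  structure(
    list(modules = genes, provenance = "gmt",
         descriptions = stats::setNames(
           vapply(fields, `[`, character(1), 2), names_)),
    class = "module_set"
  )
}

#' Functional module activity (FMA) scores
#'
#' Mean DGA of each functional module's genes per disease with matched
#' permutation p-values — the same computation as protein-module
#' activity, on curated gene sets. Negative FMA means the module's genes
#' are collectively downregulated in disease relative to controls.
#' Modules with no gene in the DGA universe are dropped with a warning.
#'
#' @param fms a `module_set` (typically from [load_gene_sets()]).
#' @param dga a [dga_matrix()].
#' @param null_store a `perm_null` with statistic `"module-activity"`
#'   built on the intersected modules (see [permutation_null()]), or NULL.
#' @return an `activity_matrix`.
#' @export
fma_scores <- function(fms, dga, null_store = NULL) {
  kept <- filter_modules(fms, rownames(dga), min_size = 1L)
  dropped <- attr(kept, "n_original") - attr(kept, "n_surviving")
  if (length(kept$modules) == 0)
    abort_dganet("no functional module overlaps the gene universe",
                 "empty_result")
  if (dropped > 0)
    warning(sprintf("%d functional module(s) had no gene in the universe and were dropped",
                    dropped))
  module_activity(kept, dga, null_store)
}

#' Functional modules shared by a disease pair
#'
#' Modules significant (p < alpha) in both diseases, flagged for whether
#' the two activity scores agree in sign (concordant dysregulation) or
#' oppose each other — the latter marks mechanistically divergent use of
#' the same machinery, as seen for calcium handling in some disease
#' pairs.
#'
#' @param activity an `activity_matrix` with p-values.
#' @param disease_a,disease_b disease ids (column names of the activity).
#' @param alpha significance level.
#' @return tibble `fm_id`, `activity_a`, `activity_b`, `p_a`, `p_b`,
#'   `concordant`.
#' @export
shared_fms <- function(activity, disease_a, disease_b, alpha = 0.05) {
  if (is.null(activity$pvals))
    abort_dganet("activity matrix has no p-values", "bad_input")
  for (d in c(disease_a, disease_b)) {
    if (!d %in% colnames(activity$activity))
      abort_dganet(sprintf("unknown disease '%s'", d), "bad_input")
  }
  sig <- activity$pvals[, disease_a] < alpha & activity$pvals[, disease_b] < alpha
  ids <- rownames(activity$activity)[sig]
  tibble::tibble(
    fm_id = ids,
    activity_a = activity$activity[ids, disease_a],
    activity_b = activity$activity[ids, disease_b],
    p_a = activity$pvals[ids, disease_a],
    p_b = activity$pvals[ids, disease_b],
    concordant = sign(activity$activity[ids, disease_a]) ==
      sign(activity$activity[ids, disease_b])
  )
}

#' Shared functional modules for every disease pair
#'
#' @param activity an `activity_matrix` with p-values.
#' @param alpha significance level.
#' @return tibble `disease_a`, `disease_b`, `n_shared`, `fm_ids`
#'   (list-column), one row per unordered pair.
#' @export
shared_fms_all_pairs <- function(activity, alpha = 0.05) {
  ds <- colnames(activity$activity)
  pairs <- utils::combn(ds, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    sh <- shared_fms(activity, pairs[1, k], pairs[2, k], alpha)
    tibble::tibble(disease_a = pairs[1, k], disease_b = pairs[2, k],
                   n_shared = nrow(sh), fm_ids = list(sh$fm_id))
  })
}
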