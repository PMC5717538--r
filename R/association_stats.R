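#' Hypergeometric overlap of two gene sets
#'
#' Tests whether two disease-gene lists overlap more than expected if
#' both were drawn at random from the universe:
#' `p = P(X >= |A intersect B|)` with
#' `X ~ Hypergeometric(N = |universe|, K = |A|, n = |B|)`, computed
#' exactly.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector: the space genes are drawn from.
#' @return list with `overlap` (count) and `p_value`.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    abort_dganet("gene sets must be subsets of the universe", "bad_input")
  ov <- length(intersect(set_a, set_b))
  p <- stats::phyper(ov - 1, length(set_a),
                     length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = ov, p_value = p)
}

#' Pairwise disease-gene overlap table
#'
#' [hypergeom_overlap()] for every unordered disease pair; no
#' multiple-testing correction is applied (significant pairs are raw
#' p < alpha calls).
#'
#' @param disease_genes named list: disease id -> gene-id vector.
#' @param universe gene universe; defaults to the union of all lists.
#' @param alpha significance level.
#' @return tibble `disease_a`, `disease_b`, `overlap`, `p_value`,
#'   `significant`, with attribute `n_pairs`.
#' @export
pairwise_overlap_table <- function(disease_genes,
                                   universe = sort(unique(unlist(disease_genes))),
                                   alpha = 0.05) {
  if (length(disease_genes) < 2)
    abort_dganet("need >= 2 diseases", "bad_input")
  ds <- names(disease_genes)
  pairs <- utils::combn(ds, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    h <- hypergeom_overlap(disease_genes[[pairs[1, k]]],
                           disease_genes[[pairs[2, k]]], universe)
    tibble::tibble(disease_a = pairs[1, k], disease_b = pairs[2, k],
                   overlap = h$overlap, p_value = h$p_value)
  }) |>
    dplyr::mutate(significant = .data$p_value < alpha)
  attr(out, "n_pairs") <- ncol(pairs)
  out
}

#' One-sided Fisher concordance between two significance criteria
#'
#' Cross-classifies disease pairs by two notions of similarity (e.g.
#' expression-based correlation vs. shared disease genes) and tests for
#' enrichment of joint calls: `p = P(X >= a)` with
#' `X ~ Hypergeometric(N = a+b+c+d, K = a+b, n = a+c)` — the one-sided
#' ("greater") Fisher exact test on the 2x2 table.
#'
#' @param a pairs significant under both criteria.
#' @param b pairs significant under the first (row) criterion only.
#' @param c_ pairs significant under the second (column) criterion only.
#' @param d pairs significant under neither.
#' @return list with `p_value` and `table` (the 2x2 matrix).
#' @export
fisher_concordance <- function(a, b, c_, d) {
  counts <- c(a = a, b = b, c = c_, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_dganet("counts must be non-negative integers", "bad_input")
  p <- stats::phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
  list(p_value = p,
       table = matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                      dimnames = list(criterion1 = c("sig", "not"),
                                      criterion2 = c("sig", "not"))))
}

#' Concordance of expression-based and gene-based disease pairs
#'
#' Builds the 2x2 table from two significant-pair sets over the same
#' diseases and applies [fisher_concordance()].
#'
#' @param expr_pairs,gene_pairs data frames with columns `disease_a`,
#'   `disease_b` listing significant pairs under each criterion.
#' @param diseases character vector of all disease ids considered.
#' @return list with `p_value`, `table`, and the pair counts.
#' @export
pair_concordance <- function(expr_pairs, gene_pairs, diseases) {
  key <- function(df) paste(pmin(df$disease_a, df$disease_b),
                            pmax(df$disease_a, df$disease_b), sep = "|")
  all_pairs <- utils::combn(sort(diseases), 2)
  universe <- paste(all_pairs[1, ], all_pairs[2, ], sep = "|")
  e <- intersect(key(expr_pairs), universe)
  g <- intersect(key(gene_pairs), universe)
  a <- length(intersect(g, e))
  b <- length(setdiff(g, e))
  c_ <- length(setdiff(e, g))
  d <- length(universe) - a - b - c_
  c(fisher_concordance(a, b, c_, d),
    list(n_pairs = length(universe), counts = c(a = a, b = b, c = c_, d = d)))
}

#' Over-representation of a gene category in a gene set
#'
#' Upper-tail hypergeometric test that a category (e.g. druggable
#' targets) is enriched in a set of interest (e.g. signature-module
#' genes) relative to the universe. Shares the exact computation of
#' [hypergeom_overlap()].
#'
#' @param set_genes genes of interest (non-empty).
#' @param category_genes category gene set.
#' @param universe gene universe containing both.
#' @return list with `overlap` and `p_value`.
#' @export
overrepresentation <- function(set_genes, category_genes, universe) {
  if (length(set_genes) == 0) abort_dganet("empty gene set", "bad_input")
  hypergeom_overlap(set_genes, category_genes, universe)
}
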