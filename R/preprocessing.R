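#' Collapse probe rows to one row per gene (MaxMean rule)
#'
#' Microarray platforms measure many genes with several probes. For each
#' gene the probe row with the highest mean value is retained; probes
#' without a gene assignment are dropped. Ties on the mean are broken by
#' keeping the lexicographically smallest probe id, so output is
#' deterministic. Genes are returned in lexicographic order.
#'
#' @param values numeric matrix, probes x samples, rownames = probe ids.
#' @param probe_map data frame with columns `probe_id`, `gene_symbol`
#'   (each probe maps to at most one gene).
#' @return genes x samples matrix with gene rownames.
#' @export
collapse_probes <- function(values, probe_map) {
  values <- as.matrix(values)
  probe_map <- tibble::as_tibble(probe_map)
  if (nrow(probe_map) == 0) abort_dganet("empty probe map", "bad_input")
  if (anyDuplicated(probe_map$probe_id))
    abort_dganet("a probe maps to more than one gene", "bad_input")
  keep <- tibble::tibble(
    probe_id = rownames(values),
    probe_mean = rowMeans(values)
  ) |>
    dplyr::inner_join(probe_map, by = "probe_id") |>
    dplyr::filter(!is.na(.data$gene_symbol), .data$gene_symbol != "") |>
    dplyr::arrange(.data$gene_symbol,
                   dplyr::desc(.data$probe_mean), .data$probe_id) |>
    dplyr::distinct(.data$gene_symbol, .keep_all = TRUE)
  if (nrow(keep) == 0)
    abort_dganet("no probe maps to a gene: empty matrix", "empty_result")
  out <- values[keep$probe_id, , drop = FALSE]
  rownames(out) <- keep$gene_symbol
  out
}

#' Per-gene z-transformation
#'
#' Standardizes each gene row across all samples of the study (disease and
#' control pooled) to mean 0 and sample standard deviation 1 (n-1
#' denominator). Constant rows cannot be standardized; they are set to all
#' zeros and listed in the `constant_genes` attribute.
#'
#' @param study an [expression_study()].
#' @return the study with standardized values; `attr(,"constant_genes")`
#'   names any all-constant rows.
#' @export
ztransform <- function(study) {
  x <- study$values
  if (ncol(x) < 2) abort_dganet("need >= 2 samples to z-transform", "bad_input")
  m <- rowMeans(x)
  s <- row_sds(x)
  constant <- s == 0
  s[constant] <- 1
  z <- (x - m) / s
  z[constant, ] <- 0
  study$values <- z
  attr(study, "constant_genes") <- rownames(x)[constant]
  study
}

#' Merge batches of one disease with per-batch standardization
#'
#' Stand-in for empirical-Bayes batch correction: genes are restricted to
#' the intersection across inputs and every (study, batch) block is
#' standardized gene-wise before the blocks are concatenated, which removes
#' additive per-batch offsets exactly. Batch ids are preserved (prefixed
#' with the study index when inputs collide on batch names).
#'
#' @param studies list of [expression_study()] objects for one disease;
#'   a single multi-batch study is also accepted.
#' @return a single merged [expression_study()].
#' @export
merge_batches <- function(studies) {
  if (inherits(studies, "expression_study")) studies <- list(studies)
  stopifnot(length(studies) >= 1)
  ids <- unique(vapply(studies, function(s) s$disease_id, character(1)))
  if (length(ids) != 1)
    abort_dganet("merge_batches() takes studies of a single disease", "bad_input")
  genes <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  if (length(genes) == 0)
    abort_dganet("no genes shared across batches", "empty_intersection")
  genes <- sort(genes)

  batch_names <- unlist(lapply(studies, function(s) unique(s$samples$batch)))
  prefix <- length(studies) > 1 && anyDuplicated(batch_names) > 0

  blocks <- list(); sheets <- list()
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    vals <- s$values[genes, , drop = FALSE]
    for (b in unique(s$samples$batch)) {
      cols <- s$samples$batch == b
      block <- vals[, cols, drop = FALSE]
      m <- rowMeans(block)
      sd_b <- row_sds(block)
      sd_b[sd_b == 0] <- 1
      block <- (block - m) / sd_b
      bid <- if (prefix) paste0("s", i, ".", b) else as.character(b)
      blocks[[length(blocks) + 1]] <- block
      sheets[[length(sheets) + 1]] <- dplyr::mutate(
        s$samples[cols, ], batch = bid
      )
    }
  }
  expression_study(ids, do.call(cbind, blocks), dplyr::bind_rows(sheets))
}

#' Restrict a compendium to its common gene universe
#'
#' @param studies list of [expression_study()] objects (one per disease).
#' @return list with `universe` (sorted character vector) and `studies`
#'   (inputs re-indexed to the universe, same order).
#' @export
intersect_genes <- function(studies) {
  stopifnot(length(studies) >= 1)
  universe <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  if (length(universe) == 0)
    abort_dganet("no genes shared across all studies", "empty_intersection")
  universe <- sort(universe)
  studies <- lapply(studies, function(s) {
    s$values <- s$values[universe, , drop = FALSE]
    s
  })
  list(universe = universe, studies = studies)
}
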