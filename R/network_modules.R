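#' Load a weighted protein-interaction edge list
#'
#' Reads a STRING-style TSV (two node columns plus a confidence score,
#' with or without a header line), keeps edges with score strictly above
#' the threshold, drops self-loops, and de-duplicates undirected edges
#' keeping the maximum score. Scores on a 0-1000 integer scale are
#' auto-detected (any value > 1) and divided by 1000.
#'
#' @param path TSV file: columns node1, node2, score.
#' @param threshold strict lower cutoff on the combined score
#'   (default 0.85, the high-confidence regime).
#' @return a `protein_network`: list with `nodes` (character) and
#'   `edges` (tibble `node1`, `node2`, `score`, node1 < node2).
#' @export
load_edges <- function(path, threshold = 0.85) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort_dganet("empty edge file", "bad_format")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (suppressWarnings(is.na(as.numeric(fields[[1]][3])))) start <- 2L
  if (start > length(lines))
    abort_dganet("no edge rows: line 1 is a lone header or malformed",
                 "bad_format")
  rows <- fields[start:length(fields)]
  bad <- which(lengths(rows) < 3)
  if (length(bad) > 0)
    abort_dganet(sprintf("malformed edge row at line %d", bad[1] + start - 1L),
                 "bad_format")
  score <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 3)))
  if (anyNA(score))
    abort_dganet(sprintf("non-numeric score at line %d",
                         which(is.na(score))[1] + start - 1L),
                 "bad_format")
  if (any(score > 1)) score <- score / 1000
  edges <- tibble::tibble(
    node1 = vapply(rows, `[`, character(1), 1),
    node2 = vapply(rows, `[`, character(1), 2),
    score = score
  ) |>
    dplyr::filter(.data$node1 != .data$node2, .data$score > threshold)
  if (nrow(edges) == 0)
    abort_dganet("no edges above threshold", "empty_result")
  edges <- edges |>
    dplyr::mutate(a = pmin(.data$node1, .data$node2),
                  b = pmax(.data$node1, .data$node2)) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::rename(node1 = "a", node2 = "b") |>
    dplyr::arrange(.data$node1, .data$node2)
  if (nrow(edges) == 0)
    abort_dganet("no edges above threshold", "empty_result")
  structure(
    list(nodes = sort(unique(c(edges$node1, edges$node2))), edges = edges,
         threshold = threshold),
    class = "protein_network"
  )
}

#' Build a protein network from an in-memory edge table
#'
#' Same filtering and de-duplication rules as [load_edges()].
#'
#' @param edges data frame with columns `node1`, `node2`, `score`.
#' @param threshold strict score cutoff.
#' @return a `protein_network`.
#' @export
as_protein_network <- function(edges, threshold = 0.85) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  readr::write_tsv(edges[, c("node1", "node2", "score")], tmp, col_names = FALSE)
  load_edges(tmp, threshold)
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("<protein_network> %d nodes, %d edges (score > %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Markov clustering parameters
#'
#' @param expansion integer matrix power e >= 2 (random-walk step count).
#' @param inflation Hadamard exponent r > 1; larger values give more,
#'   smaller clusters.
#' @param prune_threshold entries below this are zeroed each iteration
#'   (columns re-normalized afterwards).
#' @param tol convergence tolerance on the max entrywise change.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate.
#' @param self_loop_weight loop weight added to every node before
#'   normalization.
#' @return an `mcl_params` list.
#' @export
mcl_params <- function(expansion = 2L, inflation = 2.0,
                       prune_threshold = 1e-5, tol = 1e-6,
                       max_iter = 100L, self_loop_weight = 1) {
  if (expansion < 2) abort_dganet("expansion must be >= 2", "bad_params")
  if (inflation <= 1) abort_dganet("inflation must be > 1", "bad_params")
  if (tol <= 0) abort_dganet("tol must be > 0", "bad_params")
  structure(list(expansion = as.integer(expansion), inflation = inflation,
                 prune_threshold = prune_threshold, tol = tol,
                 max_iter = as.integer(max_iter),
                 self_loop_weight = self_loop_weight),
            class = "mcl_params")
}

col_normalize <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

#' Markov clustering (MCL) of a weighted network
#'
#' Simulates stochastic flow on the graph: the column-stochastic
#' transition matrix is alternately expanded (matrix power, spreading
#' flow) and inflated (entrywise power plus column re-normalization,
#' sharpening flow) until the matrix stops changing. Clusters are read
#' from the converged matrix: rows with mass on their own node are
#' attractors, each attractor row's nonzero support is a cluster, and a
#' node claimed by several attractor systems goes to the one holding the
#' largest converged weight (ties to the lowest module id). The result is
#' a partition of the node set, with modules numbered by decreasing size.
#'
#' @param network a `protein_network` (or any list with `nodes` and an
#'   `edges` tibble).
#' @param params an [mcl_params()].
#' @return a `module_set`: list with `modules` (named list of sorted
#'   gene-id vectors), `provenance = "mcl"`, `converged`, `n_iter`.
#' @export
mcl_cluster <- function(network, params = mcl_params()) {
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0) abort_dganet("empty network", "bad_input")
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(network$edges$node1, nodes)
  j <- match(network$edges$node2, nodes)
  a[cbind(i, j)] <- network$edges$score
  a[cbind(j, i)] <- network$edges$score
  diag(a) <- diag(a) + params$self_loop_weight
  m <- col_normalize(a)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    m_new <- m
    for (k in seq_len(params$expansion - 1L)) m_new <- m_new %*% m
    m_new <- m_new^params$inflation
    m_new[m_new < params$prune_threshold] <- 0
    m_new <- col_normalize(m_new)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < params$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations; using last iterate",
                    params$max_iter))

  attractors <- which(diag(m) > params$tol)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # group attractors whose supports overlap (one attractor system = one cluster)
  supports <- lapply(attractors, function(r) which(m[r, ] > 0))
  group <- seq_along(attractors)
  find <- function(x) { while (group[x] != x) x <- group[x]; x }
  for (p in seq_along(attractors)) for (q in seq_len(p - 1L)) {
    if (length(intersect(supports[[p]], supports[[q]])) > 0) {
      rp <- find(p); rq <- find(q)
      group[max(rp, rq)] <- min(rp, rq)
    }
  }
  roots <- vapply(seq_along(attractors), find, integer(1))
  cluster_of_attractor <- match(roots, unique(roots))
  n_cl <- length(unique(roots))
  # assign every node to the cluster with the largest converged weight
  weight <- matrix(0, n_cl, n)
  for (p in seq_along(attractors)) {
    cl <- cluster_of_attractor[p]
    weight[cl, ] <- pmax(weight[cl, ], m[attractors[p], ])
  }
  assignment <- integer(n)
  for (v in seq_len(n)) {
    w <- weight[, v]
    assignment[v] <- if (max(w) > 0) which.max(w) else 0L
  }
  # stragglers not covered by any attractor system become singletons
  for (v in which(assignment == 0L)) {
    n_cl <- n_cl + 1L
    assignment[v] <- n_cl
  }
  modules <- split(nodes, assignment)
  modules <- lapply(modules, sort)
  ord <- order(-lengths(modules),
               vapply(modules, `[`, character(1), 1))
  modules <- modules[ord]
  names(modules) <- sprintf("M%03d", seq_along(modules))
  structure(
    list(modules = modules, provenance = "mcl",
         converged = converged, n_iter = iter),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  sz <- lengths(x$modules)
  cat(sprintf("<module_set> %d modules (%s), sizes %d-%d\n",
              length(x$modules), x$provenance,
              if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L))
  invisible(x)
}

#' Filter modules against a gene universe and a minimum size
#'
#' Each module is intersected with the measured-gene universe; modules
#' with fewer than `min_size` surviving genes are dropped.
#'
#' @param module_set a `module_set`.
#' @param universe character vector of measured gene ids.
#' @param min_size minimum surviving module size (default 3).
#' @return the filtered `module_set`, with attributes `n_original` and
#'   `n_surviving`.
#' @export
filter_modules <- function(module_set, universe, min_size = 3L) {
  trimmed <- lapply(module_set$modules, intersect, y = universe)
  keep <- lengths(trimmed) >= min_size
  out <- module_set
  out$modules <- trimmed[keep]
  attr(out, "n_original") <- length(module_set$modules)
  attr(out, "n_surviving") <- sum(keep)
  out
}

#' Module activity scores with matched permutation p-values
#'
#' The activity of module i in disease k is the arithmetic mean of the
#' DGA scores of the module's genes (in the universe) for that disease —
#' the PMA score for protein modules, the FMA score for functional
#' modules; negative values mean the module's genes are collectively down
#' in disease. Significance is two-sided: the p-value compares
#' |activity| with the same module's and disease's permuted activities,
#' `p = (1 + #\{|null| >= |obs|\}) / (N + 1)`, so module size is matched
#' between observed and null.
#'
#' @param module_set a `module_set` already filtered against the DGA
#'   universe (empty modules are an error).
#' @param dga a [dga_matrix()].
#' @param null_store a `perm_null` with statistic `"module-activity"`
#'   built on the same modules, or NULL to skip p-values.
#' @return an `activity_matrix`: list with `activity` and `pvals`
#'   (modules x diseases matrices) and `module_genes`.
#' @export
module_activity <- function(module_set, dga, null_store = NULL) {
  genes <- rownames(dga)
  idx <- lapply(module_set$modules, function(g) which(genes %in% g))
  if (any(lengths(idx) == 0))
    abort_dganet("empty module after universe intersection; run filter_modules()",
                 "empty_module")
  activity <- t(vapply(idx, function(ix)
    colMeans(unclass(dga)[ix, , drop = FALSE]), numeric(ncol(dga))))
  dimnames(activity) <- list(names(module_set$modules), colnames(dga))
  pvals <- NULL
  if (!is.null(null_store)) {
    stopifnot(inherits(null_store, "perm_null"),
              null_store$statistic == "module-activity")
    if (!identical(null_store$module_ids, names(module_set$modules)))
      abort_dganet("null store was built on different modules", "bad_input")
    nv <- abs(null_store$values)          # [perm, module, disease]
    np <- dim(nv)[1]
    exceed <- apply(sweep(nv, c(2, 3), abs(activity), ">="), c(2, 3), sum)
    pvals <- (1 + exceed) / (np + 1)
    dimnames(pvals) <- dimnames(activity)
  }
  structure(
    list(activity = activity, pvals = pvals,
         module_genes = module_set$modules,
         provenance = module_set$provenance),
    class = "activity_matrix"
  )
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d modules x %d diseases (%s)%s\n",
              nrow(x$activity), ncol(x$activity), x$provenance,
              if (is.null(x$pvals)) " [no p-values]" else ""))
  invisible(x)
}

#' Extract the cross-disease signature modules
#'
#' Two-step rule: stage 1 keeps modules significantly active
#' (p < alpha) in strictly more than half the diseases; stage 2 keeps, of
#' those, the modules whose mean absolute activity over all diseases is
#' at or above the median of that summary across stage-1 modules (the
#' "upper 50th percentile of module expression").
#'
#' @param activity an `activity_matrix` with p-values.
#' @param alpha per-disease significance level.
#' @param summary_over `"all"` (mean |activity| over all diseases,
#'   default) or `"significant"` (over the significant diseases only).
#' @return list with `stage1` (module ids), `signature` (module ids),
#'   `expression_threshold`, and `summaries` (named numeric).
#' @export
signature_modules <- function(activity, alpha = 0.05,
                              summary_over = c("all", "significant")) {
  summary_over <- match.arg(summary_over)
  if (is.null(activity$pvals))
    abort_dganet("activity matrix has no p-values", "bad_input")
  D <- ncol(activity$activity)
  sig <- activity$pvals < alpha
  stage1 <- rownames(activity$activity)[rowSums(sig) > D / 2]
  if (length(stage1) == 0) {
    warning("no module is significant in a strict majority of diseases")
    return(list(stage1 = character(0), signature = character(0),
                expression_threshold = NA_real_, summaries = numeric(0)))
  }
  absact <- abs(activity$activity[stage1, , drop = FALSE])
  summaries <- if (summary_over == "all") {
    rowMeans(absact)
  } else {
    masked <- absact
    masked[!sig[stage1, , drop = FALSE]] <- NA
    rowMeans(masked, na.rm = TRUE)
  }
  threshold <- stats::median(summaries)
  list(stage1 = stage1,
       signature = stage1[summaries >= threshold],
       expression_threshold = threshold,
       summaries = summaries)
}

#' Write a module set as a GMT file
#'
#' @param module_set a `module_set` or named list of gene vectors.
#' @param path output path.
#' @param description optional description column (recycled).
#' @export
write_gmt <- function(module_set, path, description = "na") {
  modules <- if (inherits(module_set, "module_set")) module_set$modules
             else module_set
  lines <- vapply(seq_along(modules), function(i)
    paste(c(names(modules)[i], description[(i - 1) %% length(description) + 1],
            modules[[i]]), collapse = "\t"), character(1))
  readr::write_lines(lines, path)
  invisible(module_set)
}
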