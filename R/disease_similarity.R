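#' Pairwise partial correlations from the precision matrix
#'
#' The partial correlation of variables i and j controlling for all other
#' columns is `-P_ij / sqrt(P_ii * P_jj)` where `P` is the inverse of the
#' column correlation matrix. For the disease-similarity analysis the
#' input is the DGA matrix (genes as observations, diseases as variables),
#' so each entry is the correlation of two diseases' differential programs
#' with every other disease factored out.
#'
#' @param x observations x variables numeric matrix (more observations
#'   than variables, no constant column).
#' @return symmetric variables x variables matrix with unit diagonal.
#' @export
partial_correlation <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    abort_dganet("need more observations (rows) than variables (columns)",
                 "bad_input")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    abort_dganet(paste0("constant column(s): ",
                        paste(colnames(x)[sds == 0], collapse = ", ")),
                 "bad_input")
  r <- stats::cor(x)
  prec <- tryCatch(
    solve(r),
    error = function(e) {
      cors <- abs(r); diag(cors) <- 0
      bad <- which(cors > 1 - 1e-10, arr.ind = TRUE)
      cols <- if (nrow(bad) > 0) {
        pairs <- unique(t(apply(bad, 1, sort)))
        paste(apply(pairs, 1, function(p)
          paste(colnames(r)[p], collapse = " ~ ")), collapse = "; ")
      } else "unknown"
      abort_dganet(
        sprintf("correlation matrix is singular (collinear columns: %s)", cols),
        "singular_matrix"
      )
    }
  )
  d <- sqrt(diag(prec))
  pcor <- -prec / tcrossprod(d)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  dimnames(pcor) <- dimnames(r)
  pcor
}

#' Label-shuffling permutation null
#'
#' For each permutation the disease/control labels are reshuffled
#' independently within every study (arm sizes preserved), the DGA matrix
#' is recomputed, and the requested statistic is re-evaluated:
#' `"pairwise-pcor"` stores every off-diagonal pairwise partial
#' correlation, `"module-activity"` stores the mean DGA of each supplied
#' module in each disease. Defaults to 100 permutations.
#'
#' @param studies list of [expression_study()] objects on a shared gene
#'   universe.
#' @param params a [reg_t_params()].
#' @param n_perm number of label shuffles (>= 1).
#' @param seed integer seed; the null store is reproducible from it.
#' @param statistic `"pairwise-pcor"` or `"module-activity"`.
#' @param modules named list of gene-id vectors; required for
#'   `"module-activity"`.
#' @return a `perm_null` store. For `"pairwise-pcor"`: `values` is an
#'   `n_perm` x n_pairs matrix and `pooled()` gives the flattened
#'   background. For `"module-activity"`: `values` is an array
#'   `[n_perm, module, disease]`.
#' @export
permutation_null <- function(studies, params = reg_t_params(),
                             n_perm = 100L, seed = 1L,
                             statistic = c("pairwise-pcor", "module-activity"),
                             modules = NULL) {
  statistic <- tryCatch(match.arg(statistic),
                        error = function(e)
                          abort_dganet("unknown statistic", "bad_params"))
  if (n_perm < 1) abort_dganet("n_perm must be >= 1", "bad_params")
  disease_ids <- vapply(studies, `[[`, character(1), "disease_id")
  genes <- rownames(studies[[1]]$values)
  if (statistic == "module-activity") {
    if (is.null(modules) || length(modules) == 0)
      abort_dganet("modules required for statistic='module-activity'",
                   "bad_params")
    idx <- lapply(modules, function(g) which(genes %in% g))
    if (any(lengths(idx) == 0))
      abort_dganet("a module has no gene in the universe; filter first",
                   "empty_module")
  }
  D <- length(studies)
  withr::with_seed(as.integer(seed), {
    if (statistic == "pairwise-pcor") {
      ut <- upper.tri(matrix(0, D, D))
      pair_names <- outer(disease_ids, disease_ids,
                          function(a, b) paste(a, b, sep = "|"))[ut]
      values <- matrix(NA_real_, n_perm, sum(ut),
                       dimnames = list(NULL, pair_names))
    } else {
      values <- array(NA_real_, c(n_perm, length(modules), D),
                      dimnames = list(NULL, names(modules), disease_ids))
    }
    for (p in seq_len(n_perm)) {
      scores <- vapply(studies, function(s)
        dga_column(s$values, sample(s$samples$arm), params),
        numeric(length(genes)))
      if (statistic == "pairwise-pcor") {
        values[p, ] <- partial_correlation(scores)[ut]
      } else {
        for (m in seq_along(idx)) {
          values[p, m, ] <- colMeans(scores[idx[[m]], , drop = FALSE])
        }
      }
    }
    structure(
      list(statistic = statistic, values = values, n_perm = n_perm,
           seed = as.integer(seed), disease_ids = disease_ids,
           module_ids = names(modules)),
      class = "perm_null"
    )
  })
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %s: %d permutations, %d diseases\n",
              x$statistic, x$n_perm, length(x$disease_ids)))
  invisible(x)
}

pooled_null <- function(null_store) {
  stopifnot(inherits(null_store, "perm_null"),
            null_store$statistic == "pairwise-pcor")
  as.vector(null_store$values)
}

#' Permutation p-values for disease pairs
#'
#' One-sided upper-tail p against the pooled null of all permuted pairwise
#' correlations: `p = (1 + #\{null >= observed\}) / (N + 1)`. The add-one
#' smoothing keeps p > 0 with finitely many permutations; `smooth = FALSE`
#' gives the raw exceedance count fraction.
#'
#' @param pcor observed partial-correlation matrix.
#' @param null_store a `perm_null` with statistic `"pairwise-pcor"`.
#' @param smooth add-one smoothing (default) or raw counts.
#' @return symmetric matrix of p-values in (0, 1\] (raw variant may reach 0).
#' @export
pair_pvalues <- function(pcor, null_store, smooth = TRUE) {
  null <- sort(pooled_null(null_store))
  n <- length(null)
  if (n == 0) abort_dganet("empty null store", "bad_input")
  # #{null >= v} = n - #{null < v}
  below <- findInterval(pcor, null, left.open = TRUE)
  exceed <- n - below
  p <- if (smooth) (1 + exceed) / (n + 1) else exceed / n
  p <- matrix(p, nrow(pcor), ncol(pcor), dimnames = dimnames(pcor))
  (p + t(p)) / 2
}

# Complete-linkage agglomeration with a deterministic tie-break: among
# minimum-distance pairs, merge the one whose (smallest, largest) member
# labels sort lexicographically first. Returns merge steps and heights.
complete_linkage <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  members <- as.list(labels)           # member labels per active cluster
  key <- labels                         # smallest member label per cluster
  dist <- d
  diag(dist) <- Inf
  merges <- vector("list", n - 1)
  assign_sets <- stats::setNames(as.list(seq_len(n)), NULL)
  for (step in seq_len(n - 1)) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cand <- sort(c(key[i], key[j]))
      if (is.null(best) || dist[i, j] < best$h - 1e-15 ||
          (abs(dist[i, j] - best$h) <= 1e-15 &&
           (cand[1] < best$pair[1] ||
            (cand[1] == best$pair[1] && cand[2] < best$pair[2])))) {
        best <- list(i = i, j = j, h = dist[i, j], pair = cand)
      }
    }
    i <- best$i; j <- best$j
    merges[[step]] <- tibble::tibble(
      step = step, cluster_a = key[i], cluster_b = key[j], height = best$h
    )
    new_members <- c(members[[i]], members[[j]])
    new_dist <- pmax(dist[i, ], dist[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(m), c(i, j))
    members <- c(members[keep], list(new_members))
    key <- c(key[keep], min(new_members))
    dist <- dist[keep, keep, drop = FALSE]
    dist <- rbind(cbind(dist, new_dist), c(new_dist, Inf))
  }
  dplyr::bind_rows(merges)
}

cut_linkage <- function(linkage, labels, h) {
  parent <- stats::setNames(labels, labels)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (s in seq_len(nrow(linkage))) {
    if (linkage$height[s] < h) {
      ra <- find(linkage$cluster_a[s]); rb <- find(linkage$cluster_b[s])
      parent[[max(ra, rb)]] <- min(ra, rb)
    }
  }
  roots <- vapply(labels, find, character(1))
  ids <- match(roots, unique(roots))
  tibble::tibble(
    disease_id = labels,
    cluster = sprintf("cluster_%d", ids),
    clustered = as.vector(table(roots)[roots] > 1)
  )
}

#' Cluster diseases by complete linkage with a permutation-calibrated cut
#'
#' Distances are `1 - pcor`; agglomeration is complete linkage with a
#' deterministic lexicographic tie-break. The tree is cut at
#' `h* = 1 - q`, where `q` is the (1 - alpha) quantile of the pooled
#' null correlations, so subtrees entirely below the cut are exactly the
#' groups whose mutual similarity is significant at level alpha.
#' Singletons are reported with `clustered = FALSE`.
#'
#' @param pcor disease partial-correlation matrix.
#' @param null_store a `perm_null` with statistic `"pairwise-pcor"`.
#' @param alpha significance level in (0, 1).
#' @return list with `linkage` (tibble of merges), `clusters` (tibble
#'   `disease_id`, `cluster`, `clustered`), `cut_height`, `null_quantile`.
#' @export
cluster_diseases <- function(pcor, null_store, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    abort_dganet("alpha must lie in (0,1)", "bad_params")
  q <- stats::quantile(pooled_null(null_store), 1 - alpha, names = FALSE)
  h <- 1 - q
  d <- 1 - pcor
  linkage <- complete_linkage(d)
  clusters <- cut_linkage(linkage, rownames(pcor), h)
  list(linkage = linkage, clusters = clusters,
       cut_height = h, null_quantile = q, alpha = alpha)
}

#' Disease similarity from a compendium, end to end
#'
#' Convenience wrapper: DGA matrix, partial correlations, permutation
#' null, pair p-values, and the calibrated complete-linkage clustering in
#' one call.
#'
#' @param studies list of [expression_study()] objects on a shared gene
#'   universe (one per disease).
#' @param params a [reg_t_params()].
#' @param n_perm label-shuffling permutations (default 100).
#' @param alpha significance level for pairs and the tree cut.
#' @param seed integer seed for the permutation null.
#' @return a `similarity_result`: list with `disease_ids`, `dga`, `pcor`,
#'   `pvals`, `null_store`, `linkage`, `clusters`, `cut_height`, `alpha`.
#' @export
disease_similarity <- function(studies, params = reg_t_params(),
                               n_perm = 100L, alpha = 0.05, seed = 1L) {
  dga <- dga_matrix(studies, params)
  pcor <- partial_correlation(unclass(dga))
  null_store <- permutation_null(studies, params, n_perm, seed,
                                 statistic = "pairwise-pcor")
  pvals <- pair_pvalues(pcor, null_store)
  cl <- cluster_diseases(pcor, null_store, alpha)
  structure(
    list(disease_ids = colnames(pcor), dga = dga, pcor = pcor, pvals = pvals,
         null_store = null_store, linkage = cl$linkage,
         clusters = cl$clusters, cut_height = cl$cut_height,
         null_quantile = cl$null_quantile, alpha = alpha),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  sig <- significant_pairs(x)
  cat(sprintf(
    "<similarity_result> %d diseases, %d/%d significant pairs (alpha=%g), %d clusters\n",
    length(x$disease_ids), nrow(sig),
    choose(length(x$disease_ids), 2), x$alpha,
    length(unique(x$clusters$cluster[x$clusters$clustered]))
  ))
  invisible(x)
}

#' Significant disease pairs of a similarity result
#'
#' @param result a `similarity_result`.
#' @param alpha threshold; defaults to the one used at fit time.
#' @return tibble `disease_a`, `disease_b`, `pcor`, `p_value`.
#' @export
significant_pairs <- function(result, alpha = result$alpha) {
  ut <- upper.tri(result$pcor)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    disease_a = rownames(result$pcor)[idx[, 1]],
    disease_b = colnames(result$pcor)[idx[, 2]],
    pcor = result$pcor[ut],
    p_value = result$pvals[ut]
  ) |>
    dplyr::filter(.data$p_value < alpha) |>
    dplyr::arrange(.data$p_value, .data$disease_a, .data$disease_b)
}
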