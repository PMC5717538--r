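#' Hyperparameters of the regularized t-statistic
#'
#' The differential gene activity (DGA) score is a two-sample t-statistic
#' whose per-arm variances are shrunk toward a "background" variance
#' estimated from genes of similar expression level. Two knobs control the
#' shrinkage: the window `w` of rank-neighboring genes averaged into the
#' background standard deviation, and the confidence `c`, a pseudo-
#' observation count. Each arm's prior weight is `v0 = max(c - n_arm, 0)`,
#' so well-replicated arms (`n_arm >= c`) get no shrinkage and the score
#' reduces exactly to Welch's t.
#'
#' @param window odd integer, 3 <= window <= number of genes.
#' @param confidence non-negative pseudo-observation count.
#' @return a `reg_t_params` list with elements `window`, `confidence`.
#' @export
reg_t_params <- function(window = 101L, confidence = 10L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    abort_dganet("window must be an odd integer >= 3", "bad_params")
  if (confidence < 0) abort_dganet("confidence must be >= 0", "bad_params")
  structure(list(window = window, confidence = as.numeric(confidence)),
            class = "reg_t_params")
}

prior_weight <- function(params, n_arm) max(params$confidence - n_arm, 0)

#' Background standard deviation by expression rank
#'
#' Genes are ranked by their arm mean (ties broken by gene id); the
#' background sd of a gene is the average of the per-gene sample sds over
#' the `w` genes centered on its rank. Near the ends the window is clamped
#' so it always covers exactly `w` genes.
#'
#' @param arm_matrix genes x samples matrix for one arm (>= 2 samples).
#' @param window odd window width, at most the number of genes.
#' @return named numeric vector of background sds, in input gene order.
#' @export
background_sd <- function(arm_matrix, window) {
  g <- nrow(arm_matrix)
  if (window > g) abort_dganet("window larger than gene count", "bad_params")
  if (ncol(arm_matrix) < 2) abort_dganet("arm needs >= 2 samples", "bad_input")
  means <- rowMeans(arm_matrix)
  sds <- row_sds(arm_matrix)
  ord <- order(means, rownames(arm_matrix) %||% seq_len(g))
  half <- (window - 1L) %/% 2L
  # rolling mean over the rank-ordered sds, window clamped to [1, g]
  cs <- cumsum(c(0, sds[ord]))
  start <- pmin(pmax(seq_len(g) - half, 1L), g - window + 1L)
  bg_ranked <- (cs[start + window] - cs[start]) / window
  bg <- numeric(g)
  bg[ord] <- bg_ranked
  names(bg) <- rownames(arm_matrix)
  bg
}

#' Regularized two-sample t-statistic
#'
#' Per arm the variance is shrunk toward the background:
#' `var_tilde = (v0 * bg^2 + (n - 1) * s^2) / (v0 + n - 1)`, and
#' `t = (m1 - m2) / sqrt(var_tilde1 / n1 + var_tilde2 / n2)`. With
#' `v0 = 0` this is exactly Welch's statistic. Positive values mean the
#' first arm (disease) is up. If both regularized variances vanish the
#' statistic is returned as 0 with attribute `degenerate = TRUE`.
#'
#' @param g1,g2 numeric sample vectors (disease, control), each length >= 2.
#' @param bg1,bg2 background sds for the gene in each arm.
#' @param params a [reg_t_params()].
#' @return a single t value.
#' @export
regularized_t <- function(g1, g2, bg1, bg2, params = reg_t_params()) {
  if (length(g1) < 2 || length(g2) < 2)
    abort_dganet("each arm needs >= 2 samples", "bad_input")
  n1 <- length(g1); n2 <- length(g2)
  v01 <- prior_weight(params, n1); v02 <- prior_weight(params, n2)
  s1 <- stats::sd(g1); s2 <- stats::sd(g2)
  var1 <- (v01 * bg1^2 + (n1 - 1) * s1^2) / (v01 + n1 - 1)
  var2 <- (v02 * bg2^2 + (n2 - 1) * s2^2) / (v02 + n2 - 1)
  den <- sqrt(var1 / n1 + var2 / n2)
  if (den == 0) return(structure(0, degenerate = TRUE))
  (mean(g1) - mean(g2)) / den
}

# Vectorized DGA column for one study: regularized t for every gene at
# once. Shared by the observed scores and the permutation machinery.
dga_column <- function(values, arm_labels, params) {
  x1 <- values[, arm_labels == "disease", drop = FALSE]
  x2 <- values[, arm_labels == "control", drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  v01 <- prior_weight(params, n1); v02 <- prior_weight(params, n2)
  s1 <- row_sds(x1); s2 <- row_sds(x2)
  w <- min(params$window, nrow(values) - (1 - nrow(values) %% 2))
  bg1 <- background_sd(x1, w)
  bg2 <- background_sd(x2, w)
  var1 <- (v01 * bg1^2 + (n1 - 1) * s1^2) / (v01 + n1 - 1)
  var2 <- (v02 * bg2^2 + (n2 - 1) * s2^2) / (v02 + n2 - 1)
  den <- sqrt(var1 / n1 + var2 / n2)
  t <- (rowMeans(x1) - rowMeans(x2)) / den
  t[den == 0] <- 0
  t
}

#' Differential gene activity matrix
#'
#' One column per disease: the regularized t of disease vs. control for
#' every gene of the shared universe. All studies must already be
#' restricted to a common gene universe (see [intersect_genes()]).
#'
#' @param studies list of [expression_study()] objects, one per disease,
#'   sharing identical gene rownames.
#' @param params a [reg_t_params()].
#' @return a `dga_matrix`: genes x diseases numeric matrix (S3 class on
#'   top of `matrix`) with dimnames.
#' @export
dga_matrix <- function(studies, params = reg_t_params()) {
  stopifnot(length(studies) >= 1)
  genes <- rownames(studies[[1]]$values)
  for (s in studies) {
    if (!identical(rownames(s$values), genes))
      abort_dganet("studies do not share a gene universe; run intersect_genes()",
                   "bad_input")
    if (length(unique(s$samples$arm)) < 2)
      abort_dganet(sprintf("study '%s' is missing an arm", s$disease_id),
                   "bad_input")
  }
  scores <- vapply(
    studies,
    function(s) dga_column(s$values, s$samples$arm, params),
    numeric(length(genes))
  )
  dimnames(scores) <- list(genes,
                           vapply(studies, `[[`, character(1), "disease_id"))
  structure(scores, class = c("dga_matrix", class(scores)))
}

#' @export
print.dga_matrix <- function(x, ...) {
  cat(sprintf("<dga_matrix> %d genes x %d diseases\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write a DGA matrix as TSV
#'
#' @param dga a [dga_matrix()].
#' @param path output file; first column `gene_id`, one column per disease.
#' @export
write_dga_matrix <- function(dga, path) {
  readr::write_tsv(tibble::as_tibble(unclass(dga), rownames = "gene_id"), path)
  invisible(dga)
}
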