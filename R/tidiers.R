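#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DGA matrix into long form
#'
#' @param x a [dga_matrix()].
#' @param ... unused.
#' @return tibble `gene`, `disease`, `dga`.
#' @exportS3Method generics::tidy
tidy.dga_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "disease", values_to = "dga")
}

#' Tidy disease-pair similarities
#'
#' @param x a `similarity_result`.
#' @param ... unused.
#' @return tibble `disease_a`, `disease_b`, `pcor`, `p_value`,
#'   `significant`, one row per unordered pair.
#' @exportS3Method generics::tidy
tidy.similarity_result <- function(x, ...) {
  ut <- upper.tri(x$pcor)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    disease_a = rownames(x$pcor)[idx[, 1]],
    disease_b = colnames(x$pcor)[idx[, 2]],
    pcor = x$pcor[ut],
    p_value = x$pvals[ut],
    significant = x$pvals[ut] < x$alpha
  )
}

#' One-row summary of a similarity result
#'
#' @param x a `similarity_result`.
#' @param ... unused.
#' @return tibble with `n_diseases`, `n_pairs`, `n_significant`,
#'   `n_clusters`, `cut_height`, `alpha`, `n_perm`.
#' @exportS3Method generics::glance
glance.similarity_result <- function(x, ...) {
  tibble::tibble(
    n_diseases = length(x$disease_ids),
    n_pairs = choose(length(x$disease_ids), 2),
    n_significant = sum(x$pvals[upper.tri(x$pvals)] < x$alpha),
    n_clusters = length(unique(x$clusters$cluster[x$clusters$clustered])),
    cut_height = x$cut_height,
    alpha = x$alpha,
    n_perm = x$null_store$n_perm
  )
}

#' Tidy module activity scores
#'
#' @param x an `activity_matrix`.
#' @param ... unused.
#' @return tibble `module`, `disease`, `activity`, `p_value`.
#' @exportS3Method generics::tidy
tidy.activity_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$activity, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "disease",
                        values_to = "activity")
  if (!is.null(x$pvals)) {
    pv <- tibble::as_tibble(x$pvals, rownames = "module") |>
      tidyr::pivot_longer(-"module", names_to = "disease",
                          values_to = "p_value")
    out <- dplyr::left_join(out, pv, by = c("module", "disease"))
  }
  out
}

#' One-row summary of an activity matrix
#'
#' @param x an `activity_matrix`.
#' @param alpha significance level for the significant-cell count.
#' @param ... unused.
#' @return tibble with module/disease counts and significant cells.
#' @exportS3Method generics::glance
glance.activity_matrix <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_modules = nrow(x$activity),
    n_diseases = ncol(x$activity),
    n_significant_cells = if (is.null(x$pvals)) NA_integer_
                          else sum(x$pvals < alpha),
    provenance = x$provenance
  )
}

#' Tidy a module set into membership pairs
#'
#' @param x a `module_set`.
#' @param ... unused.
#' @return tibble `module`, `gene`.
#' @exportS3Method generics::tidy
tidy.module_set <- function(x, ...) {
  tibble::tibble(
    module = rep(names(x$modules), lengths(x$modules)),
    gene = unlist(x$modules, use.names = FALSE)
  )
}

#' Heatmap of disease partial correlations
#'
#' Tiles the partial-correlation matrix with significant pairs outlined.
#'
#' @param object a `similarity_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_result <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, disease_a = "disease_b", disease_b = "disease_a")
  )
  ggplot2::ggplot(df2, ggplot2::aes(.data$disease_a, .data$disease_b,
                                    fill = .data$pcor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df2, .data$significant),
                       fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial\ncorrelation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of module activity
#'
#' @param object an `activity_matrix`.
#' @param alpha cells with p below this are marked with a dot.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.activity_matrix <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$disease, .data$module,
                                        fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activity") +
    ggplot2::theme_minimal()
  if ("p_value" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$p_value < alpha), size = 0.8)
  }
  p
}

#' Pooled permutation-null distribution with observed correlations
#'
#' Histogram of the pooled null pairwise correlations with the observed
#' values overlaid as a rug; the dashed line marks the (1 - alpha) null
#' quantile that sets the tree-cut height.
#'
#' @param result a `similarity_result`.
#' @return a ggplot object.
#' @export
plot_null_distribution <- function(result) {
  null_df <- tibble::tibble(value = pooled_null(result$null_store))
  obs_df <- tibble::tibble(value = result$pcor[upper.tri(result$pcor)])
  ggplot2::ggplot(null_df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_rug(data = obs_df, colour = "red") +
    ggplot2::geom_vline(xintercept = result$null_quantile,
                        linetype = "dashed") +
    ggplot2::labs(x = "pairwise partial correlation",
                  y = "permutation count") +
    ggplot2::theme_minimal()
}
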