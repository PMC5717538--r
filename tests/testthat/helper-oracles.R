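# Independent reference implementations used as oracles. These must stay
# naive and unrelated to the code paths they check.

# textbook Welch statistic
welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# first-order partial correlation by the classic recursion (k = 3 only)
pcor_recursion_3 <- function(x) {
  r <- cor(x)
  out <- diag(3)
  combos <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))
  for (cc in combos) {
    i <- cc[1]; j <- cc[2]; z <- cc[3]
    out[i, j] <- out[j, i] <-
      (r[i, j] - r[i, z] * r[j, z]) /
      sqrt((1 - r[i, z]^2) * (1 - r[j, z]^2))
  }
  out
}

# partial correlation as the correlation of least-squares residuals
pcor_residuals <- function(x) {
  k <- ncol(x)
  out <- diag(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    z <- x[, -c(i, j), drop = FALSE]
    ri <- if (ncol(z) > 0) residuals(lm(x[, i] ~ z)) else x[, i]
    rj <- if (ncol(z) > 0) residuals(lm(x[, j] ~ z)) else x[, j]
    out[i, j] <- out[j, i] <- cor(ri, rj)
  }
  out
}

# upper-tail hypergeometric P(X >= ov) by full enumeration of draws
hyper_enum <- function(overlap, size_a, size_b, n_universe) {
  universe <- seq_len(n_universe)
  a_set <- seq_len(size_a)
  draws <- combn(universe, size_b)
  mean(colSums(draws <= size_a) >= overlap)
}

# tiny deterministic compendium helpers
toy_study <- function(disease_id = "D01", genes = paste0("g", 1:6),
                      n_per_arm = 3, seed = 1, batch = NULL) {
  set.seed(seed)
  n <- 2 * n_per_arm
  vals <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sprintf("%s_s%d", disease_id, 1:n)))
  expression_study(
    disease_id, vals,
    tibble::tibble(
      sample_id = colnames(vals),
      arm = rep(c("disease", "control"), each = n_per_arm),
      batch = batch %||% rep("b1", n)
    )
  )
}

# manual perm_null store for module-activity unit tests
fake_module_null <- function(values, module_ids, disease_ids) {
  structure(
    list(statistic = "module-activity", values = values,
         n_perm = dim(values)[1], seed = 0L,
         disease_ids = disease_ids, module_ids = module_ids),
    class = "perm_null"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
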