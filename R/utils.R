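#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#' Used throughout the test suite to score recovery of planted structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Row means/sds without matrixStats; sd uses the n-1 denominator.
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1))
}

# deterministic child seed derivation: keeps all seeds < 2^31
child_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset) * 9973L) %% 2147483647L
}

abort_dganet <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dganet_error"))
}
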