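# Shannon entropy / information gain kernel and its analytic gamma null.
# All entropies are in bits (log base 2). A natural-log version would rescale
# the statistic and the null scale 1/(N ln 2) by the same factor, leaving
# p-values unchanged.

#' Shannon entropy of a discrete count distribution
#'
#' @param counts Nonnegative numeric vector of counts, one per category
#'   level. At least one count must be positive.
#' @return Entropy in bits, in `[0, log2(#nonzero levels)]`. Cells with zero
#'   count contribute nothing (`0 * log 0` is taken as 0).
#' @examples
#' shannon_entropy(c(1, 1))  # 1 bit
#' shannon_entropy(c(5, 0))  # 0 bits
#' @export
shannon_entropy <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L) {
    stop("`counts` must be a nonempty numeric vector")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("`counts` must be nonnegative and free of NA")
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("empty distribution: all counts are zero")
  }
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

# Coerce a contingency_table object or plain matrix to a count matrix
# (rows = levels of X, columns = levels of Y).
as_count_matrix <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else table
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("contingency counts must be nonnegative and free of NA")
  }
  if (sum(counts) <= 0) stop("empty contingency table")
  counts
}

#' Conditional entropy H(Y | X) of a contingency table
#'
#' @param table A [contingency_table()] or a count matrix with rows indexed
#'   by levels of X and columns by levels of Y.
#' @return `sum_i p(X = x_i) H(Y | X = x_i)` in bits. Rows with zero total
#'   contribute 0.
#' @export
conditional_entropy <- function(table) {
  counts <- as_count_matrix(table)
  n <- sum(counts)
  row_tot <- rowSums(counts)
  h <- 0
  for (i in which(row_tot > 0)) {
    h <- h + (row_tot[[i]] / n) * shannon_entropy(counts[i, ])
  }
  h
}

#' Information gain (mutual information) of a contingency table
#'
#' `IG(Y|X) = H(Y) - H(Y|X)`: the reduction in phenotype entropy once the
#' genotype combination is known. Nonnegative and bounded above by
#' `min(H(X), H(Y))`; tiny negative values from floating-point cancellation
#' (within 1e-12) are clamped to 0.
#'
#' @inheritParams conditional_entropy
#' @return Information gain in bits.
#' @export
information_gain <- function(table) {
  counts <- as_count_matrix(table)
  ig <- shannon_entropy(colSums(counts)) - conditional_entropy(counts)
  if (ig < 0) {
    if (ig < -1e-12) stop("information gain came out negative beyond tolerance")
    ig <- 0
  }
  ig
}

#' Gamma null distribution of the information gain
#'
#' Under independence of X and Y, `IG(Y|X)` approximately follows a gamma
#' distribution with shape `(|Y|-1)(|X|-1)/2` and scale `1/(N ln 2)`;
#' equivalently `2 N ln2 * IG` is chi-square with `(|X|-1)(|Y|-1)` degrees
#' of freedom.
#'
#' @param n_samples Sample size N behind the table (complete cases).
#' @param levels_x Number of levels of the genotype combination X.
#' @param levels_y Number of levels of the phenotype Y (2 for case-control).
#' @return An object of class `"gamma_null"` with fields `shape`, `scale`,
#'   `n_samples`, `levels_x`, `levels_y`. A single-level X (or Y) gives
#'   shape 0: a constant variable carries no information and its p-value is
#'   defined as 1.
#' @export
gamma_null <- function(n_samples, levels_x, levels_y = 2L) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("`n_samples` must be a positive integer")
  }
  if (levels_x < 1 || levels_y < 1) stop("level counts must be >= 1")
  structure(
    list(
      shape = (levels_y - 1) * (levels_x - 1) / 2,
      scale = 1 / (n_samples * log(2)),
      n_samples = as.integer(n_samples),
      levels_x = as.integer(levels_x),
      levels_y = as.integer(levels_y)
    ),
    class = "gamma_null"
  )
}

#' @export
print.gamma_null <- function(x, ...) {
  cat(sprintf(
    "gamma null of IG: shape %.6g, scale %.6g (N = %d, |X| = %d, |Y| = %d)\n",
    x$shape, x$scale, x$n_samples, x$levels_x, x$levels_y
  ))
  invisible(x)
}

#' Upper-tail p-value of an observed information gain
#'
#' Survival probability `P(Gamma(shape, scale) >= ig)` under the analytic
#' null, computed as an upper tail directly (not `1 - CDF`) so far-tail
#' precision is preserved.
#'
#' @param ig Observed information gain in bits (vectorized). Values in
#'   `[-1e-12, 0)` are clamped to 0; more negative values are an error.
#' @param null A [gamma_null()] object.
#' @return P-values in `[0, 1]`. Degenerate shape 0 returns 1.
#' @export
ig_pvalue <- function(ig, null) {
  stopifnot(inherits(null, "gamma_null"))
  if (any(is.na(ig))) stop("`ig` contains NA")
  if (any(ig < -1e-12)) stop("`ig` must be nonnegative")
  ig <- pmax(ig, 0)
  if (null$shape <= 0) {
    return(rep(1, length(ig)))
  }
  p <- pgamma(ig, shape = null$shape, scale = null$scale, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

# Vectorized p-value helper used by the scan engines: per-element level
# counts and complete-case sizes. shape 0 (constant X) -> p = 1.
ig_pvalue_vec <- function(ig, n_samples, levels_x, levels_y = 2L) {
  shape <- (levels_y - 1) * (levels_x - 1) / 2
  scale <- 1 / (pmax(n_samples, 1) * log(2))
  p <- ifelse(
    shape <= 0 | n_samples < 1,
    1,
    pgamma(pmax(ig, 0), shape = pmax(shape, 1e-300), scale = scale,
           lower.tail = FALSE)
  )
  pmin(pmax(p, 0), 1)
}

#' Bonferroni adjustment of a p-value
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Number of tests in the family, `m >= 1`.
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("`m` must be a single integer >= 1")
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]")
  }
  pmin(1, m * p)
}
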