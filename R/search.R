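# Search engines: exhaustive enumeration of k-SNP combinations and the
# stepwise forward-selection search for higher-order interactions. Both run
# the same compiled counting/IG kernel, so a combination evaluated by either
# engine gets bit-identical statistics.

#' Joint-genotype contingency table for a SNP combination
#'
#' Tabulates the joint genotype of `snp_indices` (up to `3^k` categories)
#' against case/control status over the complete cases: samples missing any
#' of the k genotypes are excluded, and `n_total` is the complete-case
#' count. Only categories observed with nonzero count are kept as rows.
#'
#' @param g A [genotype_matrix()].
#' @param snp_indices Distinct SNP column indices (the combination).
#' @return An object of class `"contingency_table"`: `counts` (levels_x x 2
#'   matrix, columns control/case), `n_total`, `snp_indices`.
#' @export
contingency_table <- function(g, snp_indices) {
  stopifnot(inherits(g, "genotype_matrix"))
  snp_indices <- as.integer(snp_indices)
  if (anyDuplicated(snp_indices) || any(snp_indices < 1) ||
      any(snp_indices > ncol(g$genotypes))) {
    stop("`snp_indices` must be distinct valid SNP column indices")
  }
  k <- length(snp_indices)
  sub <- g$genotypes[, snp_indices, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  if (!any(complete)) stop("no complete cases for this SNP combination")
  sub <- sub[complete, , drop = FALSE]
  y <- g$phenotype[complete]
  # joint genotype code, first SNP most significant (base-3)
  code <- as.vector(sub %*% 3^((k - 1):0))
  lab <- apply(sub, 1L, paste, collapse = "/")
  seen <- !duplicated(code)
  level_order <- order(code[seen])
  codes_u <- code[seen][level_order]
  labs_u <- unname(lab[seen][level_order])
  counts <- matrix(0L, nrow = length(codes_u), ncol = 2,
                   dimnames = list(labs_u, c("control", "case")))
  idx <- match(code, codes_u)
  for (i in seq_along(code)) {
    counts[idx[i], y[i] + 1L] <- counts[idx[i], y[i] + 1L] + 1L
  }
  structure(
    list(counts = counts, n_total = nrow(sub), snp_indices = snp_indices),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency table for SNPs %s (n = %d complete cases)\n",
              paste(x$snp_indices, collapse = ", "), x$n_total))
  print(x$counts)
  invisible(x)
}

# Run the compiled kernel on a combos matrix (k x C, 1-based) and return
# ig/levels/n vectors.
combo_scan <- function(g, combos) {
  storage.mode(combos) <- "integer"
  combo_scan_cpp(g$genotypes, g$phenotype, combos)
}

# All-pairs kernel; results ordered as combn(M, 2) columns.
pair_scan <- function(g) {
  pair_scan_cpp(g$genotypes, g$phenotype)
}

# Assemble a ranked results data frame from kernel output.
build_results <- function(g, combos, scan, m_tests, levels_mode) {
  k <- nrow(combos)
  lev_used <- if (levels_mode == "theoretical") {
    rep.int(3L^k, ncol(combos))
  } else {
    scan$levels
  }
  if (any(is.na(scan$ig))) {
    stop("combination(s) with empty complete-case set encountered")
  }
  p_raw <- ig_pvalue_vec(scan$ig, scan$n, lev_used)
  ids <- g$snp_meta$id
  res <- data.frame(
    snp_ids = apply(combos, 2L, function(ix) paste(ids[ix], collapse = ";")),
    snp_indices = apply(combos, 2L, paste, collapse = ";"),
    order = rep.int(k, ncol(combos)),
    ig_bits = scan$ig,
    levels_x = lev_used,
    n_complete = scan$n,
    p_raw = p_raw,
    p_adjusted = pmin(1, m_tests * p_raw),
    m_tests = rep.int(as.integer(m_tests), ncol(combos)),
    stringsAsFactors = FALSE
  )
  rank_results(res)
}

#' Rank interaction results
#'
#' Stable sort by raw p-value ascending, then information gain descending,
#' then SNP indices lexicographically, so runs are reproducible and ties
#' break deterministically.
#'
#' @param results A results data frame.
#' @return The same data frame, reordered.
#' @export
rank_results <- function(results) {
  if (nrow(results) == 0L) return(results)
  key <- vapply(
    strsplit(results$snp_indices, ";", fixed = TRUE),
    function(ix) paste(sprintf("%08d", as.integer(ix)), collapse = ";"),
    ""
  )
  ord <- order(results$p_raw, -results$ig_bits, key, method = "radix")
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive scan over all k-SNP combinations
#'
#' Evaluates information gain and its analytic gamma p-value for every
#' `choose(M, order)` combination of the M SNPs, then Bonferroni-adjusts by
#' the number of combinations (or `m_tests` if supplied).
#'
#' @param g A [genotype_matrix()].
#' @param order Interaction order k (1 = single-SNP scan).
#' @param alpha Significance level applied to adjusted p-values.
#' @param levels How to count the levels of X for the null: `"observed"`
#'   (default) uses the number of joint-genotype categories actually seen,
#'   adapting the degrees of freedom to sparse tables; `"theoretical"` uses
#'   `3^k` regardless.
#' @param m_tests Optional override of the Bonferroni family size.
#' @param keep_all If `TRUE`, return every combination rather than only
#'   those with `p_adjusted < alpha`.
#' @return A ranked data frame with one row per (significant) combination:
#'   `snp_ids`, `snp_indices`, `order`, `ig_bits`, `levels_x`, `n_complete`,
#'   `p_raw`, `p_adjusted`, `m_tests`.
#' @export
scan_exhaustive <- function(g, order = 2L, alpha = 0.05,
                            levels = c("observed", "theoretical"),
                            m_tests = NULL, keep_all = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  levels <- match.arg(levels)
  order <- as.integer(order)
  m_snps <- ncol(g$genotypes)
  if (order < 1L) stop("`order` must be >= 1")
  if (order > m_snps) stop("`order` exceeds the number of SNPs")
  combos <- combn(m_snps, order)
  scan <- if (order == 2L) pair_scan(g) else combo_scan(g, combos)
  m <- if (is.null(m_tests)) ncol(combos) else m_tests
  res <- build_results(g, combos, scan, m, levels)
  if (!keep_all) res <- res[res$p_adjusted < alpha, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Stepwise forward search for higher-order interactions
#'
#' Forward selection over interaction order: (1) evaluate all M single SNPs;
#' (2) retain combinations with raw p-value below the threshold `t`;
#' (3) extend every retained combination by each SNP not already in it and
#' evaluate the extensions (each distinct set once, even when reachable from
#' several parents); (4) if any extension passes the threshold, advance the
#' order and repeat from the passing set. The search stops at `max_order` or
#' when no combination passes. All combinations passing the threshold are
#' carried forward in rank order, so no ranked candidate is left untried
#' before termination.
#'
#' Bonferroni adjustment at each order uses, by default, the number of IG
#' evaluations actually performed at that order (`m_mode = "adaptive"`);
#' `m_mode = "fixed"` uses `choose(M, k)` for comparability with the
#' exhaustive scan.
#'
#' @param g A [genotype_matrix()].
#' @param max_order Highest interaction order to consider (>= 2).
#' @param threshold Raw p-value threshold `t` in `(0, 1]` for carrying a
#'   combination forward.
#' @param alpha Significance level applied to adjusted p-values.
#' @param levels See [scan_exhaustive()].
#' @param m_mode `"adaptive"` or `"fixed"` Bonferroni family size.
#' @param keep_all If `TRUE`, `results` contains every evaluated
#'   combination, not only the significant ones.
#' @return A list with `results` (ranked data frame as in
#'   [scan_exhaustive()], all orders pooled) and `state`: `evaluated_count`
#'   (total IG evaluations), `h_k` (number of combinations over the
#'   threshold at each order), `m_per_order`, `orders_reached`.
#' @export
scan_stepwise <- function(g, max_order = 4L, threshold = 0.05, alpha = 0.05,
                          levels = c("observed", "theoretical"),
                          m_mode = c("adaptive", "fixed"), keep_all = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  levels <- match.arg(levels)
  m_mode <- match.arg(m_mode)
  if (threshold <= 0 || threshold > 1) stop("`threshold` must lie in (0, 1]")
  max_order <- as.integer(max_order)
  if (max_order < 2L) stop("`max_order` must be >= 2")
  m_snps <- ncol(g$genotypes)

  eval_order <- function(combos) {
    scan <- combo_scan(g, combos)
    k <- nrow(combos)
    m <- if (m_mode == "fixed") choose(m_snps, k) else ncol(combos)
    build_results(g, combos, scan, m, levels)
  }

  # order 1: all single SNPs
  res1 <- eval_order(matrix(seq_len(m_snps), nrow = 1L))
  all_res <- list(res1)
  evaluated_count <- m_snps
  pass <- res1[res1$p_raw < threshold, , drop = FALSE]
  h_k <- c(nrow(pass))
  m_per_order <- c(res1$m_tests[1])
  frontier <- lapply(strsplit(pass$snp_indices, ";", fixed = TRUE), as.integer)
  k <- 1L

  while (k < max_order && length(frontier) > 0L) {
    # all one-SNP extensions of the frontier, each distinct set once
    ext <- unlist(lapply(frontier, function(f) {
      lapply(setdiff(seq_len(m_snps), f), function(s) sort(c(f, s)))
    }), recursive = FALSE)
    keys <- vapply(ext, paste, "", collapse = ";")
    ext <- ext[!duplicated(keys)]
    if (length(ext) == 0L) break
    combos <- do.call(cbind, ext)
    res_k <- eval_order(combos)
    evaluated_count <- evaluated_count + ncol(combos)
    all_res <- c(all_res, list(res_k))
    pass_k <- res_k[res_k$p_raw < threshold, , drop = FALSE]
    h_k <- c(h_k, nrow(pass_k))
    m_per_order <- c(m_per_order, res_k$m_tests[1])
    frontier <- lapply(strsplit(pass_k$snp_indices, ";", fixed = TRUE),
                       as.integer)
    k <- k + 1L
  }

  results <- rank_results(do.call(rbind, all_res))
  if (!keep_all) {
    results <- results[results$p_adjusted < alpha, , drop = FALSE]
    rownames(results) <- NULL
  }
  list(
    results = results,
    state = list(
      evaluated_count = evaluated_count,
      h_k = h_k,
      m_per_order = m_per_order,
      orders_reached = length(h_k),
      threshold = threshold
    )
  )
}
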