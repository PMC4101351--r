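# Independent brute-force oracles against which the scan engines are
# checked. These deliberately avoid the package's own entropy/IG routines:
# IG is computed from the direct mutual-information formula
# sum_ij p_ij log2(p_ij / (p_i. p_.j)) on a table() cross-tabulation, and
# p-values come from the chi-square identity rather than the gamma tail.

oracle_ig <- function(genotypes, phenotype, snp_indices) {
  sub <- genotypes[, snp_indices, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  sub <- sub[complete, , drop = FALSE]
  y <- phenotype[complete]
  joint <- apply(sub, 1L, paste, collapse = "-")
  tab <- table(factor(joint), factor(y, levels = 0:1))
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  list(ig = s, levels = sum(rowSums(tab) > 0), n = n)
}

# Chi-square route to the IG p-value: 2 N ln2 IG ~ chisq with
# df = (|X|-1)(|Y|-1).
oracle_pvalue <- function(ig, n, levels_x, levels_y = 2) {
  df <- (levels_x - 1) * (levels_y - 1)
  if (df <= 0) return(1)
  pchisq(2 * n * log(2) * ig, df = df, lower.tail = FALSE)
}

# Full brute-force exhaustive scan: every combination enumerated and ranked
# independently of the package's engines.
oracle_scan <- function(g, order, m_tests = NULL) {
  combos <- combn(ncol(g$genotypes), order)
  m <- if (is.null(m_tests)) ncol(combos) else m_tests
  rows <- lapply(seq_len(ncol(combos)), function(c) {
    ix <- combos[, c]
    o <- oracle_ig(g$genotypes, g$phenotype, ix)
    p <- oracle_pvalue(o$ig, o$n, o$levels)
    data.frame(snp_indices = paste(ix, collapse = ";"), ig_bits = o$ig,
               levels_x = o$levels, n_complete = o$n, p_raw = p,
               p_adjusted = min(1, m * p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  key <- vapply(strsplit(res$snp_indices, ";", fixed = TRUE),
                function(ix) paste(sprintf("%08d", as.integer(ix)),
                                   collapse = ";"), "")
  res[order(res$p_raw, -res$ig_bits, key, method = "radix"), , drop = FALSE]
}

# Small deterministic genotype matrix with a given missingness pattern.
toy_genotypes <- function(n = 40, m = 6, seed = 42, missing_frac = 0) {
  set.seed(seed)
  geno <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing_frac > 0) {
    drop <- sample(length(geno), round(missing_frac * length(geno)))
    geno[drop] <- NA
  }
  genotype_matrix(geno, rep_len(c(1L, 0L), n))
}
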