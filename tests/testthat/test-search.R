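# Exhaustive and stepwise search engines against brute-force oracles.

test_that("contingency_table tabulates a hand-built 2-SNP fixture", {
  geno <- rbind(
    c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L),
    c(1L, 0L), c(1L, 0L), c(2L, 2L), c(2L, 2L)
  )
  y <- c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L)
  g <- genotype_matrix(geno, y)
  ct <- contingency_table(g, c(1, 2))
  expect_equal(ct$n_total, 8L)
  expect_equal(rownames(ct$counts), c("0/0", "0/1", "1/0", "2/2"))
  expect_equal(unname(ct$counts["0/0", ]), c(1L, 1L))
  expect_equal(unname(ct$counts["0/1", ]), c(2L, 0L))
  expect_equal(unname(ct$counts["1/0", ]), c(0L, 2L))
  expect_equal(unname(ct$counts["2/2", ]), c(1L, 1L))

  # permuting sample order leaves the table unchanged
  perm <- sample(8)
  g2 <- genotype_matrix(geno[perm, ], y[perm])
  expect_equal(contingency_table(g2, c(1, 2))$counts, ct$counts)

  # missing genotypes are excluded as complete cases
  geno_na <- geno; geno_na[1, 2] <- NA
  g3 <- genotype_matrix(geno_na, y)
  expect_equal(contingency_table(g3, c(1, 2))$n_total, 7L)
  expect_error(contingency_table(g, c(1, 1)), "distinct")
})

test_that("a constant SNP yields a single-level table with zero IG and p = 1", {
  g <- genotype_matrix(matrix(0L, 20, 1), rep_len(c(1L, 0L), 20))
  ct <- contingency_table(g, 1)
  expect_equal(nrow(ct$counts), 1L)
  expect_equal(information_gain(ct), 0)
  res <- scan_exhaustive(g, order = 1, keep_all = TRUE)
  expect_equal(res$ig_bits, 0)
  expect_equal(res$p_raw, 1)
})

test_that("exhaustive scan matches the brute-force oracle (orders 1-3, with missing)", {
  g <- toy_genotypes(n = 80, m = 8, seed = 17, missing_frac = 0.05)
  for (k in 1:3) {
    res <- scan_exhaustive(g, order = k, keep_all = TRUE)
    orc <- oracle_scan(g, order = k)
    expect_equal(res$snp_indices, orc$snp_indices)
    expect_equal(res$ig_bits, orc$ig_bits, tolerance = 1e-12)
    expect_equal(res$levels_x, orc$levels_x)
    expect_equal(res$n_complete, orc$n_complete)
    expect_equal(res$p_raw, orc$p_raw, tolerance = 1e-10)
    expect_equal(res$p_adjusted, orc$p_adjusted, tolerance = 1e-10)
  }
})

test_that("a deterministically planted pair ranks first with p_adjusted near 0", {
  set.seed(23)
  geno <- matrix(sample(0:2, 200 * 10, replace = TRUE), 200, 10)
  # phenotype is the indicator of a specific joint-genotype event of SNPs 3, 7
  y <- as.integer(geno[, 3] == 2 | (geno[, 3] == 1 & geno[, 7] >= 1))
  g <- genotype_matrix(geno, y)
  res <- scan_exhaustive(g, order = 2, keep_all = TRUE)
  expect_equal(res$snp_indices[1], "3;7")
  expect_lt(res$p_adjusted[1], 1e-10)
  res_sig <- scan_exhaustive(g, order = 2, alpha = 0.05)
  expect_true("3;7" %in% res_sig$snp_indices)
  expect_equal(nrow(scan_exhaustive(g, order = 2, alpha = 0)), 0L)
})

test_that("rank_results is a stable, idempotent, deterministic ordering", {
  res <- data.frame(
    snp_ids = c("a;b", "c;d", "e;f", "g;h"),
    snp_indices = c("1;2", "3;4", "5;6", "7;8"),
    order = 2L,
    ig_bits = c(0.1, 0.3, 0.2, 0.3),
    levels_x = 9L, n_complete = 100L,
    p_raw = c(0.5, 0.01, 0.01, 0.01),
    p_adjusted = 1, m_tests = 4L,
    stringsAsFactors = FALSE
  )
  ranked <- rank_results(res)
  # ties in p broken by larger IG, then by index order
  expect_equal(ranked$snp_indices, c("3;4", "7;8", "5;6", "1;2"))
  expect_equal(rank_results(ranked), ranked)
  expect_equal(nrow(rank_results(res[0, ])), 0L)
})

test_that("results are invariant to SNP column permutation up to relabeling", {
  g <- toy_genotypes(n = 100, m = 6, seed = 29)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  gp <- genotype_matrix(g$genotypes[, perm], g$phenotype)
  res <- scan_exhaustive(g, order = 2, keep_all = TRUE)
  resp <- scan_exhaustive(gp, order = 2, keep_all = TRUE)
  relabel <- function(sidx) {
    ix <- order(perm)[as.integer(strsplit(sidx, ";", fixed = TRUE)[[1]])]
    paste(sort(ix), collapse = ";")
  }
  expect_setequal(vapply(resp$snp_indices, relabel, ""), res$snp_indices)
  expect_equal(sort(resp$ig_bits), sort(res$ig_bits), tolerance = 1e-12)
})

test_that("stepwise with threshold 1 and max_order 2 degenerates to exhaustive", {
  g <- toy_genotypes(n = 100, m = 10, seed = 31)
  sw <- scan_stepwise(g, max_order = 2, threshold = 1, m_mode = "fixed",
                      keep_all = TRUE)
  ex1 <- scan_exhaustive(g, order = 1, keep_all = TRUE)
  ex2 <- scan_exhaustive(g, order = 2, keep_all = TRUE)
  expect_equal(sw$state$evaluated_count, 10 + choose(10, 2))
  sw2 <- sw$results[sw$results$order == 2, , drop = FALSE]
  rownames(sw2) <- NULL
  expect_equal(sw2$snp_indices, ex2$snp_indices)
  expect_equal(sw2$ig_bits, ex2$ig_bits)
  expect_equal(sw2$p_adjusted, ex2$p_adjusted)
  sw1 <- sw$results[sw$results$order == 1, , drop = FALSE]
  expect_equal(sort(sw1$ig_bits), sort(ex1$ig_bits))
})

test_that("stepwise hits reproduce exhaustive statistics and save evaluations", {
  model <- builtin_model("multiplicative")
  g <- simulate_case_control(model, 200, 200, m_noise_snps = 28, seed = 101)
  sw <- scan_stepwise(g, max_order = 3, threshold = 0.05, keep_all = TRUE)
  for (k in 2:3) {
    swk <- sw$results[sw$results$order == k, , drop = FALSE]
    if (nrow(swk) == 0) next
    exk <- scan_exhaustive(g, order = k, keep_all = TRUE)
    m <- match(swk$snp_indices, exk$snp_indices)
    expect_false(anyNA(m))
    expect_equal(swk$ig_bits, exk$ig_bits[m], tolerance = 0)
  }
  exhaustive_count <- sum(choose(30, 1:3))
  expect_lt(sw$state$evaluated_count, exhaustive_count)
  expect_equal(sw$state$orders_reached, length(sw$state$h_k))
  # adaptive Bonferroni uses the per-order evaluation counts
  expect_true(all(sw$results$m_tests[sw$results$order == 1] == 30))
})

test_that("stepwise usually misses a pure XOR pair (no marginal effects)", {
  model <- builtin_model("xor")
  found_sw <- found_ex <- logical(20)
  for (r in 1:20) {
    g <- simulate_case_control(model, 150, 150, m_noise_snps = 18,
                               seed = 500 + r)
    sw <- scan_stepwise(g, max_order = 2, threshold = 0.05)
    found_sw[r] <- any(sw$results$snp_indices == "1;2")
    ex <- scan_exhaustive(g, order = 2)
    found_ex[r] <- any(ex$snp_indices == "1;2")
  }
  # exhaustive sees the interaction; the marginal screen usually does not
  expect_gt(mean(found_ex), 0.5)
  expect_lt(mean(found_sw), mean(found_ex))
})

test_that("stepwise rejects degenerate thresholds and orders", {
  g <- toy_genotypes(n = 40, m = 5, seed = 37)
  expect_error(scan_stepwise(g, threshold = 0), "threshold")
  expect_error(scan_stepwise(g, max_order = 1), "max_order")
  expect_error(scan_exhaustive(g, order = 6), "exceeds")
})
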