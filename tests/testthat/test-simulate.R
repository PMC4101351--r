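# Penetrance-model simulator: determinism, HWE structure, model registry,
# marginalization.

test_that("null simulation is deterministic under a seed and HWE-consistent", {
  g1 <- simulate_null(50, 100, 100, seed = 7)
  g2 <- simulate_null(50, 100, 100, seed = 7)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_identical(g1$phenotype, g2$phenotype)
  g3 <- simulate_null(50, 100, 100, seed = 8)
  expect_false(identical(g1$genotypes, g3$genotypes))
  expect_equal(sum(g1$phenotype), 100)
  expect_equal(attr(g1, "causal_indices"), integer(0))

  # empirical MAF within 3 binomial SE of the sampled MAF at n = 1000
  g <- simulate_null(40, 500, 500, seed = 11)
  mafs <- attr(g, "mafs")
  emp <- colMeans(g$genotypes) / 2
  se <- sqrt(mafs * (1 - mafs) / (2 * 1000))
  expect_true(all(abs(emp - mafs) <= 3 * se + 1e-12))
  expect_error(simulate_null(10, 100, 100, maf_range = c(0.2, 0.9)), "maf_range")
})

test_that("the model registry knows its fixtures and rejects strangers", {
  expect_error(builtin_model("no-such-model"), "registered models")
  cn <- builtin_model("constant-null", baseline = 0.3)
  expect_true(all(cn$penetrance == 0.3))
  expect_equal(cn$prevalence, 0.3)

  xor <- builtin_model("xor", baseline = 0.1, effect = 0.2)
  cells <- expand.grid(g1 = 0:2, g2 = 0:2)
  expected <- ifelse((cells$g1 + cells$g2) %% 2 == 1, 0.3, 0.1)
  expect_equal(as.numeric(xor$penetrance), expected)

  mult <- builtin_model("multiplicative")
  marg <- marginal_penetrance(mult)
  # marginal risk increases monotonically with dosage at each locus
  expect_true(all(diff(marg[1, ]) > 0))
  expect_true(all(diff(marg[2, ]) > 0))

  expect_error(penetrance_model(rep(0.5, 8), c(0.3, 0.3)), "cells")
  expect_error(penetrance_model(rep(1.5, 9), c(0.3, 0.3)), "\\[0, 1\\]")
  expect_error(penetrance_model(rep(0.5, 9), c(0.3, 0.7)), "0, 0.5")
})

test_that("marginal_penetrance marginalizes over HWE weights", {
  # k = 1: the table itself
  m1 <- penetrance_model(c(0.1, 0.2, 0.7), mafs = 0.3)
  expect_equal(unname(marginal_penetrance(m1)[1, ]), c(0.1, 0.2, 0.7))

  # XOR at MAF 0.5: marginals flat (no main effects); hand value 0.1 + 0.2/2
  xor <- builtin_model("xor", mafs = c(0.5, 0.5), baseline = 0.1, effect = 0.2)
  marg <- marginal_penetrance(xor)
  expect_equal(unname(marg), matrix(0.2, 2, 3))

  # constant model: constant marginals
  cn <- builtin_model("constant-null")
  expect_equal(unname(marginal_penetrance(cn)), matrix(0.1, 2, 3))

  # hand marginalization of an arbitrary table at MAF (0.2, 0.4)
  set.seed(3)
  pen <- runif(9)
  mod <- penetrance_model(pen, mafs = c(0.2, 0.4))
  hw2 <- c(0.6^2, 2 * 0.4 * 0.6, 0.4^2)
  by_hand <- vapply(0:2, function(g1) {
    sum(pen[g1 + 1 + 3 * (0:2)] * hw2)
  }, numeric(1))
  expect_equal(unname(marginal_penetrance(mod)[1, ]), by_hand)
})

test_that("case-control sampling honors quotas, order and determinism", {
  model <- builtin_model("multiplicative")
  g1 <- simulate_case_control(model, 120, 80, m_noise_snps = 10, seed = 5)
  g2 <- simulate_case_control(model, 120, 80, m_noise_snps = 10, seed = 5)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_equal(sum(g1$phenotype == 1), 120)
  expect_equal(sum(g1$phenotype == 0), 80)
  expect_equal(ncol(g1$genotypes), 12)
  expect_equal(attr(g1, "causal_indices"), 1:2)
  expect_error(
    simulate_case_control(penetrance_model(rep(0, 9), c(0.3, 0.3)), 10, 10,
                          max_draws = 1e4),
    "too rare"
  )
})

test_that("constant penetrance gives no genotype-phenotype association", {
  model <- builtin_model("constant-null", baseline = 0.5)
  g <- simulate_case_control(model, 300, 300, seed = 13)
  res <- scan_exhaustive(g, order = 2, keep_all = TRUE)
  expect_gt(res$p_raw[1], 1e-3)  # nothing extreme between the two causal slots
  # genotype distribution of each causal SNP similar in cases vs controls
  for (j in 1:2) {
    tab <- table(g$genotypes[, j], g$phenotype)
    expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
  }
})

test_that("population draws reproduce cell penetrances and HWE frequencies", {
  model <- builtin_model("xor", mafs = c(0.5, 0.5))
  pop <- simulate_population(model, 20000, seed = 17)
  # MAF 0.5 HWE: genotype frequencies ~ (0.25, 0.5, 0.25)
  freq <- table(pop$genotypes[, 1]) / 20000
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.03)
  # empirical penetrance per cell within 3 SE of the table
  pen <- as.numeric(model$penetrance)
  for (cell in unique(pop$cell)) {
    sel <- pop$cell == cell
    n_cell <- sum(sel)
    if (n_cell < 50) next
    se <- sqrt(pen[cell] * (1 - pen[cell]) / n_cell)
    expect_lt(abs(mean(pop$status[sel]) - pen[cell]), 3 * se + 1e-9)
  }
})

test_that("penetrance tables round-trip through TSV", {
  model <- builtin_model("multiplicative", mafs = c(0.2, 0.4))
  path <- tempfile(fileext = ".tsv")
  write_penetrance_tsv(model, path)
  back <- read_penetrance_tsv(path, mafs = c(0.2, 0.4))
  expect_equal(back$penetrance, model$penetrance, tolerance = 1e-12)
  expect_equal(back$prevalence, model$prevalence, tolerance = 1e-12)
})

test_that("distinct seeds give effectively independent replicates", {
  g1 <- simulate_null(200, 100, 100, seed = 1)
  g2 <- simulate_null(200, 100, 100, seed = 2)
  s1 <- scan_exhaustive(g1, order = 1, keep_all = TRUE)
  s2 <- scan_exhaustive(g2, order = 1, keep_all = TRUE)
  # align by SNP index (results come ranked by p-value)
  ig1 <- s1$ig_bits[order(as.integer(s1$snp_indices))]
  ig2 <- s2$ig_bits[order(as.integer(s2$snp_indices))]
  # 200 independent SNPs per replicate: cor should be ~0 (SE ~ 1/sqrt(200))
  expect_lt(abs(cor(ig1, ig2)), 0.2)
})
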