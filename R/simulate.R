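# Penetrance-model case-control simulator. Genotypes are drawn independently
# per SNP under Hardy-Weinberg equilibrium; disease status follows the
# penetrance of the joint causal genotype; case/control quotas are filled by
# rejection sampling from that population model. Noise SNPs carry no
# association by construction. No linkage disequilibrium is simulated.

#' Construct a k-locus penetrance model
#'
#' A penetrance model is a `3^k` table of disease probabilities indexed by
#' the joint minor-allele dosage of k causal loci, together with the loci's
#' minor allele frequencies.
#'
#' @param penetrance Numeric vector of length `3^k` or a k-dimensional
#'   `3 x 3 x ...` array of probabilities in `[0, 1]`. The vector layout has
#'   the first locus varying fastest: entry `1 + g1 + 3*g2 + ...` is the
#'   cell for dosages `(g1, g2, ...)`.
#' @param mafs Minor allele frequencies of the k causal loci, in `(0, 0.5]`.
#' @param label Optional model name carried in outputs.
#' @return An object of class `"penetrance_model"` with fields `k`,
#'   `penetrance` (array of dim `rep(3, k)`), `mafs`, `label`, `prevalence`
#'   (population disease probability implied by the table under HWE).
#' @export
penetrance_model <- function(penetrance, mafs, label = NULL) {
  k <- length(mafs)
  if (k < 1L) stop("at least one locus is required")
  if (any(mafs <= 0) || any(mafs > 0.5)) stop("`mafs` must lie in (0, 0.5]")
  pen <- as.numeric(penetrance)
  if (length(pen) != 3^k) {
    stop(sprintf("`penetrance` must have 3^%d = %d cells", k, 3^k))
  }
  if (any(is.na(pen)) || any(pen < 0) || any(pen > 1)) {
    stop("penetrance entries must lie in [0, 1]")
  }
  pen <- array(pen, dim = rep(3L, k))
  w <- cell_weights(mafs)
  structure(
    list(k = k, penetrance = pen, mafs = mafs, label = label,
         prevalence = sum(pen * w)),
    class = "penetrance_model"
  )
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("penetrance model%s: %d locus/loci, MAF %s, prevalence %.4f\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$k, paste(format(x$mafs), collapse = "/"), x$prevalence))
  invisible(x)
}

# HWE genotype probabilities (p^2, 2pq, q^2) for minor allele frequency q,
# indexed by minor-allele dosage 0/1/2.
hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# Joint HWE probability of every penetrance cell, as an array dim rep(3, k).
cell_weights <- function(mafs) {
  w <- hwe_probs(mafs[1])
  for (l in seq_along(mafs)[-1]) w <- outer(w, hwe_probs(mafs[l]))
  array(w, dim = rep(3L, length(mafs)))
}

#' Built-in penetrance model fixtures
#'
#' Representative two-locus parameterizations of the model families commonly
#' used in epistasis simulation studies; all parameters are user-overridable
#' and arbitrary tables can be supplied to [penetrance_model()] directly
#' (or loaded from TSV with [read_penetrance_tsv()]).
#'
#' * `"xor"` — pure interaction with no marginal effects at MAF 0.5:
#'   penetrance `baseline + effect` where the summed dosage is odd,
#'   `baseline` elsewhere.
#' * `"multiplicative"` — disease odds `baseline_odds * (1 + effect)^(g1*g2)`:
#'   an interaction with clear marginal effects.
#' * `"additive"` — penetrance `baseline + effect * (g1 + g2)/4` (capped at
#'   1): main effects only, no interaction beyond them.
#' * `"constant-null"` — all cells equal to `baseline`: no association.
#'
#' @param name One of the registered names above.
#' @param mafs MAFs of the two loci (default 0.5 for `"xor"`, 0.4 otherwise).
#' @param baseline Baseline penetrance (`"multiplicative"`: baseline odds).
#' @param effect Effect-size parameter as described per model.
#' @return A [penetrance_model()].
#' @export
builtin_model <- function(name, mafs = NULL, baseline = 0.1, effect = NULL) {
  registry <- c("xor", "multiplicative", "additive", "constant-null")
  if (!name %in% registry) {
    stop("unknown model '", name, "'; registered models: ",
         paste(registry, collapse = ", "))
  }
  g <- expand.grid(g1 = 0:2, g2 = 0:2)  # g1 varying fastest
  pen <- switch(name,
    "xor" = {
      if (is.null(effect)) effect <- 0.2
      baseline + effect * ((g$g1 + g$g2) %% 2)
    },
    "multiplicative" = {
      if (is.null(effect)) effect <- 1.0
      odds <- baseline * (1 + effect)^(g$g1 * g$g2)
      odds / (1 + odds)
    },
    "additive" = {
      if (is.null(effect)) effect <- 0.3
      pmin(1, baseline + effect * (g$g1 + g$g2) / 4)
    },
    "constant-null" = rep(baseline, 9)
  )
  if (is.null(mafs)) mafs <- if (name == "xor") c(0.5, 0.5) else c(0.4, 0.4)
  penetrance_model(pen, mafs, label = name)
}

#' Per-locus marginal penetrance of a model
#'
#' For each locus, the penetrance averaged over the other loci's HWE
#' genotype distribution: `P(disease | g_l = g)`. A model with no marginal
#' effects has all three values equal at every locus.
#'
#' @param model A [penetrance_model()].
#' @return A `k x 3` matrix; row l gives the marginal penetrance of locus l
#'   at dosage 0, 1, 2.
#' @export
marginal_penetrance <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  k <- model$k
  if (k == 1L) {
    return(matrix(as.numeric(model$penetrance), nrow = 1,
                  dimnames = list(NULL, 0:2)))
  }
  cells <- as.matrix(expand.grid(rep(list(0:2), k)))  # locus 1 fastest
  pen <- as.numeric(model$penetrance)
  out <- matrix(0, nrow = k, ncol = 3, dimnames = list(NULL, 0:2))
  for (l in seq_len(k)) {
    w_other <- rep(1, nrow(cells))
    for (j in setdiff(seq_len(k), l)) {
      w_other <- w_other * hwe_probs(model$mafs[j])[cells[, j] + 1L]
    }
    for (gv in 0:2) {
      sel <- cells[, l] == gv
      out[l, gv + 1L] <- sum(pen[sel] * w_other[sel])
    }
  }
  out
}

#' Simulate a population cohort under a penetrance model
#'
#' Draws `n` individuals from the population model directly (HWE genotypes
#' at the model's MAFs, disease status Bernoulli with the cell penetrance),
#' with no case/control quotas. Useful for checking that empirical cell
#' penetrances converge to the table, which case-control sampling would
#' distort.
#'
#' @param model A [penetrance_model()].
#' @param n Number of individuals.
#' @param seed Optional RNG seed.
#' @return A list with `genotypes` (n x k dosage matrix), `status` (0/1)
#'   and `cell` (1-based penetrance cell index per individual).
#' @export
simulate_population <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "penetrance_model"))
  if (n < 1) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  gk <- draw_hwe_genotypes(n, model$mafs)
  cell <- 1L + as.vector(gk %*% 3^(0:(model$k - 1)))
  status <- rbinom(n, 1L, as.numeric(model$penetrance)[cell])
  list(genotypes = gk, status = status, cell = cell)
}

# HWE genotype draw: n x m matrix at per-SNP minor allele frequencies.
draw_hwe_genotypes <- function(n, mafs) {
  m <- length(mafs)
  matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n, ncol = m)
}

new_simulated_dataset <- function(genotypes, phenotype, causal_indices,
                                  seed, model = NULL, mafs = NULL) {
  m <- ncol(genotypes)
  ids <- sprintf("snp%04d", seq_len(m))
  if (length(causal_indices)) {
    ids[causal_indices] <- sprintf("causal%02d", seq_along(causal_indices))
  }
  colnames(genotypes) <- ids
  g <- genotype_matrix(genotypes, phenotype)
  attr(g, "causal_indices") <- as.integer(causal_indices)
  attr(g, "seed") <- seed
  attr(g, "model") <- model
  attr(g, "mafs") <- mafs
  g
}

#' Simulate a null case-control dataset
#'
#' Every SNP is drawn independently under HWE at its own MAF and the
#' phenotype is assigned independently of all genotypes, so any detected
#' association is a false positive. By default MAFs are uniform on
#' `[0.05, 0.5]` (matching the usual MAF >= 5% QC convention).
#'
#' @param m_snps Number of SNPs.
#' @param n_cases,n_controls Sample sizes (phenotype 1 then 0).
#' @param maf_range Range from which per-SNP MAFs are drawn uniformly, or a
#'   function `f(m)` returning m MAFs.
#' @param seed Optional RNG seed for reproducibility.
#' @return A [genotype_matrix()] with attributes `causal_indices`
#'   (`integer(0)`), `mafs` and `seed`.
#' @export
simulate_null <- function(m_snps, n_cases, n_controls,
                          maf_range = c(0.05, 0.5), seed = NULL) {
  if (m_snps < 1) stop("`m_snps` must be >= 1")
  n <- n_cases + n_controls
  if (n < 2) stop("need at least two samples")
  if (!is.null(seed)) set.seed(seed)
  mafs <- if (is.function(maf_range)) {
    maf_range(m_snps)
  } else {
    if (any(maf_range < 0) || any(maf_range > 0.5)) {
      stop("`maf_range` must lie within [0, 0.5]")
    }
    runif(m_snps, maf_range[1], maf_range[2])
  }
  if (any(mafs <= 0) || any(mafs > 0.5)) stop("MAFs must lie in (0, 0.5]")
  genotypes <- draw_hwe_genotypes(n, mafs)
  phenotype <- rep(c(1L, 0L), c(n_cases, n_controls))
  new_simulated_dataset(genotypes, phenotype, integer(0), seed, mafs = mafs)
}

#' Simulate a case-control dataset under a penetrance model
#'
#' Population individuals are drawn as HWE genotypes at the model's MAFs;
#' disease status is Bernoulli with the penetrance of the joint causal
#' genotype; sampling continues (rejection sampling) until the requested
#' case and control quotas are filled. Noise SNPs with no association are
#' appended after the causal loci, which occupy the first k columns.
#'
#' @param model A [penetrance_model()].
#' @param n_cases,n_controls Requested sample sizes.
#' @param m_noise_snps Number of non-causal SNPs appended.
#' @param noise_maf_range MAF range (or sampler function) for noise SNPs.
#' @param seed Optional RNG seed.
#' @param max_draws Safety cap on population draws before giving up (an
#'   all-zero penetrance table with `n_cases > 0` is unsatisfiable).
#' @return A [genotype_matrix()] with attributes `causal_indices = 1:k`,
#'   `model` and `seed`. Cases come first.
#' @export
simulate_case_control <- function(model, n_cases, n_controls,
                                  m_noise_snps = 0,
                                  noise_maf_range = c(0.05, 0.5),
                                  seed = NULL, max_draws = 1e8) {
  stopifnot(inherits(model, "penetrance_model"))
  if (n_cases < 0 || n_controls < 0 || n_cases + n_controls < 1) {
    stop("sample counts must be nonnegative with a positive total")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- model$k
  pen_vec <- as.numeric(model$penetrance)
  cases <- matrix(0L, nrow = 0, ncol = k)
  controls <- matrix(0L, nrow = 0, ncol = k)
  drawn <- 0
  batch <- max(1000L, 4L * (n_cases + n_controls))
  while ((nrow(cases) < n_cases || nrow(controls) < n_controls) &&
         drawn < max_draws) {
    gk <- draw_hwe_genotypes(batch, model$mafs)
    cell <- 1L + as.vector(gk %*% 3^(0:(k - 1)))  # locus 1 fastest
    status <- rbinom(batch, 1L, pen_vec[cell])
    drawn <- drawn + batch
    if (nrow(cases) < n_cases) {
      take <- which(status == 1L)[seq_len(min(sum(status == 1L),
                                              n_cases - nrow(cases)))]
      cases <- rbind(cases, gk[take, , drop = FALSE])
    }
    if (nrow(controls) < n_controls) {
      take <- which(status == 0L)[seq_len(min(sum(status == 0L),
                                              n_controls - nrow(controls)))]
      controls <- rbind(controls, gk[take, , drop = FALSE])
    }
  }
  if (nrow(cases) < n_cases || nrow(controls) < n_controls) {
    stop("could not fill case/control quotas: penetrance model makes the ",
         "requested group(s) too rare")
  }
  causal <- rbind(cases, controls)
  phenotype <- rep(c(1L, 0L), c(n_cases, n_controls))
  if (m_noise_snps > 0) {
    noise_mafs <- if (is.function(noise_maf_range)) {
      noise_maf_range(m_noise_snps)
    } else {
      runif(m_noise_snps, noise_maf_range[1], noise_maf_range[2])
    }
    noise <- draw_hwe_genotypes(nrow(causal), noise_mafs)
    genotypes <- cbind(causal, noise)
  } else {
    genotypes <- causal
  }
  new_simulated_dataset(genotypes, phenotype, seq_len(k), seed, model = model)
}

#' Read a penetrance table from TSV
#'
#' Expected columns: one dosage column per locus (`g1`, `g2`, ...) and a
#' `penetrance` column; all `3^k` joint genotype rows must be present.
#'
#' @param path Input file.
#' @param mafs MAFs of the k loci.
#' @param label Optional model name.
#' @return A [penetrance_model()].
#' @export
read_penetrance_tsv <- function(path, mafs, label = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  if (!"penetrance" %in% colnames(tab)) {
    stop("penetrance TSV must contain a 'penetrance' column")
  }
  k <- length(mafs)
  gcols <- paste0("g", seq_len(k))
  if (!all(gcols %in% colnames(tab))) {
    stop("penetrance TSV must contain dosage columns ",
         paste(gcols, collapse = ", "))
  }
  if (nrow(tab) != 3^k) stop("penetrance TSV must have 3^k rows")
  idx <- 1L + as.vector(as.matrix(tab[, gcols]) %*% 3^(0:(k - 1)))
  if (anyDuplicated(idx)) stop("duplicate joint genotype rows in penetrance TSV")
  pen <- numeric(3^k)
  pen[idx] <- tab$penetrance
  penetrance_model(pen, mafs, label = label)
}

#' Write a penetrance model's table to TSV
#'
#' @param model A [penetrance_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_penetrance_tsv <- function(model, path) {
  stopifnot(inherits(model, "penetrance_model"))
  cells <- expand.grid(rep(list(0:2), model$k))
  colnames(cells) <- paste0("g", seq_len(model$k))
  cells$penetrance <- as.numeric(model$penetrance)
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
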