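# Replicate-level experiment drivers: type-I error on null data, detection
# power under a penetrance model, and stepwise-vs-exhaustive efficiency.
# Replicate r uses seed base_seed + r so reports are reproducible and the
# two scan modes in the efficiency study see identical data.

experiment_report <- function(kind, estimates, config) {
  structure(list(kind = kind, estimates = estimates, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment report: %s (%d replicates)\n", x$kind,
              x$config$n_replicates))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

# Monte-Carlo standard error of a proportion.
mc_se <- function(p_hat, r) sqrt(p_hat * (1 - p_hat) / r)

# Minimum raw pairwise p-value of one dataset plus the family size,
# without materializing a full results data frame.
min_pair_pvalue <- function(g, levels = "observed") {
  m_snps <- ncol(g$genotypes)
  m <- choose(m_snps, 2)
  scan <- pair_scan(g)
  lev <- if (levels == "theoretical") rep.int(9L, m) else scan$levels
  p <- ig_pvalue_vec(scan$ig, scan$n, lev)
  list(min_p = min(p), m = m)
}

#' Type-I error (family-wise error rate) under the null
#'
#' Generates null replicates with [simulate_null()], runs the exhaustive
#' pairwise scan on each, Bonferroni-adjusts by the number of pairs, and
#' estimates the family-wise error rate at each nominal level as the
#' fraction of replicates whose minimum adjusted p-value falls below it.
#'
#' @param n_replicates Number of null replicates.
#' @param m_snps,n_cases,n_controls Per-replicate dimensions.
#' @param alphas Nominal significance levels to evaluate.
#' @param maf_range MAF range for [simulate_null()].
#' @param levels Level-counting mode, see [scan_exhaustive()].
#' @param base_seed Replicate r uses seed `base_seed + r`.
#' @return An `experiment_report` whose `estimates` data frame has columns
#'   `alpha`, `fwer`, `mc_se` (`sqrt(p(1-p)/R)`), `n_replicates`.
#' @export
type1_experiment <- function(n_replicates, m_snps, n_cases, n_controls,
                             alphas = c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                             maf_range = c(0.05, 0.5),
                             levels = "observed", base_seed = 1) {
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  if (any(alphas <= 0) || any(alphas > 1)) stop("`alphas` must lie in (0, 1]")
  min_adj <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    g <- simulate_null(m_snps, n_cases, n_controls, maf_range,
                       seed = base_seed + r)
    mp <- min_pair_pvalue(g, levels)
    min_adj[r] <- min(1, mp$m * mp$min_p)
  }
  # rejection at p <= alpha: ties matter only where clamping to 1 creates
  # mass at exactly 1 (the alpha = 1 edge case)
  fwer <- vapply(alphas, function(a) mean(min_adj <= a), numeric(1))
  experiment_report(
    "type1",
    data.frame(alpha = alphas, fwer = fwer,
               mc_se = mc_se(fwer, n_replicates),
               n_replicates = n_replicates),
    list(n_replicates = n_replicates, m_snps = m_snps, n_cases = n_cases,
         n_controls = n_controls, maf_range = maf_range, levels = levels,
         base_seed = base_seed)
  )
}

# Is the causal combination among the significant results? Exact set match
# on snp_indices by default; lenient mode accepts any significant superset.
detected_causal <- function(results, causal_indices, lenient = FALSE) {
  if (nrow(results) == 0L) return(FALSE)
  hit_sets <- lapply(strsplit(results$snp_indices, ";", fixed = TRUE),
                     as.integer)
  causal <- sort(as.integer(causal_indices))
  if (lenient) {
    any(vapply(hit_sets, function(s) all(causal %in% s), logical(1)))
  } else {
    any(vapply(hit_sets, function(s) identical(sort(s), causal), logical(1)))
  }
}

#' Detection power under a penetrance model
#'
#' Power is the fraction of replicates in which the causal SNP combination
#' itself appears among the results with Bonferroni-adjusted p-value below
#' `alpha` (exact set match; `lenient = TRUE` accepts supersets).
#'
#' @param model A [penetrance_model()].
#' @param n_replicates Number of replicate datasets.
#' @param n_cases,n_controls Per-replicate sample sizes.
#' @param m_noise_snps Non-causal SNPs appended per replicate.
#' @param alpha Significance level on adjusted p-values.
#' @param mode `"exhaustive"` (scan at the model's order) or `"stepwise"`.
#' @param threshold,max_order Stepwise parameters (ignored for exhaustive).
#' @param lenient Accept significant supersets of the causal set.
#' @param base_seed Replicate r uses seed `base_seed + r`.
#' @return An `experiment_report` with `power`, `mc_se` and the evaluation
#'   counts per replicate.
#' @export
power_experiment <- function(model, n_replicates, n_cases, n_controls,
                             m_noise_snps, alpha = 0.05,
                             mode = c("exhaustive", "stepwise"),
                             threshold = 0.05, max_order = NULL,
                             lenient = FALSE, base_seed = 1) {
  mode <- match.arg(mode)
  if (is.null(max_order)) max_order <- max(2L, model$k)
  hits <- logical(n_replicates)
  evals <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    g <- simulate_case_control(model, n_cases, n_controls, m_noise_snps,
                               seed = base_seed + r)
    if (mode == "exhaustive") {
      res <- scan_exhaustive(g, order = model$k, alpha = alpha)
      evals[r] <- choose(ncol(g$genotypes), model$k)
    } else {
      sw <- scan_stepwise(g, max_order = max_order, threshold = threshold,
                          alpha = alpha)
      res <- sw$results
      evals[r] <- sw$state$evaluated_count
    }
    hits[r] <- detected_causal(res, attr(g, "causal_indices"), lenient)
  }
  p_hat <- mean(hits)
  experiment_report(
    "power",
    data.frame(power = p_hat, mc_se = mc_se(p_hat, n_replicates),
               mean_evaluations = mean(evals), n_replicates = n_replicates),
    list(model = model$label, n_replicates = n_replicates,
         n_cases = n_cases, n_controls = n_controls,
         m_noise_snps = m_noise_snps, alpha = alpha, mode = mode,
         threshold = threshold, max_order = max_order, lenient = lenient,
         base_seed = base_seed)
  )
}

#' Stepwise vs exhaustive efficiency
#'
#' Runs both search modes on the same replicate datasets (shared seeds) and
#' reports the ratio of detection powers and the ratio of IG-evaluation
#' counts. Evaluation counts, not wall-clock, make the computation ratio
#' hardware-independent. The exhaustive reference evaluates every
#' combination of every order from 1 to `max_order`.
#'
#' @inheritParams power_experiment
#' @param threshold Stepwise carry-forward threshold `t` on raw first-order
#'   p-values.
#' @return An `experiment_report` with per-mode powers, `power_ratio`
#'   (NA when exhaustive power is 0), and `computation_ratio`.
#' @export
stepwise_efficiency <- function(model, n_replicates, n_cases, n_controls,
                                m_noise_snps, max_order = 2L,
                                threshold = 0.05, alpha = 0.05,
                                base_seed = 1) {
  hits_ex <- logical(n_replicates)
  hits_sw <- logical(n_replicates)
  evals_sw <- numeric(n_replicates)
  m_total <- model$k + m_noise_snps
  evals_ex <- sum(choose(m_total, seq_len(max_order)))
  for (r in seq_len(n_replicates)) {
    g <- simulate_case_control(model, n_cases, n_controls, m_noise_snps,
                               seed = base_seed + r)
    causal <- attr(g, "causal_indices")
    ex <- scan_exhaustive(g, order = model$k, alpha = alpha)
    hits_ex[r] <- detected_causal(ex, causal)
    sw <- scan_stepwise(g, max_order = max_order, threshold = threshold,
                        alpha = alpha)
    hits_sw[r] <- detected_causal(sw$results, causal)
    evals_sw[r] <- sw$state$evaluated_count
  }
  power_ex <- mean(hits_ex)
  power_sw <- mean(hits_sw)
  experiment_report(
    "stepwise_efficiency",
    data.frame(
      power_stepwise = power_sw,
      power_exhaustive = power_ex,
      power_ratio = if (power_ex > 0) power_sw / power_ex else NA_real_,
      mean_evaluations_stepwise = mean(evals_sw),
      evaluations_exhaustive = evals_ex,
      computation_ratio = mean(evals_sw) / evals_ex,
      n_replicates = n_replicates
    ),
    list(model = model$label, n_replicates = n_replicates,
         n_cases = n_cases, n_controls = n_controls,
         m_noise_snps = m_noise_snps, max_order = max_order,
         threshold = threshold, alpha = alpha, base_seed = base_seed)
  )
}
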