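---
title: "Entropy-based scanning for gene-gene interactions: model, searches, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based scanning for gene-gene interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigain)
```

## The statistic

Complex-disease risk can depend on the *joint* genotype at several loci
(epistasis) in ways that single-SNP association scans cannot see. epigain
tests a combination of k SNPs, X, against a binary case-control phenotype,
Y, with the information gain

$$IG(Y \mid X) = H(Y) - H(Y \mid X),$$

the reduction in phenotype entropy once the joint genotype is known. H is
Shannon entropy in bits; each SNP is coded as minor-allele dosage 0/1/2, so
X takes up to $3^k$ levels. IG is zero exactly under independence, grows
with association strength of *any* functional form (no genetic model is
assumed), and is comparable across interaction orders — the properties that
make it attractive as a genome-scale screening statistic.

## The analytic null

Permutation testing is what makes most interaction scans infeasible at
genome scale. Here significance is analytic: under independence,

$$IG(Y \mid X) \;\sim\; \Gamma\!\left(\tfrac{(|Y|-1)(|X|-1)}{2},\;
\frac{1}{N \ln 2}\right)$$

approximately, where N is the number of (complete-case) samples and $|X|$,
$|Y|$ are the level counts. This is the classical likelihood-ratio result
in disguise: $2N\ln 2 \cdot IG$ is the G statistic of the $|X|\times|Y|$
table, asymptotically $\chi^2$ with $(|X|-1)(|Y|-1)$ degrees of freedom,
and dividing a $\chi^2_{df}$ by $2N\ln 2$ gives exactly the gamma above.
`ig_pvalue()` evaluates the upper tail of the gamma directly (never
`1 - CDF`) so far-tail precision survives; the test suite verifies the
chi-square identity to 1e-10 on randomized inputs.

Two conventions matter and are fixed package-wide:

* **Bits everywhere.** Natural-log entropies would scale the statistic and
  the null's scale parameter by the same $\ln 2$, leaving every p-value
  unchanged; bits are used because the scale $1/(N\ln 2)$ is stated on that
  convention.
* **$0\log 0 = 0$**, and IG values in $[-10^{-12}, 0)$ from floating-point
  cancellation are clamped to zero.

### Counting the levels of X

$|X|$ enters the degrees of freedom. The default (`levels = "observed"`)
counts the joint-genotype categories actually present with nonzero count,
adapting the df to sparse tables — with a rare allele pair, the
double-homozygote-minor cell is often empty and a theoretical $3^k$ would
overstate the df. `levels = "theoretical"` restores $3^k$ for users who
want the fixed-df convention. A combination whose X is constant (one
level) has shape 0; its IG is reported as 0 and its p-value as 1, since a
constant variable cannot carry association.

### Missing data

Each combination is evaluated on its own complete cases (samples missing
any of its k genotypes are dropped), and the N in the gamma scale is that
combination's complete-case count — the null must describe the table that
was actually tested.

## The two searches

`scan_exhaustive()` evaluates all $\binom{M}{k}$ combinations, Bonferroni-
adjusting by that count. A compiled counting kernel makes the pairwise scan
(the common genome-scale case) run at roughly $10^5$ pairs per second per
1000 samples on one core; the contract, enforced by test, is exact equality
with a naive brute-force enumeration.

`scan_stepwise()` is the forward search for higher orders: score all single
SNPs; carry forward those with raw $p < t$ (default $t = 0.05$, the
marginal screen used in the reference simulation design); extend each
carried combination by every SNP not already in it, evaluating each
distinct set once; advance the order while anything passes, up to
`max_order` (default 4). Two under-specified points were decided as
follows:

* *Backtracking.* The search carries forward **all** combinations passing
  t in rank order, not just the top one, so "try the next-ranked
  combination" is subsumed: no ranked candidate is ever left untried before
  termination.
* *Threshold scale.* t applies to **raw** p-values (matching the marginal
  screen), while final significance is declared on Bonferroni-adjusted
  p-values. The adjustment at each order uses the number of evaluations
  actually performed there (claiming $\binom{M}{k}$ tests when only a
  subset was run would be dishonest about the family); `m_mode = "fixed"`
  restores $\binom{M}{k}$ for direct comparability with the exhaustive
  scan. A consequence worth knowing: with the adaptive family size the
  stepwise scan can occasionally declare a pair significant that the
  exhaustive scan (with its larger m) does not, so its empirical power can
  exceed the exhaustive power even though its *candidate set* is a subset.

Because both engines share one counting kernel, a combination evaluated by
either produces bit-identical IG, making the soundness property (every
stepwise hit reproduces the exhaustive statistics) testable with zero
tolerance. By construction the stepwise search has no power for
interactions with no marginal effects — its first step is a marginal
screen — and the test suite demonstrates this on XOR data.

## The simulator

`simulate_case_control()` draws population individuals as independent
Hardy-Weinberg genotypes at the model's MAFs, assigns disease by the
penetrance of the joint causal genotype, and fills the case/control quotas
by rejection sampling — the standard mechanism for penetrance-model
case-control studies. Noise SNPs are appended independently of phenotype
with MAFs uniform on [0.05, 0.5], mirroring the usual MAF ≥ 5% QC
convention; `simulate_null()` generates pure-noise datasets the same way
with the phenotype assigned independently (balanced splits by default).
Determinism is per-seed, and the experiment drivers give replicate r the
seed `base_seed + r`, so paired comparisons (stepwise vs exhaustive) see
identical data.

What the simulator deliberately does **not** emulate: linkage
disequilibrium (SNPs are independent), genotyping error, population
structure, covariates, or quantitative phenotypes. Passing tests therefore
establish correctness of the method on idealized panels, not robustness to
real-data confounding.

### Built-in penetrance fixtures

Published epistasis model collections live in supplementary materials of
their papers; rather than hard-coding any, the package accepts arbitrary
$3^k$ tables (`penetrance_model()`, `read_penetrance_tsv()`) and ships
four transparent two-locus fixtures:

| model | penetrance | default MAF | character |
|---|---|---|---|
| `xor` | $0.1 + 0.2\cdot[(g_1+g_2)\ \mathrm{odd}]$ | 0.5 | pure interaction, flat marginals |
| `multiplicative` | odds $0.1\,(1+\theta)^{g_1 g_2}$, $\theta = 1$ | 0.4 | interaction with clear main effects |
| `additive` | $0.1 + 0.3 (g_1+g_2)/4$ | 0.4 | main effects only |
| `constant-null` | all cells 0.1 | 0.4 | no association |

Effect sizes were chosen once from analytic population-IG calculations so
that, at the reference simulation scale of 400 individuals and 50 SNPs,
the multiplicative pair is detectable with high-but-not-saturated power
(population $IG_2 \approx 0.08$ bits, single-locus screen power ≈ 0.99)
and the XOR pair has exactly flat marginals at MAF 0.5
(`marginal_penetrance()` verifies this analytically). They are odds-ratio-2
/ prevalence-10–20% settings of the kind used throughout the epistasis
simulation literature.

## Experiment drivers and their problem sizes

`type1_experiment()` estimates the family-wise error rate: per null
replicate, the minimum Bonferroni-adjusted pairwise p-value is compared to
each nominal level (rejection at $p \le \alpha$, so the clamped mass at
exactly 1 still trips at $\alpha = 1$). The packaged calibration study
uses 300 replicates of 500 SNPs × 1000 balanced samples — about 3.7 × 10⁷
pair tests in ~75 s on one core — with Monte-Carlo standard errors
$\sqrt{\hat p(1-\hat p)/R}$ reported alongside.

`power_experiment()` counts a replicate as a detection only when the exact
causal set is significant (a superset is not a detection of *that*
interaction; `lenient = TRUE` relaxes this). `stepwise_efficiency()` runs
both engines on shared seeds and reports the power ratio and the ratio of
IG-evaluation counts — evaluation counts, not wall-clock, so the figure is
hardware-independent; the exhaustive reference count is
$\sum_{j \le K}\binom{M}{j}$.

## Known limitations

* **Far-tail conservatism of the analytic null.** The gamma approximation
  is empirically excellent through p ≈ 1e-4 (first-order p-values are
  KS-uniform; pooled pairwise tail ratios sit at 1.0), but at the extreme
  depths implied by Bonferroni correction over ~10⁵ pairs (p ≈ 4e-7) the
  true distribution of the statistic at N = 1000 carries less mass than
  the gamma predicts — the statistic is bounded on a finite table, and
  sparse low-MAF cells starve the deep tail first. The packaged
  calibration study accordingly estimates family-wise error *below* the
  nominal level at the larger thresholds (roughly half of nominal at
  0.15–0.30), i.e. the scan is conservative, not anti-conservative, at
  this scale. Users wanting exact far-tail control should permute; the
  point of the analytic null is to make genome-scale screening feasible.
* The HWE QC filter uses the 1-df chi-square goodness-of-fit test in
  controls only (standard practice; an exact-test upgrade would matter
  mainly for very small control panels).
* The stepwise search inherits the marginal-screen blind spot for
  purely epistatic (no-marginal-effect) models; this is a property of the
  algorithm, demonstrated in the tests, not a bug.
* PLINK input is the v1 SNP-major binary layout only; minor-allele
  orientation is recomputed from observed frequencies, and .bim allele
  order is metadata, not trusted.

## A worked example

```{r example, eval = FALSE}
model <- builtin_model("multiplicative")
g <- simulate_case_control(model, n_cases = 200, n_controls = 200,
                           m_noise_snps = 48, seed = 1)
hits <- scan_exhaustive(g, order = 2, alpha = 0.05)
head(hits)

sw <- scan_stepwise(g, max_order = 3, threshold = 0.05)
sw$state$evaluated_count   # versus choose(50, 2) + 50 exhaustively
```
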