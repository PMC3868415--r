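---
title: "Design calculations for association and variant-discovery studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design calculations for association and variant-discovery studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasdesign)
```

This vignette explains the models behind each calculator, the conventions
and numerical choices the package commits to, and what its exact
constructions and simulators do and do not demonstrate about real data.

## 1. Gametic LD and its frequency-dependent ceiling

All LD statistics are *gametic*: they are functions of the four haplotype
(gamete) frequencies `p_AB, p_Ab, p_aB, p_ab`, never of diploid genotype
counts. `D = p_AB − p_A p_B` and the indicator correlation
`r = D / sqrt(p_A p_a p_B p_b)`; `r = 1` exactly when
`p_A = p_B = p_AB`. Composite (genotypic) disequilibrium, `D'`,
multi-allelic LD and decay with distance are out of scope.

Given marginal allele frequencies, `p_AB` can only range over the Fréchet
interval `[max(0, p_A + p_B − 1), min(p_A, p_B)]`, so `r²` has a
frequency-dependent supremum. The package makes the usual
"without loss of generality" reduction explicit code:
`allele_freq_pair()` folds each frequency to the minor allele and orders
the loci so `p_B ≤ p_A ≤ 1/2`, recording every swap. In canonical form the
supremum is `(1 − p_A) p_B / [p_A (1 − p_B)]`, attained at the coupling
boundary `p_AB = p_B`; the test suite verifies this against brute-force
maximization of `r²` over a grid of feasible `p_AB`.

Input hygiene: haplotype frequencies must sum to 1 within `1e-9`
(renormalized, with a warning above `1e-12`, the silent band covering
accumulated float rounding); `haplotypes_from_margins()` rejects Fréchet
violations naming the offending bound.

```{r ld}
max_r_squared(1/3, 1/51)
r2_relative(1/3, 1/51, 1/40)
```

## 2. Discovery designs under a folded site-frequency spectrum

A design is `(n, k, c)`: `n` diploid people, a filter requiring each allele
at least `k` times (`1 ≤ k ≤ n`), and a target minor-allele-frequency
cutoff `c`. With independent chromosomes the minor-allele count is
`X ~ Bin(2n, p)`, so the detection probability is
`1 − (1−p)^{2n} − p^{2n}` (evaluated in log space) and the filter passes
with probability `P(k ≤ X ≤ 2n − k)`, computed from binomial
distribution-function differences — the regularized incomplete beta
underneath, never term-by-term summation, so samples up to `n = 1e5` are
safe from overflow and cancellation.

Sensitivity and PPV average this over a folded site-frequency spectrum.
The neutral constant-size model gives density `∝ 1/p` for derived-allele
frequency; folding adds `p` and `1 − p` classes, `1/p + 1/(1−p) =
1/[p(1−p)]` on `(0, 1/2]`. Because only ratios of integrals are used, no
normalization is needed. Numerical choices:

* The pure spectrum mass `∫ dp/[p(1−p)] = logit(b) − logit(a)` is used in
  closed form for the sensitivity denominator.
* The numerator `∫ P_k(p) f(p) dp` uses adaptive quadrature
  (`stats::integrate`, relative tolerance `1e-8`) with the integration
  range split at `p = 1e-3` so the steep near-zero region is handled
  separately.
* The PPV denominator is improper at 0, but `P_k(p) f(p) = O(p^{k−1})`
  there; the integrand is defined analytically at the endpoint (`2n` for
  `k = 1`, `0` for `k ≥ 2`) so the integrator sees a bounded function.
* Finite-population spectra use the grid `p = i/(2N)`, `i = 1..N`, weights
  `1/[p(1−p)]`, with sums replacing integrals; the suite checks
  convergence to the continuous values as `N` grows. Growth-skewed
  spectra enter only through `sfs_custom()`; no demographic inference is
  attempted.

```{r discovery}
d <- sample_design(250, 30, c = 0.05)
c(sensitivity = sensitivity(d), one_minus_ppv = 1 - ppv(d))
```

`roc_sweep()` tabulates the sensitivity/PPV trade-off over `k`, and
`plan_design()` searches for the smallest `(n, k)` meeting joint targets,
exploiting monotonicity of both metrics in `k`. Under any continuous
spectrum, sensitivity is strictly below 1 for finite designs, so
perfection is correctly reported infeasible.

## 3. Exact haplotype models and phenotype maps

`haplotype_table()` stores an explicit finite distribution over
multi-locus haplotypes; every derived quantity (marginals, pairwise `r²`
via collapse to the two-locus engine, phenotype moments, locus–phenotype
correlations, conditional marginals) is an exact weighted enumeration.
Phenotype maps are deterministic — either additive per-allele effects or an
explicit value per haplotype; noise enters only through the samplers.
Haploid semantics are the default; `diploid_additive` models a genotype as
the random union of two independent gametes with summed effects, under
which covariance and both variances double, so locus–phenotype
correlations are unchanged — the package computes diploid moments by these
identities and restricts diploid maps to additive mode.

Three builders reproduce the canonical counterexamples:

* `risk_protective_model(u, v, w, x)` — marker M, risk locus R (+1), and a
  protective locus P (−1) whose allele rides only on the M₁ background.
  With `x = 0` the marker is conditionally independent of the phenotype
  given R and the attenuation identity
  `corr²(M, φ) = r²(M, R) · corr²(R, φ)` holds exactly (tested). With
  `w = x` the marker is *uncorrelated* with the phenotype despite
  `r²(M, R) = 1/3` and R explaining 2/3 of the phenotype variance; with
  `x > w` the sign of the association reverses.
* `shared_marker_model(y)` — a marker allele of frequency `2y` whose
  haplotypes each carry exactly one of two alternative risk alleles. The
  marker is perfectly associated with the phenotype while each causal
  locus has `corr² = (1 − 2y)/[2(1 − y)] < 1`. This closed form is
  validated against the enumeration oracle rather than assumed.
* `epistasis_model()` — four equifrequent haplotypes over causal loci A
  and B, disease iff AB or ab, and a marker C riding exactly on the
  diseased haplotypes: both causal loci have `corr² = 0`, the non-causal
  marker `corr² = 1`. Relabeling B as a binary environmental exposure
  gives the gene–environment version.

## 4. Allelic power and the 1/r² inflation factor

The committed test is the uncorrected 1-df Pearson chi-square on the 2×2
table of case/control allele counts (2n alleles per group); genotypic and
trend tests are out of scope. The default power computation enumerates the
joint distribution of the two binomial allele counts restricted to their
`1e-14` probability windows and sums the rejection region exactly,
conditioning out zero-margin tables just as the simulators do. This was
chosen over the classical noncentral chi-square approximation (retained as
`method = "chisq_ncp"`) after measurement: the approximation's bias
reaches ~0.01 in mid-power regions, an order of magnitude beyond the
Monte-Carlo resolution the suite works at, while enumeration matches
simulation to within sampling error and costs milliseconds. Above 8000
alleles per group the default switches to a two-proportion normal
approximation (null variance on the critical value, alternative variance
on the difference), whose error vanishes in that regime. At
`q_case = q_control` power is reported as exactly `alpha` by convention.
`required_n()` inverts power by geometric bracketing plus integer
bisection.

Retrospective ascertainment is assumed throughout: cases and controls are
i.i.d. draws from the conditional haplotype distributions, with prevalence
entering only through Bayes inversion (`marker_case_control_freqs()`).
`inflation_check()` compares the required sample size at a marker with the
`1/r²` prediction; it accepts only single-locus penetrance models, because
with one causal locus conditional independence holds by construction and
the factor is valid in the small-effect limit (the suite verifies the
ratio within 10% there, and that deviations grow with effect size).
Multi-causal maps are refused with a pointer to the exact machinery — in
those regimes (the risk/protective and epistasis models above) the factor
can fail arbitrarily, including "no finite sample size": the `w = x`
construction has zero marker–phenotype correlation, and the symmetric
+1/−1 contrast yields identical case and control marker frequencies, which
`required_n()` reports as an error rather than a number. A binary
disease coding (`φ = +1` versus the rest) of the same table *does* retain
marker association (`q_case = 1` vs `1/3`); the package exposes both
codings (`marker_case_control_freqs()`, `conditional_marginal()`) rather
than choosing silently.

`joint_false_positive(alpha, m)` is the textbook `alpha^m` for independent
replications (0.05³ = 0.000125), with the independence assumption stated
in its output; correlated-study designs are future work.

## 5. Stratification diagnostics

For subpopulations `(γᵢ, pᵢ, qᵢ)` the exact case/control allele
frequencies follow by Bayes over subpopulation membership, and spurious
association occurs iff the sampling-weighted covariance
`Σγᵢpᵢqᵢ − (Σγᵢpᵢ)(Σγᵢqᵢ)` is nonzero — algebraically equivalent to
`q_case ≠ q_control`, and the only criterion consistent with the
two-subpopulation "both must differ" characterization. The magnitude is
operationalized as `δ = |q_case − q_control|` (labelled
`delta_case_control_freq_diff` in outputs, since the δ of the original
stratification literature is parameterized differently). Scenario
builders A–C reproduce the standard two-subpopulation illustrations
exactly (fractions, not decimals); scenario D, a three-subpopulation set
described in the source literature as unconfounded, actually has
covariance `11/21600 ≠ 0` under this criterion — the builder attaches a
warning rather than silently reclassifying it, and no exactness claims
are made for it.

## 6. Simulators and what the tests show

Every analytic quantity has a seeded Monte-Carlo oracle:
`empirical_rejection_rate()` (vectorized binomial panels, zero-margin
replicates counted separately), `empirical_discovery()` (MAF drawn from
the spectrum, then `Bin(2n, p)`), and `sample_panel()`. Continuous-SFS
sampling uses the exact inverse CDF — the cumulative mass of `1/[p(1−p)]`
is linear in `logit p`, so draws need no grid interpolation — truncated at
`ε = 1e-4` where the spectrum is not integrably summable in practice for
sampling purposes; the truncation affects PPV estimates by less than the
Monte-Carlo error for any `k ≥ 2`. All stochastic output is
bit-reproducible given `sim_config(seed =)`.

The test suite runs its oracles at `1e5` replicates (a few seconds on one
CPU; agreement asserted within 3 Monte-Carlo standard errors), brute-force
grids at `1e4` points, and property loops over hundreds to thousands of
random instances under fixed seeds — sizes chosen so the full suite
completes in well under a minute while leaving the 3-SE bars meaningful.

These are *exact-model* validations: the generators emulate idealized
populations (independent chromosomes, Hardy–Weinberg unions, deterministic
phenotypes, discrete subpopulations, no genotyping error or missingness).
Passing tests therefore demonstrate correctness of the calculations, not
that real studies obey the neutral spectrum, random mating, or clean
ascertainment; in particular, real spectra skewed by population growth
must be supplied via `sfs_custom()`, and continuous admixture is outside
the discrete-subpopulation stratification model.
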