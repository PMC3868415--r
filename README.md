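# gwasdesign

Calculators and seeded simulators for the population-genetic quantities that
drive the design and interpretation of genome-wide association (GWA) and
variant-discovery studies. The package is aimed at statistical geneticists
and methods teaching: every quantity is computed exactly (enumeration or
closed form) or by adaptive quadrature, and every analytic result has a
matching Monte-Carlo oracle.

Four problem areas are covered:

1. **Frequency-dependent bounds on LD.** For gamete frequencies
   `p_AB, p_Ab, p_aB, p_ab`, the correlation between allele indicators is
   `r = D / sqrt(p_A p_a p_B p_b)` with `D = p_AB − p_A p_B`. After folding
   both loci to minor alleles with `p_A ≥ p_B`, `r²` cannot exceed

   ```
   r²max = (1 − p_A) p_B / [p_A (1 − p_B)]
   ```

   which equals 1 only when the minor-allele frequencies match. Raw `r²`
   therefore understates LD between loci of dissimilar frequency;
   `relative_r_squared()` reports the observed fraction of the attainable
   maximum.

2. **Variant-discovery design.** For a sample of `n` people (2n
   chromosomes) and a filter that accepts a site only if each allele is seen
   at least `k` times, the package computes the detection probability
   `1 − (1−p)^{2n} − p^{2n}`, the binomial threshold probability
   `P(k ≤ X ≤ 2n−k)`, and — averaging over a folded site-frequency spectrum
   (neutral constant-size `f(p) ∝ 1/[p(1−p)]`, finite-population, or
   custom) — the sensitivity and positive predictive value (PPV) of the
   design for cataloging loci with minor allele frequency above a cutoff
   `c`, plus threshold sweeps and a smallest-feasible-design search.

3. **Case-control power and the 1/r² inflation factor.** Exact power of the
   uncorrected 1-df allelic chi-square test (enumeration of the two binomial
   allele counts), required sample sizes, and the classical result that
   testing a marker in LD `r²` with a causal locus inflates the required
   sample size by `1/r²`. Exact multi-locus haplotype models
   (`risk_protective_model()`, `shared_marker_model()`, `epistasis_model()`)
   reproduce the constructions in which that factor fails: a marker in
   substantial LD with a strong risk locus yet uncorrelated with the
   phenotype, a non-causal marker more strongly associated than either
   cause, and an epistatic model whose causal loci are invisible to
   single-locus tests.

4. **Population stratification.** For subpopulations with sampling priors
   `γᵢ`, prevalences `pᵢ` and allele frequencies `qᵢ`, case-control
   sampling confounds a locus iff
   `Σγᵢpᵢqᵢ − (Σγᵢpᵢ)(Σγᵢqᵢ) ≠ 0`; the package computes the exact
   case/control frequencies, this covariance, the magnitude
   `|q_case − q_control|`, and simulates the resulting type-I-error
   inflation.

## Worked example

```r
library(gwasdesign)

# Two pairs of loci, observed r² = 1/40 and 1/4.  Which shows "more" LD?
r2_relative(1/3, 1/51, 1/40)   # 0.625  -- 62.5% of its maximum (1/25)
r2_relative(1/3, 1/5,  1/4)    # 0.5    -- only 50% of its maximum (1/2)

# Discovery design: 250 people, each allele seen >= 30 times, target MAF > 0.05
d <- sample_design(250, 30, c = 0.05)
sensitivity(d)                  # 0.933913  -- >93.3% of common loci found
1 - ppv(d)                      # 0.00704   -- 0.7% of accepted loci are rare
sensitivity(sample_design(250, 30, 0.1))  # 0.9999895

# A marker in LD r² = 1/3 with a risk locus explaining 2/3 of the phenotype
# variance -- and yet carrying zero association signal:
mod <- risk_protective_model(u = 1/2, v = 0, w = 1/4, x = 1/4)
pairwise_r2(mod$table, "M", "R")                 # 0.3333333
locus_phenotype_corr2(mod$table, mod$map, "R")   # 0.6666667
locus_phenotype_corr(mod$table, mod$map, "M", "1")  # 0

# Stratification: prevalences AND allele frequencies differ across two
# subpopulations sampled 50/50
s <- strat_scenario("C")
case_control_freqs(s)           # q_case = 0.5, q_control = 0.3518519
confounding_covariance(s)       # 0.01953125 (= 5/256): confounded
```

A thin command-line wrapper is installed at `exec/gwasdesign`
(subcommands `ld`, `discovery`, `power`, `haplo`, `strata`, `simulate`,
`fixtures`; JSON output; see `?toolkit_main`).

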