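---
title: "Allele-sharing estimators of FST and their expected values under migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-sharing estimators of FST and their expected values under migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashfst)
```

## The model

We consider `r` populations of effective sizes `N_i` exchanging migrants
according to a backward migration matrix `M`: `M[i, i']` is the fraction of
alleles in population `i` that resided in population `i'` one generation
earlier, so rows sum to one.  Let `theta[i, i']` be the mean probability of
identity by descent for two alleles in distinct individuals, one in `i` and
one in `i'`, *relative to generation 0*.  Writing
`phi_i = 1/(2 N_i) + (1 - 1/(2 N_i)) theta_i` for the identity of two alleles
drawn with replacement among the parents of population `i`, one generation of
drift, migration and mutation gives

    Theta(t+1) = (1 - mu)^2 * M [ I (1/2N) + (J - I (1/2N)) o Theta(t) ] M^T

(`o` is the elementwise product, `J` the all-ones matrix).  Mutation enters
only through the identity-destroying factor `(1 - mu)^2`; there is no
finite-alleles mutation model.  Because identities are relative to generation
0, the natural initial condition is `Theta(0) = 0`, and that is the default
in `coancestry_trajectory()`; a caller may supply any valid starting state.

Relative coancestries follow by recentring on the mean between-population
value `theta_B`:

    F_ST(t) = (Theta(t) - J theta_B) / (1 - theta_B)

Diagonal entries are population-specific F<sub>ST</sub> values, off-diagonal
entries are population-pair values, and the off-diagonal mean is zero by
construction.  The overall F<sub>ST</sub> is the mean diagonal.  The classical
models are special cases of `M` (builders:
`continent_island_model()`, `finite_island_model()`,
`stepping_stone_model()`, `river_model()`), and the continent-island model
admits the closed-form equilibrium implemented in
`continent_island_equilibrium()`.

Numerical choices:

* A continent is a finite population of `N = 1e9` rather than a symbolic
  infinity, so the same matrix step covers every model.  Its own coancestry
  then creeps upward at about `1/(2N)` per generation; quantities that depend
  on it (e.g. convergence of the islands to the closed form) are accurate to
  about `1e-6` over a few thousand generations, which is far below every
  tolerance used here.
* Rows of `M` must sum to 1 within `1e-12`; models failing this are rejected
  rather than silently renormalised.
* `coancestry_equilibrium()` declares convergence when the largest
  elementwise change per generation falls below `1e-12`, with a hard
  iteration cap.

## The estimators

For dosages `x, y` in `0..k` at a biallelic locus of ploidy `k`, allele
sharing is the match probability of one allele drawn from each individual,
`(x y + (k - x)(k - y)) / k^2` (`pair_sharing()`).  Averaging over loci gives
the individual-level matrix `A` and the population-level matrix `Abar`
(`allele_sharing()`); self-sharing is excluded from the within-population
averages, and populations carry equal weight regardless of sample size.  All
the estimators are ratios of the form `(value - ref) / (1 - ref)`:
`kinship_as()`, `individual_fis()`, `fst_matrix_estimate()`,
`overall_fst_estimate()`, `pairwise_fst_estimate()`, bundled by the fitting
function `fst_as()`.

Design decisions where the definitions leave room:

* **Missing dosages** are handled pairwise-complete: each pair of individuals
  is averaged over the loci both have observed, preserving the per-pair
  expectation; the per-pair counts are kept in `loci_used`.  A pair with no
  jointly observed locus is an error, never an imputation.
* **Monomorphic loci** are kept by default.  Loci fixed for the same allele
  in the whole sample contribute sharing 1 to every pair, which scales the
  numerator and denominator of every ratio estimator identically, so
  estimates are unchanged (this is tested to `1e-12`).  No allele-frequency
  filter is applied by default.
* **Populations with one sampled individual** have no within-population pairs;
  their diagonal entry of `Abar` is `NA` with a warning, and they still
  contribute to between-population entries.
* **Equal population weights** in `Abar` (not sample-size weights) make the
  overall estimate match the Weir-Cockerham estimator exactly when sample
  sizes are equal.  For inbreeding the identity is population-wise: each
  population's allele-sharing F<sub>IS</sub> equals the Weir-Cockerham
  within-population `f` exactly, and the overall value is their unweighted
  mean; pooling the variance components across populations instead weights
  populations by their heterozygosity and differs slightly.  The independent
  oracle `wc_fstats()` reports the population-wise form.
* **Denominators** below `1e-12` (reference value of 1) raise an error rather
  than returning infinities.

## Reference points

Every statistic is relative.  The default reference is the mean
between-population sharing; `set_reference()` re-expresses an `fst_matrix`
relative to the minimum between-population value (all entries then
non-negative, the least related pair pinned at 0), an external constant
`c < 1`, or a percentile of the off-diagonal entries (a robust alternative to
the minimum).  The transforms form a closed affine family and are exactly
invertible; `pairwise_fst_estimate()` is invariant under all of them because
it uses only the pair concerned.  Rankings of diagonal entries *within* one
matrix survive any of these monotone transforms, but rankings *across*
matrices (chromosomes, say) need not, because each matrix is shifted by its
own minimum — a unit test demonstrates the flip on two synthetic matrices.

## The simulator

`simulate.migration_model()` produces unlinked biallelic genotypes.  Each
locus starts from an ancestral frequency drawn uniformly on (0.05, 0.95)
(configurable; the ratio estimators are insensitive to this law because the
common ancestral-homozygosity factor cancels), identical in all populations.
Each generation applies, in order:

1. **binomial drift in every source population**, `Binomial(2 N_k, p_k)/(2 N_k)`
   — gametes are drawn in the sources *before* migration mixes them, which is
   exactly the order in which the recursion applies `phi_k` inside the
   migration double sum; mixing before drifting would instead give sampled
   within-population sharing the previous generation's `phi`, a systematic
   offset of order `2 m theta`;
2. **deterministic migration mixing** `p <- M p`;
3. **symmetric mutation** `p <- p (1 - mu) + (1 - p) mu`.

With this order the expected sharing matrix of a sample is exactly
`hom0 + (1 - hom0) * Theta(t)` (with `hom0` the ancestral homozygosity), so
the estimated F<sub>ST</sub> matrix is unbiased for the predicted one at the
same generation — at any generation, not only at stationarity.  Populations
with `2N >= 1e8` are advanced without drift (per-generation variance below
`5e-9`).  Sampled individuals are independent draws of `Binomial(ploidy, p)`
within their population, so samples larger than `N` are permitted (with a
warning), matching frequency-based metapopulation simulators.  Fixed loci are
kept by default (`polymorphic_only = FALSE`); dropping them provably leaves
every ratio estimator unchanged.

What the simulator does *not* emulate: linkage (all loci independent;
with real, linked SNPs the effective number of markers is smaller and
roughly an order of magnitude more SNPs are needed for comparable precision),
selection, non-equilibrium demography beyond what `M` expresses, and admixed
individuals.  Passing tests therefore demonstrate correctness of the
estimator under the generative model, not robustness to linkage or admixture.

## Verification experiments

The test suite reruns the verification study at desk scale: for the
10-island unequal-size island model, the 10-population stepping stone
(`m = 0.005`; `m = 0.02` is an equally plausible parameterisation of this
system and both are exposed as arguments) and the 14-station river with
asymmetric up/downstream migration, it simulates 20 replicates of 10^4
unlinked SNPs with 50 individuals per population and compares the elementwise
replicate mean of the estimated F<sub>ST</sub> matrix with the recursion
expectation (within 3 standard errors for every element), and checks that the
median elementwise RMSE increases as loci are subsampled (10^4 to 10^3 to
10^2) while subsampling individuals down to 5 per population changes it by
less than a factor 1.5.  The forward simulations run each scenario's time
horizon scaled by one quarter (island 500, stepping stone 1000, river 500
generations): unbiasedness holds generation by generation (the expectation is
computed at the same `t`), so the comparison does not require the full
2000-4000 generations, while the quarter-scale horizons keep the scenarios'
relative differentiation levels and the whole study inside a desk-scale test
run.  The individual-subsampling RMSE ratio does depend on the
differentiation level reached (the lower the differentiation, the smaller the
locus-sampling RMSE base against which individual-sampling noise is
compared), which is why the horizons are scaled proportionally rather than
truncated uniformly.  Bootstrap coverage is checked at reduced size (40
datasets, 99 resamples).

The river model's migration parameters are read as backward (immigration)
fractions: each station receives `m_d = 0.02` of its alleles from each
upstream neighbour and `m_u = 0.005` from each downstream neighbour.  The
sources only state the rates, not the direction convention; only structural
properties of the river matrix (row sums, neighbour pattern) are treated as
exact, and the river's estimator checks are statistical, not numeric.

## Known limitations

* The recursion predicts expectations, not sampling distributions; RMSE and
  confidence intervals come from replication and the block bootstrap.
* The Weir-Cockerham oracle covers diploid, complete-data genotypes only.
* VCF input keeps biallelic SNPs; multi-allelic records are skipped, not
  split.
* Minimum-between (and percentile) references inherit the sampling noise of
  an extreme order statistic; confidence intervals on that scale are wider,
  which is one reason the mean-between scale is the default.
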