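# ashfst

Allele-sharing moment estimators of global, population-specific and
population-pair F<sub>ST</sub>, with a coancestry-recursion engine that
predicts the expected values under any migration model.

## The problem

F<sub>ST</sub> measures genetic differentiation as mean coancestry within
populations relative to mean coancestry between populations.  Coancestries
(probabilities of identity by descent) are only ever estimable *relative to a
reference set of alleles*; the estimators here use Rousset's general form

```
F = (Q_w - Q_b) / (1 - Q_b)
```

with the mean between-population value as the reference.  Beyond the familiar
global F<sub>ST</sub>, each population has its own history, so the package
estimates the full r x r matrix **F**<sub>ST</sub>: the diagonal holds
population-specific values (small, drifted populations have large ones) and
the off-diagonal holds population-pair relative coancestries, whose sign says
whether a pair of populations together captures more (negative) or less
(positive) of the total diversity than a random pair.  The package is aimed at
population geneticists, molecular ecologists and conservation geneticists
working with SNP genotypes from structured samples.

## The estimator

For each pair of individuals, allele sharing at a biallelic locus of ploidy
*k* is the probability that one allele drawn from each matches:
`A = (x*y + (k-x)(k-y)) / k^2` for dosages `x, y` (for diploids: 1 for
identical homozygotes, 0 for opposite homozygotes, 0.5 with any heterozygote).
Averaging over loci gives an individual matrix **A** and a population-level
matrix **Ā** (self-sharing excluded, populations weighted equally).  With
`Ā_B` the mean between-population sharing, the moment estimators are

```
F̂_ST      = (Ā - J Ā_B) / (1 - Ā_B)          # full matrix
F̂_ST^i    = (A^ii - Ā_B) / (1 - Ā_B)          # population-specific (diagonal)
F̂_ST      = mean(diag(F̂_ST))                  # overall; equals Weir-Cockerham
                                               # for equal sample sizes
F̂_STp^ii' = [(A^ii + A^i'i')/2 - A^ii'] / (1 - A^ii')   # pairwise, reference-free
K̂_AS      = (A - J A_B) / (1 - A_B)           # kinship
```

These are unbiased for the corresponding functions of the coancestry matrix
**Θ** predicted by the transition equations

```
Θ(t+1) = (1-μ)^2 · M [ I(1/2N) + (J - I(1/2N)) ∘ Θ(t) ] Mᵀ
F_ST(t) = (Θ(t) - J θ_B) / (1 - θ_B)
```

for a backward migration matrix **M**, effective sizes **N** and mutation rate
μ — implemented in `predict.migration_model()`, with builders for the
continent-island, finite island, stepping stone and river models.

## Worked example

```r
library(ashfst)

mod <- finite_island_model(N = c(100, 1000, 10000), m = 0.002)
predict(mod, generations = 1000)          # expected FST from the recursion
#> FST matrix (expected-from-theory, reference: mean-between)
#>        pop1    pop2    pop3
#> pop1 0.5562  0.0533  0.0285
#> pop2 0.0533  0.0279 -0.0819
#> pop3 0.0285 -0.0819 -0.0972

g <- simulate(mod, seed = 42, loci = 5000, generations = 1000, n = 30)
fit <- fst_as(g)
fit
#> Allele-sharing F-statistics: 90 individuals, 3 populations, 5000 loci
#> Overall FST = 0.1636   Overall FIS = 0.0017
#> Population-specific FST (diagonal of the FST matrix):
#>    pop1    pop2    pop3
#>  0.5585  0.0327 -0.1003
round(fit$fst_pairwise, 4)
#>        pop1   pop2   pop3
#> pop1 0.0000 0.2530 0.2103
#> pop2 0.2530 0.0000 0.0435
#> pop3 0.2103 0.0435 0.0000
```

The smallest population (N = 100) drifts fastest and has the largest
population-specific F<sub>ST</sub> (0.56, expected 0.556); the largest
population's value is negative (−0.10): a random pair of its members shares
*fewer* alleles than a random between-population pair.  Pairwise
F̂<sub>STp</sub> values are always non-negative and reference-free.  The
overall estimate (0.1636) equals the independently coded Weir–Cockerham
estimator on the same data to machine precision because the sample sizes are
equal.

Reference points can be switched after the fact — e.g.
`to_os_reference(fit$fst)` re-expresses the matrix relative to the least
related population pair (all entries then non-negative), and
`from_os_reference()` inverts it exactly.  `block_bootstrap_ci()` gives
percentile confidence intervals from blocks of loci; `wc_fstats()` is the
Weir–Cockerham oracle; `read_vcf()` / `read_dosage_tsv()` load real data.

A thin command-line wrapper over these functions ships in
`inst/cli/ashfst.R` (subcommands `expect`, `simulate`, `estimate`,
`transform`, `fixtures`).

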