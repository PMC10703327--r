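# Replicated simulation studies for the three population structures
# (island, stepping stone, river).  Each study simulates `nrep` datasets of
# `loci` unlinked SNPs with `n` individuals per population after `generations`
# generations, fits the allele-sharing estimators on the full data and on
# locus/individual subsamples, and keeps only the (small) estimated matrices.
# Built lazily and cached for the whole test run; the raw genotype matrices
# are discarded replicate by replicate.
.scenario_cache <- new.env(parent = emptyenv())

# time horizons: the study systems' horizons (2000, 4000, 2000 generations)
# scaled by one quarter; unbiasedness is checked against the expectation at
# the same generation, so the comparison is exact at any horizon
scenario_study <- function(which = c("island", "stepping", "river"),
                           nrep = 20, loci = 1e4, n = 50, generations = NULL) {
  which <- match.arg(which)
  if (is.null(generations))
    generations <- switch(which, island = 500L, stepping = 1000L, river = 500L)
  key <- paste(which, nrep, loci, n, generations, sep = "_")
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])

  model <- switch(which,
                  island = island_scenario(),
                  stepping = stepping_stone_scenario(),
                  river = river_scenario())
  base_seed <- switch(which, island = 101L, stepping = 211L, river = 307L)
  expected <- predict(model, generations = generations)

  fits <- vector("list", nrep)
  fits_l1k <- list()
  fits_l100 <- list()
  fits_i5 <- vector("list", nrep)
  for (rep in seq_len(nrep)) {
    g <- suppressWarnings(simulate(model, seed = base_seed + rep - 1L,
                                   loci = loci, generations = generations,
                                   n = n))
    fits[[rep]] <- fst_as(g)$fst
    for (s in 1:5) {
      fits_l1k[[length(fits_l1k) + 1L]] <-
        fst_as(subsample_loci(g, 1000, seed = rep * 1000L + s))$fst
      fits_l100[[length(fits_l100) + 1L]] <-
        fst_as(subsample_loci(g, 100, seed = rep * 1000L + 500L + s))$fst
    }
    fits_i5[[rep]] <- fst_as(subsample_individuals(g, 5, seed = rep))$fst
    rm(g)
  }
  out <- list(model = model, expected = expected, generations = generations,
              fits = fits, fits_l1k = fits_l1k, fits_l100 = fits_l100,
              fits_i5 = fits_i5)
  .scenario_cache[[key]] <- out
  out
}
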