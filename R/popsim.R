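#' Forward simulation of allele frequencies under a migration model
#'
#' Wright-Fisher simulation of unlinked biallelic loci in a metapopulation.
#' Each locus starts from a common ancestral frequency drawn from `p0`
#' (identical across populations), and each generation consists of
#'
#' 1. binomial drift within every source population `k`:
#'    `p_k <- Binomial(2 N_k, p_k) / (2 N_k)` (gametes are drawn in the
#'    sources, matching the within-population drift term of the coancestry
#'    recursion before migration mixes lineages);
#' 2. deterministic backward-migration mixing `p <- M p`;
#' 3. symmetric mutation `p <- p (1 - mu) + (1 - p) mu`.
#'
#' Populations with `2 N >= 1e8` (e.g. a continent) are advanced without
#' drift; their per-generation drift variance is below `5e-9`.
#'
#' @param model a [migration_model()].
#' @param loci number of independent loci.
#' @param generations number of generations to simulate.
#' @param seed integer seed (required, for reproducibility).
#' @param p0 range of the uniform law for the ancestral allele frequency
#'   (default `c(0.05, 0.95)`, avoiding immediate fixation).
#' @return An r x loci matrix of allele frequencies at the final generation.
#' @export
sim_allele_freqs <- function(model, loci, generations, seed,
                             p0 = c(0.05, 0.95)) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (loci < 1 || generations < 1) stop("'loci' and 'generations' must be >= 1")
  r <- model$r
  two_n <- 2 * model$N
  drift <- two_n < 1e8
  size <- round(two_n[drift])
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- matrix(stats::runif(loci, p0[1], p0[2]), nrow = r, ncol = loci,
              byrow = TRUE)
  mu <- model$mu
  for (g in seq_len(generations)) {
    if (any(drift))
      p[drift, ] <- stats::rbinom(sum(drift) * loci, size, p[drift, ]) / size
    p <- model$M %*% p
    if (mu > 0) p <- p * (1 - mu) + (1 - p) * mu
  }
  rownames(p) <- model$labels
  p
}

#' Sample genotype dosages from population allele frequencies
#'
#' Draws `n` individuals per population; each individual's dosage at a locus
#' is `Binomial(ploidy, p)` (random union of gametes within the population).
#'
#' @param freqs r x loci matrix of allele frequencies (rows = populations).
#' @param n per-population sample sizes (recycled across populations).
#' @param ploidy copies per individual (default 2).
#' @param seed optional integer seed.
#' @return A [geno_data()] object.
#' @export
sample_genotypes <- function(freqs, n, ploidy = 2L, seed = NULL) {
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  r <- nrow(freqs)
  L <- ncol(freqs)
  n <- rep_len(n, r)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pops <- rep(seq_len(r), n)
  X <- matrix(stats::rbinom(sum(n) * L, ploidy, freqs[pops, ]), sum(n), L)
  labs <- rownames(freqs)
  if (is.null(labs)) labs <- paste0("pop", seq_len(r))
  rownames(X) <- paste0(labs[pops], "_", unlist(lapply(n, seq_len)))
  geno_data(X, labs[pops], ploidy)
}

#' Simulate genotype data under a migration model
#'
#' Runs [sim_allele_freqs()] followed by [sample_genotypes()].  With the same
#' seed the result is bit-identical.  The expected FST matrix of the simulated
#' data equals [predict.migration_model()] at the same generation count.
#'
#' @param object a [migration_model()].
#' @param nsim number of replicate datasets.
#' @param seed integer seed (required).  Replicate `i` uses `seed + i - 1`.
#' @param loci number of unlinked biallelic loci (default `1e4`).
#' @param generations generations of forward simulation.
#' @param n per-population sample size(s) (default 50).  Sampling is from the
#'   population gamete frequency, so `n` may exceed `N` (a warning is given).
#' @param ploidy copies per individual (default 2).
#' @param p0 ancestral allele-frequency range.
#' @param polymorphic_only drop loci fixed across the whole sample.  Fixed
#'   loci are harmless for the ratio estimators (they cancel between numerator
#'   and denominator), so the default keeps them.
#' @param ... unused.
#' @return A [geno_data()] object, or a list of them when `nsim > 1`.
#' @examples
#' mod <- finite_island_model(N = c(50, 50), m = 0.01)
#' g <- simulate(mod, seed = 7, loci = 200, generations = 50, n = 10)
#' g
#' @export
simulate.migration_model <- function(object, nsim = 1, seed = NULL,
                                     loci = 10000, generations = 1000,
                                     n = 50, ploidy = 2L,
                                     p0 = c(0.05, 0.95),
                                     polymorphic_only = FALSE, ...) {
  if (is.null(seed)) stop("'seed' is required")
  if (any(rep_len(n, object$r) > object$N))
    warning("sample size exceeds effective size for some population(s); ",
            "samples are drawn from the gamete frequency")
  one <- function(s) {
    freqs <- sim_allele_freqs(object, loci, generations, seed = s, p0 = p0)
    g <- sample_genotypes(freqs, n, ploidy, seed = s + 1013904223L)
    if (polymorphic_only) {
      poly <- apply(g$dosages, 2, function(x) {
        x <- x[!is.na(x)]
        length(unique(x)) > 1 || (length(x) > 0 && x[1] %% ploidy != 0)
      })
      g <- g[, poly]
    }
    g
  }
  if (nsim == 1) return(one(seed))
  lapply(seq_len(nsim), function(i) one(seed + i - 1L))
}
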