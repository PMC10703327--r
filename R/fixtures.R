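#' Two-fixed-populations thought-experiment dataset
#'
#' Constructs the hand-computable dataset in which populations 1 and 2 are
#' fixed for opposite homozygotes at every locus and every other population
#' consists entirely of heterozygotes.  On this dataset the population-level
#' sharing matrix is known exactly: diagonal `(1, 1, 0.5, ..., 0.5)`,
#' off-diagonal 0 for the pair (1,2) and 0.5 everywhere else, so the FST
#' estimators take exact reference values (population 1 and 2 specific FST of
#' 1 on any scale; pairwise FST of 1 for the pair (1,2); and, as the number of
#' populations grows, FST[1,2] tends to -1 on the mean-between scale while all
#' pairs of heterozygote populations tend to 0 there and to 0.5 on the
#' minimum-between scale).
#'
#' @param r number of populations (>= 3).
#' @param n_per_pop individuals per population (default 2).
#' @param loci number of loci (default 10; the data are locus-constant, so any
#'   number gives identical estimates).
#' @return A [geno_data()] object.
#' @export
discussion_genotypes <- function(r, n_per_pop = 2, loci = 10) {
  if (r < 3) stop("'r' must be at least 3")
  dose_of_pop <- c(2, 0, rep(1, r - 2))
  X <- matrix(rep(dose_of_pop, each = n_per_pop), r * n_per_pop, loci)
  geno_data(X, rep(paste0("pop", seq_len(r)), each = n_per_pop), ploidy = 2L)
}

#' Write named fixture files
#'
#' Writes ready-made inputs to `dir`: genotype data (VCF + population map) for
#' the estimator fixtures, or migration-model JSON files for the theory
#' scenarios.
#'
#' Available names: `discussion_r4`, `discussion_r500` (the two-fixed /
#' all-heterozygote construction with 4 or 500 populations),
#' `hwe_panmictic` (one panmictic pool sampled as 4 nominal populations),
#' `island_fig3` (the 10-island unequal-size model), `stepping_fig4` (the
#' 10-population stepping stone), `river_fig2` (the 14-station river).
#'
#' @param name fixture name (see above).
#' @param dir output directory (created if needed).
#' @param seed seed for the stochastic `hwe_panmictic` genotypes.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(name, dir = ".", seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  written <- switch(name,
    discussion_r4 = ,
    discussion_r500 = {
      r <- if (name == "discussion_r4") 4L else 500L
      g <- discussion_genotypes(r)
      write_vcf(g, fp(paste0(name, ".vcf")))
      write_pop_map(g, fp(paste0(name, ".pops.tsv")))
      fp(paste0(name, c(".vcf", ".pops.tsv")))
    },
    hwe_panmictic = {
      old <- get0(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      p <- stats::runif(200, 0.05, 0.95)
      X <- matrix(stats::rbinom(80 * 200, 2, rep(p, each = 80)), 80, 200)
      g <- geno_data(X, rep(paste0("pop", 1:4), each = 20))
      write_vcf(g, fp("hwe_panmictic.vcf"))
      write_pop_map(g, fp("hwe_panmictic.pops.tsv"))
      fp(c("hwe_panmictic.vcf", "hwe_panmictic.pops.tsv"))
    },
    island_fig3 = {
      write_model_json(island_scenario(), fp("island_fig3.model.json"))
      fp("island_fig3.model.json")
    },
    stepping_fig4 = {
      write_model_json(stepping_stone_scenario(), fp("stepping_fig4.model.json"))
      fp("stepping_fig4.model.json")
    },
    river_fig2 = {
      write_model_json(river_scenario(), fp("river_fig2.model.json"))
      fp("river_fig2.model.json")
    },
    stop("unknown fixture name: ", name)
  )
  invisible(written)
}
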