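#' Fit allele-sharing F-statistics to genotype data
#'
#' The package's main estimator.  From a dosage matrix and a population
#' assignment it computes the allele-sharing matrices and every moment
#' estimator derived from them: the kinship matrix, individual and population
#' inbreeding coefficients, the full FST matrix (population-specific values on
#' the diagonal, population-pair relative coancestries off it), the overall
#' FST and the pairwise FST matrix.
#'
#' @param x a [geno_data()] object, or a dosage matrix (individuals x loci,
#'   integers in `0..ploidy`, `NA` for missing).
#' @param pops population assignment, required when `x` is a bare matrix.
#' @param ploidy copies per individual per locus (used only when `x` is a bare
#'   matrix; default 2).
#' @return An object of class `fst_as`: a list with components
#'   `fst` (the [fst_matrix()] estimate), `fst_overall`, `fst_pairwise`,
#'   `kinship`, `F_ind`, `F_is_pop`, `F_is`, `sharing` (the
#'   [allele_sharing()] matrices), `n`, `r`, `n_loci`.
#' @examples
#' mod <- finite_island_model(N = c(100, 100, 100), m = 0.01)
#' g <- simulate(mod, seed = 1, loci = 500, generations = 100, n = 20)
#' fit <- fst_as(g)
#' fit
#' coef(fit)
#' @export
fst_as <- function(x, pops = NULL, ploidy = 2L) {
  g <- if (inherits(x, "geno_data")) x else geno_data(x, pops, ploidy)
  s <- allele_sharing(g)
  f <- fst_matrix_estimate(s)
  fis <- individual_fis(s, singular = "na")
  structure(list(fst = f,
                 fst_overall = overall_fst_estimate(f),
                 fst_pairwise = pairwise_fst_estimate(s),
                 kinship = kinship_as(s),
                 F_ind = fis$F_ind,
                 F_is_pop = fis$F_is_pop,
                 F_is = fis$F_is,
                 sharing = s,
                 n = nrow(g$dosages), r = nlevels(g$pops),
                 n_loci = ncol(g$dosages)),
            class = "fst_as")
}

#' @export
print.fst_as <- function(x, digits = 4, ...) {
  cat("Allele-sharing F-statistics:", x$n, "individuals,", x$r,
      "populations,", x$n_loci, "loci\n")
  cat("Overall FST =", format(round(x$fst_overall, digits)),
      "  Overall FIS =", format(round(x$F_is, digits)), "\n")
  cat("Population-specific FST (diagonal of the FST matrix):\n")
  print(round(diag(x$fst), digits))
  invisible(x)
}

#' @export
summary.fst_as <- function(object, digits = 4, ...) {
  print(object, digits = digits)
  cat("\nFST matrix (mean-between reference):\n")
  print(round(unclass(object$fst), digits))
  cat("\nPairwise FST:\n")
  print(round(object$fst_pairwise, digits))
  cat("\nPer-population FIS:\n")
  print(round(object$F_is_pop, digits))
  invisible(object)
}

#' @export
coef.fst_as <- function(object, ...) {
  c(fst = object$fst_overall, fis = object$F_is)
}

#' @export
plot.fst_as <- function(x, ...) {
  plot(x$fst, ...)
}
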