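#' Root mean square error of FST estimates against their expectation
#'
#' Elementwise RMSE over replicate estimates: the square root of the mean of
#' squared deviations of the estimates from their expected values.
#'
#' @param estimates a list of [fst_matrix()] estimates (replicates), all on
#'   the same reference as `expected`.
#' @param expected the expected [fst_matrix()] (e.g. from
#'   [predict.migration_model()]).
#' @return An object of class `rmse_report`: list with `rmse` (r x r matrix),
#'   `median` (pooled over all elements), `median_diag`, `median_offdiag`, and
#'   `n_replicates`.
#' @export
fst_rmse <- function(estimates, expected) {
  if (inherits(estimates, "fst_matrix")) estimates <- list(estimates)
  refs <- vapply(estimates, attr, "", "reference")
  if (any(refs != attr(expected, "reference")))
    stop("all estimates must share the reference of 'expected'")
  r <- nrow(expected)
  dev2 <- matrix(0, r, r)
  for (e in estimates) {
    if (nrow(e) != r) stop("dimension mismatch among matrices")
    dev2 <- dev2 + (unclass(e) - unclass(expected))^2
  }
  rmse <- sqrt(dev2 / length(estimates))
  dimnames(rmse) <- dimnames(unclass(expected))
  structure(list(rmse = rmse,
                 median = stats::median(rmse[row(rmse) <= col(rmse)]),
                 median_diag = stats::median(diag(rmse)),
                 median_offdiag = stats::median(rmse[row(rmse) < col(rmse)]),
                 n_replicates = length(estimates)),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, digits = 4, ...) {
  cat("RMSE over", x$n_replicates, "replicates\n")
  cat("median (all elements):", format(round(x$median, digits)),
      " diagonal:", format(round(x$median_diag, digits)),
      " off-diagonal:", format(round(x$median_offdiag, digits)), "\n")
  invisible(x)
}

#' Subsample loci or individuals
#'
#' Uniform sampling without replacement; individuals are subsampled within
#' each population.
#'
#' @param g a [geno_data()] object.
#' @param loci number of loci to keep.
#' @param n number of individuals to keep per population.
#' @param seed integer seed.
#' @return A [geno_data()] object.
#' @export
subsample_loci <- function(g, loci, seed) {
  L <- ncol(g$dosages)
  if (loci > L) stop("cannot subsample ", loci, " of ", L, " loci")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g[, sort(sample.int(L, loci))]
}

#' @rdname subsample_loci
#' @export
subsample_individuals <- function(g, n, seed) {
  cnt <- tabulate(g$pops)
  if (n > min(cnt)) stop("cannot subsample ", n,
                         " individuals per population (min available ",
                         min(cnt), ")")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(g$pops), g$pops),
                        function(ix) sort(sample(ix, n))))
  g[sort(unname(keep)), ]
}

#' Block-bootstrap confidence intervals for genome-wide statistics
#'
#' Resamples blocks of loci with replacement and recomputes a statistic per
#' resample, returning percentile intervals.  Blocks are either runs of
#' `block_loci` consecutive loci, or - when positions are available -
#' half-open windows of `block_bp` base pairs (per chromosome when `chrom` is
#' set).
#'
#' @param g a [geno_data()] object.
#' @param statistic function mapping a `geno_data` to a numeric vector (e.g.
#'   `function(g) coef(fst_as(g))`).
#' @param B number of bootstrap resamples (>= 2).
#' @param block_loci number of consecutive loci per block.
#' @param block_bp window span in base pairs (requires `g$positions`).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return A list with `ci` (matrix, one row per statistic, columns lower /
#'   upper), `estimate` (on the full data), `replicates` (B x n_stat matrix),
#'   `n_blocks`.
#' @export
block_bootstrap_ci <- function(g, statistic, B = 200, block_loci = NULL,
                               block_bp = NULL, level = 0.95, seed = 1) {
  if (B < 2) stop("'B' must be at least 2")
  L <- ncol(g$dosages)
  if (is.null(block_loci) == is.null(block_bp))
    stop("give exactly one of 'block_loci' or 'block_bp'")
  if (!is.null(block_bp)) {
    if (is.null(g$positions)) stop("base-pair blocking requires locus positions")
    chrom <- if (is.null(g$chrom)) rep("chr", L) else g$chrom
    key <- paste(chrom, floor(g$positions / block_bp))
    blocks <- split(seq_len(L), key)
  } else {
    blocks <- split(seq_len(L), ceiling(seq_len(L) / block_loci))
  }
  nb <- length(blocks)
  if (nb < 2) stop("fewer than 2 blocks; decrease the block size")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  est <- statistic(g)
  reps <- matrix(NA_real_, B, length(est))
  colnames(reps) <- names(est)
  for (b in seq_len(B)) {
    take <- unlist(blocks[sample.int(nb, nb, replace = TRUE)], use.names = FALSE)
    reps[b, ] <- statistic(g[, take])
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha)))
  list(ci = ci, estimate = est, replicates = reps, n_blocks = nb)
}

#' Weir-Cockerham variance-component F-statistics (oracle)
#'
#' Independent implementation of the classic 1984 variance-component
#' estimators for diploid genotype data without missing values, used as a
#' cross-check of the allele-sharing estimators.  The overall FST is the
#' multilocus ratio of sums `sum(a) / sum(a + b + c)`; FIS is computed within
#' each population from that population's `b` and `c` components
#' (`f = 1 - sum(c)/sum(b + c)`), and the overall FIS is their unweighted mean
#' across populations.  With equal sample sizes these match
#' [overall_fst_estimate()] and [individual_fis()] exactly.
#'
#' @param g a [geno_data()] object, diploid, no missing dosages.
#' @return A list with `fst`, `fis`, `fis_pop`.
#' @export
wc_fstats <- function(g) {
  if (g$ploidy != 2) stop("the Weir-Cockerham oracle covers diploids only")
  X <- g$dosages
  if (anyNA(X)) stop("the Weir-Cockerham oracle requires complete data")
  pops <- g$pops
  r <- nlevels(pops)
  ni <- tabulate(pops)
  nsum <- sum(ni)
  nbar <- mean(ni)
  nc <- (nsum - sum(ni^2) / nsum) / (r - 1)
  # per-population allele frequency and heterozygote frequency, per locus
  P <- rowsum(X, pops) / (2 * ni)          # r x L
  H <- rowsum((X == 1) + 0, pops) / ni     # r x L
  pbar <- colSums(ni * P) / nsum
  hbar <- colSums(ni * H) / nsum
  s2 <- colSums(ni * sweep(P, 2, pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  fst <- sum(a) / sum(a + b + cc)
  # within-population f: single-population variance components
  fis_pop <- vapply(seq_len(r), function(i) {
    p <- P[i, ]; h <- H[i, ]; nn <- ni[i]
    bi <- nn / (nn - 1) * (p * (1 - p) - (2 * nn - 1) / (4 * nn) * h)
    1 - sum(h / 2) / sum(bi + h / 2)
  }, 0)
  names(fis_pop) <- levels(pops)
  list(fst = fst, fis = mean(fis_pop), fis_pop = fis_pop)
}
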