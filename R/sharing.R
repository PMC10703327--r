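#' Allele sharing between two dosages at one locus
#'
#' The probability that one allele drawn uniformly (with replacement) from each
#' of two individuals matches in type, for a biallelic locus of ploidy `k`:
#' `(x*y + (k-x)*(k-y)) / k^2`.  For diploids this reproduces the familiar
#' table: 1 for identical homozygotes, 0 for opposite homozygotes, and 0.5
#' whenever at least one individual is heterozygous.  Applied with `x = y` it
#' gives self-sharing (1 for a diploid homozygote, 0.5 for a heterozygote).
#'
#' @param x,y integer dosages in `0..ploidy` (vectorised, recycled).
#' @param ploidy number of allele copies per individual.
#' @return Numeric vector of sharing values in `[0, 1]`.
#' @examples
#' pair_sharing(c(2, 2, 1, 1), c(2, 0, 2, 1), ploidy = 2)
#' pair_sharing(3, 1, ploidy = 4)
#' @export
pair_sharing <- function(x, y, ploidy = 2) {
  if (any(x < 0 | x > ploidy | y < 0 | y > ploidy, na.rm = TRUE))
    stop("dosages must lie in {0..", ploidy, "}")
  (x * y + (ploidy - x) * (ploidy - y)) / ploidy^2
}

#' Allele-sharing matrices for a genotype dataset
#'
#' Computes the individual-level allele-sharing matrix `A` (pairwise mean of
#' [pair_sharing()] over loci where both dosages are present; the diagonal is
#' self-sharing) and the population-level matrix `Abar` of mean sharing within
#' (self-sharing excluded) and between populations.  All populations carry
#' equal weight in `Abar` regardless of sample size.  Populations with a
#' single sampled individual have no within-population pairs; their diagonal
#' entry of `Abar` is `NA` with a warning.
#'
#' @param g a [geno_data()] object.
#' @return An object of class `sharing_matrices`: a list with
#'   `A` (n x n), `Abar` (r x r), `A_B` (mean off-diagonal of `A`),
#'   `Abar_B` and `Abar_S` (mean off-diagonal and diagonal of `Abar`),
#'   `loci_used` (n x n counts of jointly non-missing loci), `pops`, `ploidy`.
#' @export
allele_sharing <- function(g) {
  if (!inherits(g, "geno_data")) stop("'g' must be a geno_data object")
  X <- g$dosages
  k <- g$ploidy
  n <- nrow(X)
  L <- ncol(X)
  miss <- is.na(X)
  if (any(miss)) {
    Z <- 1 - miss
    X0 <- X; X0[miss] <- 0
    Xk <- k - X; Xk[miss] <- 0
    num <- tcrossprod(X0) + tcrossprod(Xk)
    loci_used <- tcrossprod(Z)
    if (any(loci_used == 0)) {
      bad <- which(loci_used == 0, arr.ind = TRUE)
      bad <- bad[bad[, 1] <= bad[, 2], , drop = FALSE]
      stop("no jointly non-missing loci for pair(s): ",
           paste(apply(bad, 1, function(p)
             paste(rownames(X)[p], collapse = "/")), collapse = ", "))
    }
    A <- num / (k^2 * loci_used)
  } else {
    A <- (tcrossprod(X) + tcrossprod(k - X)) / (k^2 * L)
    loci_used <- matrix(L, n, n)
  }
  dimnames(A) <- list(rownames(X), rownames(X))

  pops <- g$pops
  r <- nlevels(pops)
  idx <- split(seq_len(n), pops)
  Abar <- matrix(NA_real_, r, r, dimnames = list(levels(pops), levels(pops)))
  for (i in seq_len(r)) {
    for (j in i:r) {
      B <- A[idx[[i]], idx[[j]], drop = FALSE]
      if (i == j) {
        if (nrow(B) < 2) next  # single-individual population: left NA
        Abar[i, i] <- mean(B[row(B) != col(B)])
      } else {
        Abar[i, j] <- Abar[j, i] <- mean(B)
      }
    }
  }
  if (anyNA(diag(Abar)))
    warning("population(s) with a single sampled individual: ",
            paste(levels(pops)[is.na(diag(Abar))], collapse = ", "),
            "; within-population sharing undefined")
  off <- Abar[row(Abar) != col(Abar)]
  structure(list(A = A,
                 Abar = Abar,
                 A_B = mean(A[row(A) != col(A)]),
                 Abar_B = mean(off),
                 Abar_S = mean(diag(Abar)),
                 loci_used = loci_used,
                 pops = pops, ploidy = k, n_loci = L),
            class = "sharing_matrices")
}

#' @export
print.sharing_matrices <- function(x, digits = 4, ...) {
  cat("Allele-sharing matrices:", nrow(x$A), "individuals,",
      nlevels(x$pops), "populations,", x$n_loci, "loci\n")
  cat("Population-level mean sharing (Abar):\n")
  print(round(x$Abar, digits))
  cat("Abar_B =", format(x$Abar_B, digits = 6),
      " Abar_S =", format(x$Abar_S, digits = 6), "\n")
  invisible(x)
}

#' Allele-sharing kinship matrix
#'
#' The moment kinship estimator `K = (A - J A_B) / (1 - A_B)`, where `A_B` is
#' the mean of the off-diagonal entries of the individual-level sharing matrix.
#' Its off-diagonal entries average zero by construction; individual
#' inbreeding relative to the whole sample is `2 * K[j, j] - 1`.
#'
#' @param s a `sharing_matrices` object from [allele_sharing()].
#' @return A symmetric n x n matrix with attribute `ref_value = A_B`.
#' @export
kinship_as <- function(s) {
  if (1 - s$A_B < 1e-12)
    stop("singular reference: mean between-individual sharing is 1")
  K <- (s$A - s$A_B) / (1 - s$A_B)
  attr(K, "ref_value") <- s$A_B
  K
}

#' Individual and population inbreeding coefficients
#'
#' Individual inbreeding relative to the individual's own population:
#' `F_j = 2 (A_jj - A_ii) / (1 - A_ii) - 1`, where `A_jj` is self-sharing and
#' `A_ii` the mean between-individual sharing within the population.  The
#' population value `F_IS_i` is the mean over its members, and the overall
#' `F_IS` the unweighted mean over populations.
#'
#' @param s a `sharing_matrices` object from [allele_sharing()].
#' @param singular `"error"` (default) to refuse populations whose
#'   within-population sharing is 1 (every member genetically identical, so
#'   inbreeding relative to the population is undefined), or `"na"` to return
#'   `NA` for them with a warning.
#' @return A list with `F_ind` (per individual), `F_is_pop` (per population)
#'   and `F_is` (overall).
#' @export
individual_fis <- function(s, singular = c("error", "na")) {
  singular <- match.arg(singular)
  pops <- s$pops
  d <- diag(s$A)
  Aii <- diag(s$Abar)[as.integer(pops)]
  sing <- !is.na(Aii) & (1 - Aii < 1e-12)
  if (any(sing)) {
    if (singular == "error")
      stop("singular within-population reference: sharing of 1")
    warning("within-population sharing of 1 for population(s) ",
            paste(unique(as.character(pops)[sing]), collapse = ", "),
            "; their inbreeding coefficients are NA")
    Aii[sing] <- NA_real_
  }
  F_ind <- 2 * (d - Aii) / (1 - Aii) - 1
  names(F_ind) <- rownames(s$A)
  F_is_pop <- tapply(F_ind, pops, mean)
  list(F_ind = F_ind, F_is_pop = F_is_pop,
       F_is = mean(F_is_pop, na.rm = FALSE))
}

#' FST matrix estimate from allele sharing
#'
#' The moment estimator `F = (Abar - J Abar_B) / (1 - Abar_B)`: diagonal
#' entries are population-specific FST estimates, off-diagonal entries are
#' population-pair relative coancestries, and the reference is the mean
#' between-population sharing (off-diagonal entries average zero).
#'
#' @param s a `sharing_matrices` object from [allele_sharing()].
#' @return An [fst_matrix()] tagged `estimated-from-data`, `mean-between`.
#' @export
fst_matrix_estimate <- function(s) {
  if (nlevels(s$pops) < 2) stop("FST needs at least 2 populations")
  if (1 - s$Abar_B < 1e-12)
    stop("singular reference: mean between-population sharing is 1")
  fst_matrix((s$Abar - s$Abar_B) / (1 - s$Abar_B),
             reference = "mean-between", origin = "estimated-from-data")
}

#' Overall FST estimate
#'
#' The mean of the diagonal of the FST matrix estimate, equal to
#' `(Abar_S - Abar_B) / (1 - Abar_B)`.
#'
#' @param x an [fst_matrix()] on the mean-between scale, or a
#'   `sharing_matrices` object.
#' @return A single number.
#' @export
overall_fst_estimate <- function(x) {
  if (inherits(x, "sharing_matrices")) x <- fst_matrix_estimate(x)
  if (attr(x, "reference") != "mean-between")
    stop("overall FST is defined on the mean-between reference")
  mean(diag(x))
}

#' Pairwise FST estimates
#'
#' The two-population statistic
#' `[(A_ii + A_i'i')/2 - A_ii'] / (1 - A_ii')` for every pair, computed from
#' the population-level sharing matrix.  Unlike the elements of the FST
#' matrix, these values do not depend on the choice of reference point; the
#' same formula applied to the elements of any reference-transformed FST
#' matrix returns identical values.
#'
#' @param x a `sharing_matrices` object, or an [fst_matrix()] (any reference).
#' @return A symmetric r x r matrix with zero diagonal.
#' @export
pairwise_fst_estimate <- function(x) {
  v <- if (inherits(x, "sharing_matrices")) x$Abar else unclass(x)
  d <- diag(v)
  if (any(1 - v[row(v) != col(v)] < 1e-12))
    stop("singular pair: between-population value of 1")
  out <- (outer(d, d, "+") / 2 - v) / (1 - v)
  diag(out) <- 0
  dimnames(out) <- dimnames(v)
  (out + t(out)) / 2
}
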