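#' Genotype dosage data
#'
#' Container for an individuals x loci matrix of allele-count dosages (integers
#' in `0..ploidy`, `NA` for missing) together with a sample-to-population
#' assignment and the ploidy.
#'
#' @param dosages numeric matrix, individuals in rows, loci in columns.  Row
#'   names are used as sample ids when present.
#' @param pops factor or character vector assigning every row to a population.
#' @param ploidy positive integer, copies per individual per locus (default 2).
#' @param positions optional numeric vector of locus positions (base pairs),
#'   used by the block bootstrap; recycled names from `colnames(dosages)` are
#'   kept as locus ids.
#' @param chrom optional character vector of locus chromosome names.
#' @return An object of class `geno_data` with elements `dosages`, `pops`
#'   (factor), `ploidy`, `positions`, `chrom`.
#' @export
geno_data <- function(dosages, pops, ploidy = 2L, positions = NULL,
                      chrom = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  if (length(pops) != n)
    stop("'pops' must assign one population to each of the ", n, " samples")
  # keep first-appearance order for character input so population order
  # matches the model/index order rather than sorting pop10 before pop2
  pops <- if (is.factor(pops)) droplevels(pops)
          else factor(pops, levels = unique(as.character(pops)))
  ploidy <- as.integer(ploidy)
  if (ploidy < 1) stop("'ploidy' must be a positive integer")
  bad <- !is.na(dosages) & (dosages < 0 | dosages > ploidy |
                            dosages != round(dosages))
  if (any(bad))
    stop(sum(bad), " dosage(s) outside {0..", ploidy, "}")
  if (ncol(dosages) < 1) stop("need at least one locus")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind", seq_len(n))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("locus", seq_len(ncol(dosages)))
  if (!is.null(positions) && length(positions) != ncol(dosages))
    stop("'positions' must have one entry per locus")
  structure(list(dosages = dosages, pops = pops, ploidy = ploidy,
                 positions = positions, chrom = chrom),
            class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("Genotype data:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "loci, ploidy", x$ploidy, "\n")
  cat("Populations:", paste(sprintf("%s (%d)", levels(x$pops),
                                    tabulate(x$pops)), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat("Missing dosages:", nmiss, "\n")
  invisible(x)
}

#' @export
`[.geno_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  geno_data(x$dosages[i, j, drop = FALSE], x$pops[i], x$ploidy,
            positions = if (!is.null(x$positions)) x$positions[j],
            chrom = if (!is.null(x$chrom)) x$chrom[j])
}
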