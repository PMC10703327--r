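#' Read genotype dosages from a VCF file
#'
#' Keeps biallelic SNP records only (multi-allelic and indel records are
#' skipped with a message).  The dosage is the count of ALT alleles in the GT
#' field; `"|"` and `"/"` separators are treated identically and any genotype
#' containing a missing allele (e.g. `./1`) becomes a missing dosage.
#' Positions and chromosomes are retained for the block bootstrap.
#'
#' @param path path to a VCF (optionally gzipped).
#' @param pop_map either a path to a two-column TSV (`sample_id`, `population`,
#'   no header required) or a named character vector mapping sample to
#'   population.  Every sample in the VCF must be covered.
#' @return A [geno_data()] object (diploid).
#' @export
read_vcf <- function(path, pop_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  snp <- vcfR::is.biallelic(v) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message("skipped ", n_skip, " non-biallelic-SNP record(s)")
  if (!any(snp)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  dosv <- vapply(strsplit(as.vector(gt), "[/|]"), function(a) {
    if (length(a) == 0 || any(a == ".") || anyNA(a)) return(NA_real_)
    sum(a == "1")
  }, 0)
  dos <- t(matrix(dosv, nrow(gt), ncol(gt)))  # samples x loci
  rownames(dos) <- colnames(gt)
  pm <- if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map))
    read_pop_map(pop_map) else pop_map
  missing_samples <- setdiff(rownames(dos), names(pm))
  if (length(missing_samples))
    stop("sample(s) absent from the population map: ",
         paste(missing_samples, collapse = ", "))
  colnames(dos) <- paste0(fix[snp, "CHROM"], ":", fix[snp, "POS"])
  geno_data(dos, pops = pm[rownames(dos)], ploidy = 2L,
            positions = as.numeric(fix[snp, "POS"]),
            chrom = fix[snp, "CHROM"])
}

#' Write simulated genotypes as a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns; diploid dosages 0,
#' 1, 2 become `0/0`, `0/1`, `1/1` and missing becomes `./.`.  Loci are laid
#' out on a single synthetic chromosome at 1 kb spacing unless `g` carries
#' positions.
#'
#' @param g a diploid [geno_data()] object.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  if (g$ploidy != 2) stop("VCF output supports diploids only")
  X <- g$dosages
  L <- ncol(X)
  pos <- if (!is.null(g$positions)) g$positions else seq_len(L) * 1000
  chrom <- if (!is.null(g$chrom)) g$chrom else rep("1", L)
  gt <- matrix(c("0/0", "0/1", "1/1")[X + 1], nrow(X), L)
  gt[is.na(X)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=ashfst",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(X)), collapse = "\t"),
    vapply(seq_len(L), function(l)
      paste(c(chrom[l], pos[l], colnames(X)[l], "A", "T", ".", ".", ".",
              "GT", gt[, l]), collapse = "\t"), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write dosage matrices as TSV
#'
#' Dialect: tab-separated, header row of locus ids, first column the sample
#' id, `NA` for missing dosages.
#'
#' @param path file path.
#' @param pop_map population map (path or named vector), as in [read_vcf()].
#' @param ploidy copies per individual (default 2).
#' @return `read_dosage_tsv()`: a [geno_data()]; `write_dosage_tsv()`:
#'   `path`, invisibly.
#' @export
read_dosage_tsv <- function(path, pop_map, ploidy = 2L) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  X <- as.matrix(tab)
  if (!is.numeric(X)) stop("non-numeric dosages in ", path)
  pm <- if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map))
    read_pop_map(pop_map) else pop_map
  missing_samples <- setdiff(rownames(X), names(pm))
  if (length(missing_samples))
    stop("sample(s) absent from the population map: ",
         paste(missing_samples, collapse = ", "))
  geno_data(X, pops = pm[rownames(X)], ploidy = ploidy)
}

#' @rdname read_dosage_tsv
#' @param g a [geno_data()] object.
#' @export
write_dosage_tsv <- function(g, path) {
  tab <- data.frame(sample_id = rownames(g$dosages), g$dosages,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample-to-population maps
#'
#' Two-column TSV: sample id, population label.  A header line is detected
#' and skipped when its first field is `sample_id`.
#'
#' @param path file path.
#' @return `read_pop_map()`: named character vector (names = sample ids);
#'   `write_pop_map()`: `path`, invisibly.
#' @export
read_pop_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (tab[1, 1] == "sample_id") tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2) stop("population map must have two columns")
  stats::setNames(tab[[2]], tab[[1]])
}

#' @rdname read_pop_map
#' @param g a [geno_data()] object.
#' @export
write_pop_map <- function(g, path) {
  utils::write.table(data.frame(rownames(g$dosages), as.character(g$pops)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write labelled matrices as TSV
#'
#' Used for FST, kinship and sharing matrices; row and column labels are
#' preserved and the reference/origin tags of an [fst_matrix()] are stored in
#' `#`-comment header lines and restored on reading.
#'
#' @param x a matrix or [fst_matrix()].
#' @param path file path.
#' @return `write_matrix_tsv()`: `path`, invisibly; `read_matrix_tsv()`: a
#'   matrix, or an [fst_matrix()] when tags are present.
#' @export
write_matrix_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "fst_matrix")) {
    writeLines(paste0("# reference: ", attr(x, "reference")), con)
    writeLines(paste0("# origin: ", attr(x, "origin")), con)
    if (!is.null(attr(x, "ref_value")))
      writeLines(paste0("# ref_value: ",
                        format(attr(x, "ref_value"), digits = 17)), con)
  }
  m <- unclass(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("pop", seq_len(nrow(m)))
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  all_lines <- readLines(path)
  hdr <- grep("^#", all_lines, value = TRUE)
  tab <- utils::read.delim(text = all_lines[!grepl("^#", all_lines)],
                           check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  tag <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NULL
  }
  ref <- tag("reference")
  if (is.null(ref)) return(m)
  rv <- tag("ref_value")
  fst_matrix(m, reference = ref, origin = tag("origin"),
             ref_value = if (!is.null(rv)) as.numeric(rv))
}

#' Read and write migration models as JSON
#'
#' The file stores the effective sizes, the dense migration matrix, the
#' mutation rate and the population labels.
#'
#' @param model a [migration_model()].
#' @param path file path.
#' @return `write_model_json()`: `path`, invisibly; `read_model_json()`: a
#'   [migration_model()].
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(N = model$N, M = model$M, mu = model$mu,
                            labels = model$labels),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  migration_model(x$N, x$M, x$mu, labels = x$labels)
}
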