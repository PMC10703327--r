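#' Relative-coancestry (FST) matrices
#'
#' An `fst_matrix` is a symmetric r x r matrix of coancestries expressed
#' relative to a reference point.  Diagonal entries are population-specific
#' FST values; off-diagonal entries are population-pair relative coancestries.
#' The object records which reference was used:
#'
#' * `"mean-between"` - the mean between-population coancestry (the default
#'   scale; off-diagonal entries then average zero by construction);
#' * `"minimum-between"` - the minimum between-population coancestry (the
#'   Ochoa-Storey scale; all entries are then non-negative and the smallest
#'   off-diagonal entry is zero);
#' * `"external-constant"` - an arbitrary constant `c < 1` supplied by the
#'   user, stored in the `ref_value` attribute.
#'
#' @param values symmetric numeric matrix with entries in `[-1, 1]`.
#' @param reference one of `"mean-between"`, `"minimum-between"`,
#'   `"external-constant"`.
#' @param origin `"expected-from-theory"` or `"estimated-from-data"`.
#' @param ref_value the constant used when `reference = "external-constant"`.
#' @return An object of class `fst_matrix` (a matrix with attributes
#'   `reference`, `origin` and optionally `ref_value`).
#' @export
fst_matrix <- function(values,
                       reference = c("mean-between", "minimum-between",
                                     "external-constant"),
                       origin = c("estimated-from-data", "expected-from-theory"),
                       ref_value = NULL) {
  reference <- match.arg(reference)
  origin <- match.arg(origin)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("'values' must be square")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("'values' must be symmetric")
  values <- (values + t(values)) / 2
  off <- values[row(values) != col(values)]
  if (reference == "mean-between" && abs(mean(off)) > 1e-12)
    stop("mean-between reference requires zero-mean off-diagonal entries")
  if (reference == "minimum-between" &&
      (min(values) < -1e-12 || abs(min(off)) > 1e-12))
    stop("minimum-between reference requires non-negative entries with ",
         "minimum off-diagonal equal to zero")
  if (reference == "external-constant" &&
      (is.null(ref_value) || ref_value >= 1))
    stop("external-constant reference requires 'ref_value' < 1")
  structure(values, class = c("fst_matrix", "matrix"),
            reference = reference, origin = origin, ref_value = ref_value)
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat("FST matrix (", attr(x, "origin"), ", reference: ",
      attr(x, "reference"), ")\n", sep = "")
  if (!is.null(attr(x, "ref_value")))
    cat("reference constant:", format(attr(x, "ref_value")), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Bubble plot of an FST matrix
#'
#' Draws each matrix element as a disc whose area scales with its magnitude,
#' blue for positive and red for negative values - the conventional display
#' for population-pair relative coancestries.
#'
#' @param x an [fst_matrix()].
#' @param max_cex disc size for the largest absolute value.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fst_matrix <- function(x, max_cex = 4, ...) {
  r <- nrow(x)
  v <- unclass(x)
  lab <- rownames(v)
  if (is.null(lab)) lab <- seq_len(r)
  graphics::plot(NA, xlim = c(0.5, r + 0.5), ylim = c(0.5, r + 0.5),
                 xlab = "", ylab = "", axes = FALSE, asp = 1, ...)
  graphics::axis(1, at = seq_len(r), labels = lab, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(r), labels = rev(lab), las = 2, cex.axis = 0.7)
  vmax <- max(abs(v))
  if (vmax == 0) vmax <- 1
  for (i in seq_len(r)) for (j in seq_len(r)) {
    val <- v[i, j]
    graphics::points(j, r + 1 - i, pch = 16,
                     cex = max_cex * sqrt(abs(val) / vmax),
                     col = if (val >= 0) grDevices::adjustcolor("blue3", 0.7)
                           else grDevices::adjustcolor("red3", 0.7))
  }
  graphics::box()
  invisible(x)
}
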