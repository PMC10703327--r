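#' Re-express an FST matrix relative to a different reference point
#'
#' All the ratio statistics in this package are of the form
#' `(value - ref) / (1 - ref)`; changing the reference is the affine transform
#' `F' = (F - J c) / (1 - c)` for a constant `c < 1`.  Supported references:
#'
#' * `"mean-between"`: recentre so the off-diagonal entries average zero (the
#'   package default scale).  Applied to a minimum-between matrix this inverts
#'   [to_os_reference()].
#' * `"minimum-between"`: subtract and divide out the minimum off-diagonal
#'   element (the Ochoa-Storey scale); all entries become non-negative and the
#'   least related pair is pinned at zero.
#' * `"constant"`: an arbitrary external constant `value < 1`, expressed on
#'   the same relative scale as `f`.
#' * `"percentile"`: the `value` percentile (in `[0, 100]`) of the
#'   off-diagonal elements, a robust alternative to the minimum.
#'
#' Pairwise FST values computed from the result ([pairwise_fst_estimate()])
#' are unchanged by any of these transforms.
#'
#' @param f an [fst_matrix()].
#' @param reference target reference point (see above).
#' @param value the constant (for `"constant"`) or percentile (for
#'   `"percentile"`).
#' @return An [fst_matrix()] on the requested scale.  For
#'   `"minimum-between"`, the attribute `argmin_pair` records which population
#'   pair attained the minimum.
#' @examples
#' th <- coancestry_state(matrix(c(.5, .1, .1, .3), 2), t = 10)
#' f <- fst_from_theta(th)
#' set_reference(f, "minimum-between")
#' @export
set_reference <- function(f, reference = c("mean-between", "minimum-between",
                                           "constant", "percentile"),
                          value = NULL) {
  if (!inherits(f, "fst_matrix")) stop("'f' must be an fst_matrix")
  reference <- match.arg(reference)
  v <- unclass(f)
  off <- v[row(v) != col(v)]
  origin <- attr(f, "origin")
  shift <- function(c0, tag, ref_value = NULL, extra = NULL) {
    if (1 - c0 < 1e-12) stop("singular reference: constant of 1")
    out <- fst_matrix((v - c0) / (1 - c0), reference = tag, origin = origin,
                      ref_value = ref_value)
    for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
    out
  }
  switch(reference,
    "mean-between" = shift(mean(off), "mean-between"),
    "minimum-between" = {
      c0 <- min(off)
      w <- which(v == c0 & row(v) != col(v), arr.ind = TRUE)[1, ]
      shift(c0, "minimum-between",
            extra = list(argmin_pair = c(rownames(v)[w[1]] %||% w[1],
                                         colnames(v)[w[2]] %||% w[2])))
    },
    "constant" = {
      if (is.null(value)) stop("'value' required for a constant reference")
      if (value >= 1) stop("constant reference must be < 1")
      shift(value, "external-constant", ref_value = value)
    },
    "percentile" = {
      if (is.null(value) || value < 0 || value > 100)
        stop("'value' must be a percentile in [0, 100]")
      c0 <- unname(stats::quantile(off, value / 100))
      shift(c0, "external-constant", ref_value = c0)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ochoa-Storey (minimum-between) reference
#'
#' Convenience wrappers around [set_reference()].  `to_os_reference()`
#' re-expresses a mean-between FST matrix relative to its minimum off-diagonal
#' element; `from_os_reference()` recentres a minimum-between matrix on its
#' mean off-diagonal element, recovering the original mean-between matrix
#' exactly (the transforms are mutually inverse).
#'
#' @param f an [fst_matrix()] on the mean-between scale
#'   (`from_os_reference()`: on the minimum-between scale).
#' @return An [fst_matrix()].
#' @export
to_os_reference <- function(f) {
  if (attr(f, "reference") != "mean-between")
    stop("expected a mean-between FST matrix")
  set_reference(f, "minimum-between")
}

#' @rdname to_os_reference
#' @export
from_os_reference <- function(f) {
  if (attr(f, "reference") != "minimum-between")
    stop("expected a minimum-between FST matrix")
  set_reference(f, "mean-between")
}

#' @rdname to_os_reference
#' @param value external constant `c < 1` on the same relative scale as `f`.
#' @export
to_constant_reference <- function(f, value) {
  set_reference(f, "constant", value)
}
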