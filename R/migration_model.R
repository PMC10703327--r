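#' Specify a metapopulation migration model
#'
#' A migration model bundles the demographic parameters that drive the
#' coancestry recursion: per-population effective sizes, a backward migration
#' matrix and a mutation rate.  Entry `M[i, i']` is the fraction of alleles in
#' population `i` that resided in population `i'` one generation earlier, so
#' every row of `M` must sum to one.
#'
#' @param N numeric vector of effective population sizes (individuals), all
#'   positive.  A continent is modelled as a very large finite size such as
#'   `1e9` rather than a symbolic infinity.
#' @param M square numeric matrix of backward migration fractions, with
#'   non-negative entries and rows summing to 1 (tolerance `1e-12`).  Rows that
#'   do not sum to one are an error; they are never silently renormalised.
#' @param mu per-generation mutation rate, in `[0, 1)`.  Mutation enters the
#'   recursion only through the identity-destroying factor `(1 - mu)^2`.
#' @param labels optional character vector of population labels.
#'
#' @return An object of class `migration_model` with elements `r`, `N`, `M`,
#'   `mu` and `labels`.
#' @seealso [finite_island_model()], [continent_island_model()],
#'   [stepping_stone_model()], [river_model()] for the classical builders;
#'   [predict.migration_model()] for expected coancestries and FST;
#'   [simulate.migration_model()] for genotype data.
#' @examples
#' m <- finite_island_model(N = c(100, 100), m = 0.4)
#' m$M
#' @export
migration_model <- function(N, M, mu = 1e-8, labels = NULL) {
  N <- as.numeric(N)
  M <- as.matrix(M)
  r <- length(N)
  if (nrow(M) != r || ncol(M) != r)
    stop("'M' must be an r x r matrix matching length(N) = ", r)
  if (any(!is.finite(N)) || any(N <= 0))
    stop("all effective sizes 'N' must be positive and finite")
  if (any(!is.finite(M)) || any(M < 0))
    stop("all entries of 'M' must be finite and >= 0")
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12))
    stop("rows of 'M' must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), "); refusing to renormalise")
  if (length(mu) != 1L || !is.finite(mu) || mu < 0 || mu >= 1)
    stop("'mu' must be a single value in [0, 1)")
  if (is.null(labels)) labels <- paste0("pop", seq_len(r))
  if (length(labels) != r) stop("'labels' must have length r")
  dimnames(M) <- list(labels, labels)
  structure(list(r = r, N = N, M = M, mu = mu, labels = labels),
            class = "migration_model")
}

#' @export
print.migration_model <- function(x, ...) {
  cat("Migration model:", x$r, "populations, mu =", format(x$mu), "\n")
  cat("N:", paste(format(x$N, trim = TRUE), collapse = " "), "\n")
  cat("Backward migration matrix M (rows sum to 1):\n")
  print(round(x$M, 6))
  invisible(x)
}

#' Continent-island model
#'
#' The first population is a continent that receives no immigrants (its row of
#' `M` is an identity row); each island receives a fraction `m[i]` of its
#' alleles from the continent and none from other islands.
#'
#' @param N_islands numeric vector of island effective sizes.
#' @param m per-island immigration rate(s) from the continent, recycled to the
#'   number of islands.
#' @param N_continent effective size used for the continent (default `1e9`).
#' @param mu mutation rate per generation.
#' @return A [migration_model()] with `length(N_islands) + 1` populations, the
#'   continent first.
#' @export
continent_island_model <- function(N_islands, m, N_continent = 1e9, mu = 1e-8) {
  k <- length(N_islands)
  m <- rep_len(as.numeric(m), k)
  if (any(m < 0 | m > 1)) stop("immigration rates 'm' must be in [0, 1]")
  r <- k + 1L
  M <- matrix(0, r, r)
  M[1, 1] <- 1
  for (i in seq_len(k)) {
    M[i + 1, 1] <- m[i]
    M[i + 1, i + 1] <- 1 - m[i]
  }
  migration_model(c(N_continent, N_islands), M, mu,
                  labels = c("continent", paste0("island", seq_len(k))))
}

#' Finite island model
#'
#' Every population receives a total immigrant fraction `m`, split equally
#' among the `r - 1` other populations; the diagonal of `M` is `1 - m`.
#'
#' @param N numeric vector of effective sizes (length gives the number of
#'   islands).
#' @param m total immigration rate per population, in `[0, 1]`.
#' @param mu mutation rate per generation.
#' @return A [migration_model()].
#' @export
finite_island_model <- function(N, m, mu = 1e-8) {
  r <- length(N)
  if (r < 2) stop("a finite island model needs at least 2 populations")
  if (m < 0 || m > 1) stop("'m' must be in [0, 1]")
  M <- matrix(m / (r - 1), r, r)
  diag(M) <- 1 - m
  migration_model(N, M, mu)
}

#' One-dimensional stepping stone model
#'
#' Each population receives a fraction `m/2` of its alleles from each of its
#' left and right neighbours; end populations receive only from their single
#' neighbour at rate `m/2` (so their diagonal is `1 - m/2`).
#'
#' @inheritParams finite_island_model
#' @return A [migration_model()].
#' @export
stepping_stone_model <- function(N, m, mu = 1e-8) {
  r <- length(N)
  if (r < 2) stop("a stepping stone model needs at least 2 populations")
  if (m < 0 || m > 1) stop("'m' must be in [0, 1]")
  M <- matrix(0, r, r)
  for (i in seq_len(r)) {
    if (i > 1) M[i, i - 1] <- m / 2
    if (i < r) M[i, i + 1] <- m / 2
    M[i, i] <- 1 - sum(M[i, ])
  }
  migration_model(N, M, mu)
}

#' River-network migration model
#'
#' Populations sit on the nodes of a directed river network given as
#' `(upstream, downstream)` edges.  Each station receives a fraction `m_down`
#' of its alleles from each of its upstream neighbours (alleles carried
#' downstream) and `m_up` from each of its downstream neighbours; both are
#' backward (immigration) fractions.  The diagonal takes up the remainder.
#'
#' @param edges two-column matrix (or list of length-2 vectors) of station
#'   indices, each row `(upstream, downstream)`.
#' @param N numeric vector of effective sizes, one per station.
#' @param m_down backward migration fraction received from each upstream
#'   neighbour.
#' @param m_up backward migration fraction received from each downstream
#'   neighbour.
#' @param mu mutation rate per generation.
#' @return A [migration_model()].
#' @export
river_model <- function(edges, N, m_down = 0.02, m_up = 0.005, mu = 1e-8) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("'edges' must have two columns (upstream, downstream)")
  r <- length(N)
  if (any(edges < 1 | edges > r)) stop("edge indices out of range 1..", r)
  g <- matrix(FALSE, r, r)  # undirected adjacency, for connectivity
  M <- matrix(0, r, r)
  for (e in seq_len(nrow(edges))) {
    up <- edges[e, 1]; dn <- edges[e, 2]
    M[dn, up] <- M[dn, up] + m_down
    M[up, dn] <- M[up, dn] + m_up
    g[up, dn] <- g[dn, up] <- TRUE
  }
  # connectivity check by breadth-first search
  seen <- logical(r); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(g[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen)) stop("river network is disconnected (stations ",
                       paste(which(!seen), collapse = ", "), " unreachable)")
  d <- 1 - rowSums(M)
  if (any(d < 0)) stop("migration fractions exceed 1 for station(s) ",
                       paste(which(d < 0), collapse = ", "))
  diag(M) <- d
  migration_model(N, M, mu, labels = paste0("station", seq_len(r)))
}

#' Equilibrium within-island coancestry for the continent-island model
#'
#' Closed-form fixed point of the scalar recursion for an island of size `N`
#' receiving a fraction `m` of its alleles from an infinite continent, with
#' mutation rate `mu`:
#' `theta = (1-m)^2 (1-mu)^2 / (2N - (2N-1)(1-m)^2(1-mu)^2)`.
#'
#' @param N island effective size.
#' @param m immigration rate from the continent.
#' @param mu mutation rate per generation.
#' @param approximate if `TRUE`, return the familiar low-rate approximation
#'   `1 / (1 + 4N(m + mu))` instead of the exact form.
#' @return Equilibrium coancestry, a number in `[0, 1]`.
#' @examples
#' continent_island_equilibrium(10, 0.001, 1e-8)
#' continent_island_equilibrium(10, 0.001, 1e-8, approximate = TRUE)
#' @export
continent_island_equilibrium <- function(N, m, mu = 0, approximate = FALSE) {
  if (approximate) return(1 / (1 + 4 * N * (m + mu)))
  a <- (1 - m)^2 * (1 - mu)^2
  den <- 2 * N - (2 * N - 1) * a
  if (den <= 0) stop("degenerate parameters: denominator not positive")
  a / den
}
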