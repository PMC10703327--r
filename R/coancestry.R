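#' Coancestry state of a metapopulation
#'
#' Holds the symmetric r x r matrix of mean identity-by-descent probabilities
#' `theta[i, i']` for distinct pairs of individuals (one in population `i`,
#' one in `i'`; the diagonal is the within-population value), together with a
#' generation counter.  Coancestries are expressed relative to the state at
#' generation 0, so the default initial state is the all-zero matrix.
#'
#' @param theta symmetric numeric matrix with entries in `[0, 1]`.
#' @param t non-negative integer generation counter.
#' @return An object of class `coancestry_state`.
#' @export
coancestry_state <- function(theta, t = 0L) {
  theta <- as.matrix(theta)
  if (nrow(theta) != ncol(theta)) stop("'theta' must be square")
  if (max(abs(theta - t(theta))) > 1e-8) stop("'theta' must be symmetric")
  if (any(theta < -1e-12) || any(theta > 1 + 1e-12))
    stop("'theta' entries must lie in [0, 1]")
  if (t < 0) stop("'t' must be non-negative")
  structure(list(theta = (theta + t(theta)) / 2, t = as.integer(t)),
            class = "coancestry_state")
}

#' @export
print.coancestry_state <- function(x, digits = 4, ...) {
  cat("Coancestry state at generation", x$t, "\n")
  print(round(x$theta, digits))
  invisible(x)
}

#' Advance the coancestry recursion by one generation
#'
#' Applies the matrix transition once:
#' `Theta' = (1 - mu)^2 * M Phi M^T`, where `Phi` equals `Theta` off the
#' diagonal and `phi_i = 1/(2 N_i) + (1 - 1/(2 N_i)) theta_i` on the diagonal
#' (the probability of identity for two alleles drawn with replacement among
#' the parents of population `i`).
#'
#' @param state a [coancestry_state()].
#' @param model a [migration_model()] with matching dimension.
#' @return The [coancestry_state()] one generation later.
#' @export
coancestry_step <- function(state, model) {
  if (!inherits(state, "coancestry_state")) stop("'state' must be a coancestry_state")
  if (!inherits(model, "migration_model")) stop("'model' must be a migration_model")
  th <- state$theta
  if (nrow(th) != model$r)
    stop("dimension mismatch: state has ", nrow(th),
         " populations, model has ", model$r)
  Phi <- th
  diag(Phi) <- 1 / (2 * model$N) + (1 - 1 / (2 * model$N)) * diag(th)
  new <- (1 - model$mu)^2 * (model$M %*% Phi %*% t(model$M))
  new <- (new + t(new)) / 2
  coancestry_state(new, state$t + 1L)
}

#' Iterate the coancestry recursion
#'
#' @param model a [migration_model()].
#' @param generations number of generations to iterate (>= 0).
#' @param initial optional starting [coancestry_state()]; defaults to zero
#'   coancestry at generation 0.
#' @param keep one of `"last"` (return the final state) or `"all"` (return the
#'   whole trajectory as a list of length `generations + 1`).
#' @return A [coancestry_state()] or a list of them.
#' @export
coancestry_trajectory <- function(model, generations, initial = NULL,
                                  keep = c("last", "all")) {
  keep <- match.arg(keep)
  if (generations < 0) stop("'generations' must be >= 0")
  if (is.null(initial))
    initial <- coancestry_state(matrix(0, model$r, model$r), 0L)
  state <- initial
  if (keep == "all") {
    out <- vector("list", generations + 1L)
    out[[1L]] <- state
    for (g in seq_len(generations)) {
      state <- coancestry_step(state, model)
      out[[g + 1L]] <- state
    }
    return(out)
  }
  for (g in seq_len(generations)) state <- coancestry_step(state, model)
  state
}

#' Iterate the coancestry recursion to its fixed point
#'
#' @param model a [migration_model()].
#' @param tol convergence tolerance on the maximum absolute elementwise change
#'   per generation.
#' @param max_iter iteration cap.
#' @param initial optional starting state.
#' @return The converged [coancestry_state()]; errors if `max_iter` is reached
#'   first.
#' @export
coancestry_equilibrium <- function(model, tol = 1e-12, max_iter = 1e6,
                                   initial = NULL) {
  if (is.null(initial))
    initial <- coancestry_state(matrix(0, model$r, model$r), 0L)
  state <- initial
  for (i in seq_len(max_iter)) {
    nxt <- coancestry_step(state, model)
    if (max(abs(nxt$theta - state$theta)) < tol) return(nxt)
    state <- nxt
  }
  stop("coancestry recursion did not converge within ", max_iter, " iterations")
}

#' Expected FST matrix from a coancestry state
#'
#' Recentres the coancestry matrix on the mean between-population coancestry
#' `theta_B` (the unweighted mean of the `r(r-1)` off-diagonal entries):
#' `F = (Theta - J theta_B) / (1 - theta_B)`.  Off-diagonal entries of the
#' result average zero by construction.
#'
#' @param state a [coancestry_state()] with at least 2 populations.
#' @return An [fst_matrix()] on the mean-between scale, tagged as expected
#'   from theory.
#' @export
fst_from_theta <- function(state) {
  th <- state$theta
  r <- nrow(th)
  if (r < 2) stop("need at least 2 populations")
  thB <- mean(th[row(th) != col(th)])
  if (1 - thB < 1e-12)
    stop("singular reference: mean between-population coancestry is 1")
  fst_matrix((th - thB) / (1 - thB), reference = "mean-between",
             origin = "expected-from-theory")
}

#' Expected overall FST from a coancestry state
#'
#' `(theta_S - theta_B) / (1 - theta_B)` with `theta_S` the mean diagonal and
#' `theta_B` the mean off-diagonal coancestry; equal to the mean diagonal of
#' [fst_from_theta()].
#'
#' @inheritParams fst_from_theta
#' @return A single number.
#' @export
overall_fst_from_theta <- function(state) {
  mean(diag(fst_from_theta(state)))
}

#' Expected pairwise FST from a coancestry state
#'
#' The two-population statistic
#' `[(theta_i + theta_i')/2 - theta_ii'] / (1 - theta_ii')`, which uses only
#' the pair concerned and is therefore invariant to the global reference
#' point.  The diagonal is set to zero.
#'
#' @inheritParams fst_from_theta
#' @return A symmetric r x r matrix.
#' @export
pairwise_fst_from_theta <- function(state) {
  th <- state$theta
  d <- diag(th)
  if (any(1 - th[row(th) != col(th)] < 1e-12))
    stop("singular pair: between-population coancestry of 1")
  out <- (outer(d, d, "+") / 2 - th) / (1 - th)
  diag(out) <- 0
  dimnames(out) <- dimnames(th)
  (out + t(out)) / 2
}

#' Expected coancestries and FST under a migration model
#'
#' Iterates the coancestry transition equations for `generations` generations
#' from zero coancestry (or `initial`) and returns the expected FST matrix, or
#' other summaries of the final state.
#'
#' @param object a [migration_model()].
#' @param generations number of generations to iterate.
#' @param what `"fst"` (default) for the expected [fst_matrix()], `"theta"`
#'   for the final [coancestry_state()], `"overall"` for the scalar overall
#'   FST, or `"pairwise"` for the pairwise FST matrix.
#' @param initial optional starting [coancestry_state()].
#' @param ... unused.
#' @return See `what`.
#' @examples
#' mod <- finite_island_model(N = c(10, 1000), m = 0.01)
#' predict(mod, generations = 500)
#' @export
predict.migration_model <- function(object, generations = 1000,
                                    what = c("fst", "theta", "overall",
                                             "pairwise"),
                                    initial = NULL, ...) {
  what <- match.arg(what)
  state <- coancestry_trajectory(object, generations, initial)
  switch(what,
         fst = fst_from_theta(state),
         theta = state,
         overall = overall_fst_from_theta(state),
         pairwise = pairwise_fst_from_theta(state))
}
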