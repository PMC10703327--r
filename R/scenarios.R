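#' Study-system scenarios
#'
#' Pre-parameterised migration models for three simulated population
#' structures used throughout the package's verification experiments:
#'
#' * `island_scenario()`: a 10-island finite island model with unequal sizes
#'   `N = (1000, 1000, 10, 10, 100, 100, 500, 500, 2000, 2000)` and total
#'   immigration `m = 0.001` split equally among the other islands.
#' * `stepping_stone_scenario()`: 10 populations of size 1000 in a line,
#'   exchanging migrants only with their neighbours.  Both `m = 0.005` and
#'   `m = 0.02` are plausible parameterisations of this system; the rate is
#'   therefore an argument, defaulting to `0.005`.
#' * `river_scenario()`: a 14-station river with two tributaries.  The main
#'   stem is stations 1-5 then 12-14; tributary 6-8 joins at station 3 and
#'   tributary 9-11 joins at station 5.  Sizes grow towards the mouth
#'   (`N14 = 5000`); downstream migration `m_d = 0.02` is four times stronger
#'   than upstream migration `m_u = 0.005`.
#'
#' @param m total migration rate (stepping stone only).
#' @param mu mutation rate per generation.
#' @return A [migration_model()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
island_scenario <- function(mu = 1e-8) {
  finite_island_model(N = c(1000, 1000, 10, 10, 100, 100, 500, 500, 2000, 2000),
                      m = 0.001, mu = mu)
}

#' @rdname scenarios
#' @export
stepping_stone_scenario <- function(m = 0.005, mu = 1e-8) {
  stepping_stone_model(N = rep(1000, 10), m = m, mu = mu)
}

#' @rdname scenarios
#' @export
river_scenario <- function(mu = 1e-8) {
  edges <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5),       # upper main stem
    c(5, 12), c(12, 13), c(13, 14),           # lower main stem
    c(6, 7), c(7, 8), c(8, 3),                # tributary joining at 3
    c(9, 10), c(10, 11), c(11, 5)             # tributary joining at 5
  )
  N <- c(100, 100, 200, 200, 400, 100, 100, 100, 200, 200, 200, 800, 1000, 5000)
  river_model(edges, N, m_down = 0.02, m_up = 0.005, mu = mu)
}
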