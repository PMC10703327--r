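test_that("one step of the coancestry recursion matches hand calculations", {
  # all-ones coancestry with no mutation is absorbing: phi_i = 1 and the
  # row-stochastic mixing conserves it
  m <- finite_island_model(N = c(10, 20, 30), m = 0.3, mu = 0)
  st <- coancestry_state(matrix(1, 3, 3))
  expect_equal(coancestry_step(st, m)$theta, matrix(1, 3, 3), tolerance = 1e-14,
               ignore_attr = TRUE)

  # single isolated population: theta' = 1/(2N)
  m1 <- migration_model(N = 10, M = matrix(1), mu = 0)
  st1 <- coancestry_step(coancestry_state(matrix(0)), m1)
  expect_equal(st1$theta[1, 1], 1 / 20)
  expect_equal(st1$t, 1L)

  expect_error(coancestry_step(coancestry_state(matrix(0, 2, 2)), m1),
               "dimension mismatch")
})

test_that("iterated continent-island coancestry converges to the closed form", {
  ci <- continent_island_model(N_islands = c(10, 100), m = c(0.001, 0.01),
                               mu = 1e-8)
  st <- coancestry_trajectory(ci, 3000)
  expect_equal(st$theta[2, 2], continent_island_equilibrium(10, 0.001, 1e-8),
               tolerance = 1e-5)
  expect_equal(st$theta[3, 3], continent_island_equilibrium(100, 0.01, 1e-8),
               tolerance = 1e-5)
})

test_that("trajectories have the documented structure and properties", {
  m <- finite_island_model(N = c(10, 50), m = 0.05, mu = 0)
  # zero-generation request returns just the initial state
  tr0 <- coancestry_trajectory(m, 0, keep = "all")
  expect_length(tr0, 1)
  expect_equal(tr0[[1]]$theta, matrix(0, 2, 2))

  tr <- coancestry_trajectory(m, 100, keep = "all")
  expect_length(tr, 101)
  # each state equals one step from its predecessor
  expect_equal(tr[[51]]$theta, coancestry_step(tr[[50]], m)$theta)
  # monotone increase from zero when mutation is absent
  for (g in 2:101)
    expect_true(all(tr[[g]]$theta >= tr[[g - 1]]$theta - 1e-15))
  # absorbing state: J stays J
  trJ <- coancestry_trajectory(m, 50, initial = coancestry_state(matrix(1, 2, 2)))
  expect_equal(trJ$theta, matrix(1, 2, 2), tolerance = 1e-13, ignore_attr = TRUE)
})

test_that("permuting population labels permutes coancestries and FST", {
  N <- c(10, 100, 1000, 50)
  M <- stepping_stone_model(N, m = 0.04)$M
  perm <- c(3, 1, 4, 2)
  P <- diag(4)[perm, ]
  m1 <- migration_model(N, M)
  m2 <- migration_model(N[perm], M[perm, perm])
  s1 <- coancestry_trajectory(m1, 200)
  s2 <- coancestry_trajectory(m2, 200)
  expect_equal(unname(s2$theta), unname(P %*% s1$theta %*% t(P)),
               tolerance = 1e-14)
  expect_equal(unname(unclass(fst_from_theta(s2))),
               unname(P %*% unclass(fst_from_theta(s1)) %*% t(P)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("within-population coancestry is larger for smaller populations", {
  # six-island model with sizes 10..5000: theta for N=10 dominates theta for
  # N=5000 at every generation
  m <- finite_island_model(N = c(10, 50, 100, 500, 1000, 5000), m = 0.001,
                           mu = 1e-8)
  tr <- coancestry_trajectory(m, 5000, keep = "all")
  d <- t(vapply(tr[-1], function(s) diag(s$theta), numeric(6)))
  expect_true(all(d[, 1] > d[, 6]))
  expect_true(all(diff(d[, 1]) >= -1e-15))
})

test_that("FST reaches stationarity even where coancestries have not", {
  models <- list(
    continent_island_model(N_islands = c(10, 50, 100, 500, 1000, 5000),
                           m = 0.001, mu = 1e-8),
    finite_island_model(N = c(10, 50, 100, 500, 1000, 5000), m = 0.001,
                        mu = 1e-8),
    stepping_stone_model(N = c(10, 50, 1000, 1000, 100, 100), m = 0.01,
                         mu = 1e-8))
  for (m in models) {
    s1 <- coancestry_trajectory(m, 5000)
    s2 <- coancestry_step(s1, m)
    f1 <- unclass(fst_from_theta(s1))
    f2 <- unclass(fst_from_theta(s2))
    expect_lt(max(abs(f2 - f1)), 1e-6)
  }
  # in the finite island model the large populations' coancestries are still
  # moving at generation 5000 even though FST has settled
  s1 <- coancestry_trajectory(models[[2]], 5000)
  s2 <- coancestry_step(s1, models[[2]])
  expect_gt(max(abs(s2$theta - s1$theta)), 1e-8)
})
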