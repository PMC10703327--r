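test_that("RMSE reduces to the expected values in degenerate cases", {
  f <- random_fst_matrix(3)
  expect_equal(fst_rmse(list(f, f, f), f)$rmse, matrix(0, 5, 5),
               ignore_attr = TRUE)
  v <- unclass(f)
  v2 <- v
  v2[2, 1] <- v2[1, 2] <- v[1, 2] + 0.01
  v2 <- v2 - mean(v2[row(v2) != col(v2)])
  # rebuild a valid mean-between matrix and measure against the original
  f2 <- fst_matrix(v2, "mean-between", "expected-from-theory")
  rep1 <- fst_rmse(list(f2), f)
  expect_equal(rep1$rmse, abs(unclass(f2) - v), ignore_attr = TRUE)

  fos <- to_os_reference(f)
  expect_error(fst_rmse(list(fos), f), "reference")
})

test_that("subsampling is uniform, per population, and validated", {
  g <- random_geno(8, r = 3, n = 12, L = 100)
  expect_equal(subsample_loci(g, 100, seed = 1)$dosages, g$dosages)
  s1 <- subsample_loci(g, 40, seed = 1)
  s2 <- subsample_loci(g, 40, seed = 2)
  expect_equal(ncol(s1$dosages), 40)
  expect_false(identical(colnames(s1$dosages), colnames(s2$dosages)))
  expect_error(subsample_loci(g, 101, seed = 1), "cannot subsample")

  si <- subsample_individuals(g, 5, seed = 1)
  expect_equal(unname(tabulate(si$pops)), rep(5, 3))
  expect_error(subsample_individuals(g, 13, seed = 1), "cannot subsample")
})

test_that("block bootstrap intervals behave and cover the expectation", {
  g <- random_geno(10, r = 3, n = 10, L = 120)
  expect_error(block_bootstrap_ci(g, function(x) 1, B = 1, block_loci = 10),
               "at least 2")
  expect_error(block_bootstrap_ci(g, function(x) 1, B = 10, block_loci = 200),
               "fewer than 2 blocks")

  # identical blocks give a degenerate zero-width interval
  Xc <- g$dosages[, rep(1:10, 6)]
  gc <- geno_data(Xc, g$pops)
  bb <- block_bootstrap_ci(gc, function(x) fst_as(x)$fst_overall, B = 25,
                           block_loci = 10, seed = 3)
  expect_equal(unname(bb$ci[1, 1]), unname(bb$ci[1, 2]))

  # coverage of the theory value across replicate simulated datasets
  mod <- finite_island_model(N = c(100, 100, 100), m = 0.02, mu = 0)
  T <- 150
  truth <- predict(mod, generations = T, what = "overall")
  runs <- 40
  covered <- 0
  for (i in seq_len(runs)) {
    g <- simulate(mod, seed = 7000 + i, loci = 400, generations = T, n = 10)
    bb <- block_bootstrap_ci(g, function(x) fst_as(x)$fst_overall, B = 99,
                             block_loci = 20, seed = i)
    if (truth >= bb$ci[1, 1] && truth <= bb$ci[1, 2]) covered <- covered + 1
  }
  expect_gte(covered, 33)  # nominal 95%, allowing binomial noise at 40 runs

  # base-pair blocking requires positions and honours them
  gp <- geno_data(g$dosages, g$pops,
                  positions = seq_len(ncol(g$dosages)) * 500)
  bb2 <- block_bootstrap_ci(gp, function(x) fst_as(x)$fst_overall, B = 10,
                            block_bp = 1e4, seed = 1)
  # positions 500..200000 at 500 bp spacing fall into 21 half-open 10 kb bins
  expect_equal(bb2$n_blocks, 21)
  expect_error(block_bootstrap_ci(g, function(x) 1, B = 10, block_bp = 1e4),
               "positions")
})

test_that("the Weir-Cockerham oracle agrees on canonical cases", {
  # two populations fixed for alternate alleles: FST = 1
  X <- rbind(matrix(2, 5, 20), matrix(0, 5, 20))
  g <- geno_data(X, rep(c("a", "b"), each = 5))
  expect_equal(wc_fstats(g)$fst, 1)
  expect_equal(suppressWarnings(fst_as(g))$fst_overall, 1)

  # fully monomorphic data: no variance components at all
  gm <- geno_data(matrix(2, 6, 10), rep(c("a", "b"), each = 3))
  expect_true(is.nan(wc_fstats(gm)$fst))

  # equal sample sizes: exact equality with the allele-sharing estimators
  for (s in 1:5) {
    g <- random_geno(100 + s, r = 4, n = 7, L = 40)
    fit <- fst_as(g)
    w <- wc_fstats(g)
    expect_equal(w$fst, fit$fst_overall, tolerance = 1e-12)
    expect_equal(unname(w$fis_pop), unname(as.vector(fit$F_is_pop)),
                 tolerance = 1e-12)
    expect_equal(w$fis, fit$F_is, tolerance = 1e-12)
  }

  expect_error(wc_fstats(geno_data(matrix(1, 4, 5), rep(c("a", "b"), 2),
                                   ploidy = 4)), "diploid")
})
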