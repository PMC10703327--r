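test_that("pair sharing reproduces the diploid table and the k-ploid formula", {
  # diploid: 1 same homozygotes, 0 opposite homozygotes, 0.5 with any het
  expect_equal(pair_sharing(c(2, 2, 1, 1, 0), c(2, 0, 2, 1, 0), ploidy = 2),
               c(1, 0, 0.5, 0.5, 1))
  # self-sharing: 1 for homozygotes, 0.5 for heterozygotes
  expect_equal(pair_sharing(c(0, 1, 2), c(0, 1, 2), ploidy = 2),
               c(1, 0.5, 1))
  # haploid
  expect_equal(pair_sharing(c(1, 1), c(1, 0), ploidy = 1), c(1, 0))
  # tetraploid example
  expect_equal(pair_sharing(3, 1, ploidy = 4), 0.375)
  expect_error(pair_sharing(3, 0, ploidy = 2), "dosages")

  # oracle: enumerate all ordered pairs of allele draws and count matches
  draw_match <- function(x, y, k) {
    ax <- c(rep(1, x), rep(0, k - x))
    ay <- c(rep(1, y), rep(0, k - y))
    mean(outer(ax, ay, "==") + 0)
  }
  for (k in 1:6)
    for (x in 0:k)
      for (y in 0:k)
        expect_equal(pair_sharing(x, y, k), draw_match(x, y, k))
})

test_that("sharing matrices on the two-fixed-populations dataset are exact", {
  g <- discussion_genotypes(4)
  s <- allele_sharing(g)
  expect_equal(unname(diag(s$Abar)), c(1, 1, 0.5, 0.5))
  expect_equal(s$Abar[1, 2], 0)
  expect_equal(s$Abar[1, 3], 0.5)
  expect_equal(s$Abar[3, 4], 0.5)
  expect_equal(s$Abar_B, 2.5 / 6)

  # two identical fully homozygous individuals share everything
  g2 <- geno_data(matrix(2, 2, 5), c("a", "b"))
  expect_warning(s2 <- allele_sharing(g2), "single sampled individual")
  expect_equal(unname(s2$A), matrix(1, 2, 2))
})

test_that("appending fixed loci leaves every ratio estimator unchanged", {
  g <- random_geno(11, r = 3, n = 8, L = 60)
  X2 <- cbind(g$dosages, matrix(0, nrow(g$dosages), 25),
              matrix(2, nrow(g$dosages), 15))
  g2 <- geno_data(X2, g$pops, g$ploidy)
  s1 <- allele_sharing(g); s2 <- allele_sharing(g2)
  expect_false(isTRUE(all.equal(s1$Abar, s2$Abar)))  # sharing itself moves
  expect_equal(kinship_as(s1), kinship_as(s2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(individual_fis(s1)$F_ind, individual_fis(s2)$F_ind,
               tolerance = 1e-12)
  expect_equal(unclass(fst_matrix_estimate(s1)),
               unclass(fst_matrix_estimate(s2)), tolerance = 1e-12)
  expect_equal(pairwise_fst_estimate(s1), pairwise_fst_estimate(s2),
               tolerance = 1e-12)
})

test_that("kinship has a zero-mean off-diagonal and the documented special cases", {
  # all individuals identical heterozygotes: sharing is constant 0.5, the
  # kinship matrix collapses to zero
  gh <- geno_data(matrix(1, 4, 6), rep(c("a", "b"), each = 2))
  K <- kinship_as(allele_sharing(gh))
  expect_equal(unname(K), matrix(0, 4, 4), ignore_attr = TRUE)

  g <- random_geno(5)
  s <- allele_sharing(g)
  K <- kinship_as(s)
  expect_lt(abs(mean(K[row(K) != col(K)])), 1e-12)
  # inbreeding relative to the whole sample
  expect_equal(2 * diag(K) - 1,
               2 * (diag(s$A) - s$A_B) / (1 - s$A_B) - 1,
               ignore_attr = TRUE)

  # every member of a fixed population has self-kinship 1
  gd <- discussion_genotypes(4)
  Kd <- kinship_as(allele_sharing(gd))
  expect_equal(unname(Kd[1, 1]), 1)
})

test_that("inbreeding coefficients behave for selfed and HW populations", {
  # a fully homozygous population inside a polymorphic sample: F_j = 1
  X <- rbind(matrix(c(0, 2), 4, 10),                      # pop a: homozygotes
             matrix(1, 4, 10))                            # pop b: heterozygotes
  g <- geno_data(X, rep(c("a", "b"), each = 4))
  fis <- individual_fis(allele_sharing(g))
  expect_equal(unname(fis$F_ind[1:4]), rep(1, 4))

  # Hardy-Weinberg population: F_IS near zero
  mod <- finite_island_model(N = c(500, 500), m = 0.05, mu = 0)
  gg <- simulate(mod, seed = 31, loci = 4000, generations = 100, n = 40)
  fis2 <- individual_fis(allele_sharing(gg))
  expect_lt(abs(fis2$F_is), 0.02)
})

test_that("missing dosages use pairwise-complete loci and edge cases are flagged", {
  g <- random_geno(21, r = 2, n = 4, L = 40)
  X <- g$dosages
  X[1, 1:10] <- NA
  X[2, 5:20] <- NA
  gm <- geno_data(X, g$pops)
  s <- allele_sharing(gm)
  expect_equal(s$loci_used[1, 2], sum(!is.na(X[1, ]) & !is.na(X[2, ])))
  # entry equals the mean over jointly observed loci
  ok <- !is.na(X[1, ]) & !is.na(X[2, ])
  expect_equal(s$A[1, 2], mean(pair_sharing(X[1, ok], X[2, ok])))

  # a pair with no jointly observed loci is an error, not an imputation
  X2 <- g$dosages
  X2[1, 1:20] <- NA
  X2[2, 21:40] <- NA
  expect_error(allele_sharing(geno_data(X2, g$pops)), "jointly non-missing")

  # single-individual population: within-population sharing undefined
  gs <- geno_data(g$dosages[1:5, ], c("a", "a", "a", "a", "b"))
  expect_warning(ss <- allele_sharing(gs), "single sampled individual")
  expect_true(is.na(ss$Abar["b", "b"]))
  expect_false(is.na(ss$Abar["a", "b"]))
})

test_that("estimates are equivariant under relabelling and individual order", {
  g <- random_geno(9, r = 3, n = 6, L = 80)
  f1 <- fst_as(g)
  set.seed(4)
  perm <- sample(seq_len(18))
  g2 <- geno_data(g$dosages[perm, ], as.character(g$pops)[perm])
  f2 <- fst_as(g2)
  lev <- levels(g2$pops)
  expect_equal(unclass(f1$fst)[lev, lev], unclass(f2$fst)[lev, lev],
               tolerance = 1e-12)
  expect_equal(f1$fst_overall, f2$fst_overall, tolerance = 1e-12)
  expect_equal(f1$F_is, f2$F_is, tolerance = 1e-12)
})

test_that("subsampled individuals barely move the estimates", {
  g <- random_geno(13, r = 3, n = 30, L = 600)
  full <- fst_as(g)
  sub <- fst_as(subsample_individuals(g, 10, seed = 2))
  expect_lt(max(abs(unclass(sub$fst) - unclass(full$fst))), 0.05)
})
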