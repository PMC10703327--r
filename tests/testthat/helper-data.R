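# small random genotype datasets used across tests
random_geno <- function(seed, r = 3, n = 10, L = 50, ploidy = 2) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- matrix(runif(r * L, 0.1, 0.9), r, L)
  pops <- rep(seq_len(r), each = n)
  X <- matrix(rbinom(r * n * L, ploidy, p[pops, ]), r * n, L)
  geno_data(X, paste0("pop", pops), ploidy)
}

# random valid mean-between FST matrix (for reference-transform properties)
random_fst_matrix <- function(seed, r = 5, scale = 0.3) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- matrix(runif(r * r, -1, 1), r, r)
  v <- (v + t(v)) / 2 * scale
  off <- v[row(v) != col(v)]
  v <- v - mean(off)
  diag(v) <- abs(diag(v))  # population-specific values typically positive
  fst_matrix(v, reference = "mean-between", origin = "expected-from-theory")
}
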