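# Shared fixtures, built once per test run. All synthetic, all seeded.

# small dFNC-level cohort for decomposition/entropy tests
small_dfnc_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh))
      coh <<- simulate_cohort(n_subjects = 16, n_networks = 10, m = 3,
                              level = "dfnc", t_windows = 120,
                              n_sites = 3, seed = 404,
                              affected_sources = 3L)
    coh
  }
})

# mixed Laplace sources with a known mixing matrix
laplace_mixture <- function(m = 3, K = 5000, seed = 7) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  S <- matrix(stats::rexp(m * K) - stats::rexp(m * K), m, K)
  A <- matrix(stats::rnorm(m * m), m, m)
  list(S = S, A = A, X = A %*% S)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

rand_sym_unitdiag <- function(n, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  M <- matrix(stats::runif(n * n, -1, 1), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}
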