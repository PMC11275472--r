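test_that("generated patterns are symmetric, unit-diagonal, distinguishable, deterministic", {
  pats <- generate_patterns(4, 20, block_spec = 2, seed = 7)
  expect_length(pats, 4)
  V <- t(sapply(pats, vectorize_upper))
  for (p in pats) {
    expect_lt(max(abs(p - t(p))), 1e-12)
    expect_identical(diag(p), rep(1, 20))
    expect_true(all(abs(p[row(p) != col(p)]) <= 1))
  }
  cc <- abs(cor(t(V)))
  expect_true(all(cc[upper.tri(cc)] < 0.5))
  expect_identical(pats, generate_patterns(4, 20, block_spec = 2, seed = 7))
  # degenerate single all-positive block: all off-diagonals equal, positive
  p1 <- generate_patterns(1, 6, block_spec = 1)[[1]]
  off <- p1[row(p1) != col(p1)]
  expect_true(all(off == off[1]) && off[1] > 0)
  expect_error(generate_patterns(2, 4, block_spec = 9), "infeasible")
  expect_error(generate_patterns(2, 6, block_spec = list(1:2, 4:6)),
               "partition")
})

test_that("designed group scales give an exact analytic entropy difference", {
  pats <- generate_patterns(3, 8, seed = 1)
  truth <- ground_truth(pats, control_scale = 1, affected_sources = 2L,
                        scale_ratio = 0.5, subject_scale_sd = 0)
  g <- rep(0:1, each = 10)
  src <- generate_sources(20, 200, truth, g, seed = 3)
  H <- attr(src, "true_entropy")
  # affected source: true entropy differs by exactly ln 2 between groups
  expect_equal(mean(H[2, g == 0]) - mean(H[2, g == 1]), log(2))
  expect_equal(mean(H[1, g == 0]) - mean(H[1, g == 1]), 0)
  # closed form for the Laplace family
  expect_equal(family_entropy("laplace", 1), 1 + log(2))
  expect_equal(family_entropy("laplace", 0.5),
               family_entropy("laplace", 1) - log(2))
  # sample scales match the design under a null subject-variance
  sc <- attr(src, "subject_scales")
  expect_equal(sc[2, g == 1] / sc[2, g == 0], rep(0.5, 10))
})

test_that("sources are mutually independent and the null design balances scales", {
  pats <- generate_patterns(2, 8, seed = 2)
  truth <- ground_truth(pats, control_scale = 1, subject_scale_sd = 0)
  src <- generate_sources(1, 10000, truth, 0L, seed = 5)
  r <- cor(src[[1]][1, ], src[[1]][2, ])
  expect_lt(abs(r), 0.05)
  # no affected sources: group sample scale ratio ~ 1
  g <- rep(0:1, each = 15)
  src2 <- generate_sources(30, 1000, truth, g, seed = 6)
  sds <- sapply(src2, function(s) sd(s[1, ]))
  expect_equal(mean(sds[g == 1]) / mean(sds[g == 0]), 1, tolerance = 0.05)
  truth_bad <- truth
  truth_bad$source_family <- "cauchy"
  expect_error(generate_sources(2, 100, truth_bad, c(0L, 1L)), "family")
})

test_that("renewal (dwell) sources keep the marginal and add persistence", {
  pats <- generate_patterns(2, 8, seed = 2)
  truth <- ground_truth(pats, control_scale = 1, subject_scale_sd = 0)
  src <- generate_sources(1, 8000, truth, 0L, seed = 8, dwell = 40)[[1]]
  # values constant within each 40-sample epoch
  expect_identical(src[1, 1:40], rep(src[1, 1], 40))
  # marginal sd still matches the Laplace scale (sd = sqrt(2) * scale)
  expect_equal(sd(src[1, seq(1, 8000, by = 40)]), sqrt(2), tolerance = 0.1)
})

test_that("generalized-Gaussian family matches its closed-form entropy", {
  # shape 1 is the Laplace family under the same parameterization
  expect_equal(family_entropy("gengauss", 0.7, shape = 1),
               family_entropy("laplace", 0.7))
  set.seed(9)
  x <- dfncentropy:::rgengauss(6000, scale = 1, shape = 3)
  expect_equal(kl_entropy(x, k = 3),
               family_entropy("gengauss", 1, shape = 3), tolerance = 0.07)
})

test_that("BOLD assembly: null sources give uncorrelated channels; seeds reproduce", {
  pats <- generate_patterns(2, 8, seed = 3)
  src <- matrix(0, 2, 2000 - 64 + 1)
  tc <- assemble_bold(src, pats, 2000, noise_sd = 0, seed = 4)
  expect_s3_class(tc, "subject_timecourses")
  expect_equal(dim(tc$data), c(2000, 8))
  R <- cor(tc$data)
  expect_lt(max(abs(R[row(R) != col(R)])), 0.08)
  tc2 <- assemble_bold(src, pats, 2000, noise_sd = 0, seed = 4)
  expect_identical(tc$data, tc2$data)
  # inconsistent lengths rejected
  expect_error(assemble_bold(src[, 1:10, drop = FALSE], pats, 5),
               "t_windows")
})

test_that("BOLD assembly reports the offending window when shrinkage cannot rescue PD", {
  pats <- generate_patterns(1, 6, block_spec = 1)  # all-positive block
  src <- matrix(0, 1, 100)
  src[1, 40] <- -80    # large negative excursion at one window
  expect_error(
    assemble_bold(src, pats, 100 + 64 - 1, clip = 100, shrink = 0,
                  pattern_scale = "none", seed = 1),
    "window 40")
})

test_that("windowed FNC of an assembled scan tracks the designed covariance", {
  # one active pattern held constant: mean windowed FNC ~ the shrunk pattern
  pats <- generate_patterns(1, 8, block_spec = 2, seed = 13)
  tw <- 2000 - 64 + 1
  src <- matrix(1, 1, tw)
  tc <- assemble_bold(src, pats, 2000, noise_sd = 0.02, clip = 1,
                      pattern_scale = "none", shrink = 0.7, seed = 14)
  mfnc <- colMeans(sliding_fnc(tc, build_taper())$data)
  P0 <- pats[[1]]; diag(P0) <- 0
  target <- vectorize_upper(cov2cor(0.7 * diag(8) + 0.3 * (diag(8) + P0)))
  expect_gt(cor(mfnc, target), 0.9)
  expect_lt(max(abs(mfnc - target)), 0.12)
})

test_that("covariate tables carry the designed schema and nuisance structure", {
  pats <- generate_patterns(2, 8, seed = 2)
  truth <- ground_truth(pats)
  g <- rep(0:1, each = 30)
  cov <- generate_covariates(60, 7, truth, g, seed = 15)
  expect_equal(length(unique(cov$site)), 7)
  expect_true(all(!is.na(cov$panss_pos[cov$diagnosis == 1])))
  expect_true(all(is.na(cov$panss_pos[cov$diagnosis == 0])))
  expect_true(all(cov$panss_pos[cov$diagnosis == 1] >= 7 &
                    cov$panss_pos[cov$diagnosis == 1] <= 49))
  expect_false(anyDuplicated(cov$subject_id) > 0)
  expect_true(all(cov$age >= 18 & cov$age <= 65))
  # null coupling: cognition score unrelated to the source scale deviation
  truth0 <- truth
  truth0$cognition_coupling$slope <- 0
  dev <- matrix(rnorm(2 * 60, sd = 0.15), 2, 60)
  cov0 <- generate_covariates(60, 3, truth0, g, seed = 16, log_dev = dev)
  fit <- lm(cov0$cminds ~ dev[1, ])
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)  # slope indistinguishable from 0
})

test_that("cohorts are reproducible and internally consistent", {
  c1 <- simulate_cohort(n_subjects = 8, n_networks = 8, m = 2,
                        level = "dfnc", t_windows = 60, seed = 17)
  c2 <- simulate_cohort(n_subjects = 8, n_networks = 8, m = 2,
                        level = "dfnc", t_windows = 60, seed = 17)
  expect_identical(c1$subjects[[3]]$data, c2$subjects[[3]]$data)
  expect_identical(c1$covariates, c2$covariates)
  expect_setequal(names(c1$subjects), c1$covariates$subject_id)
  expect_true(all(c1$covariates$diagnosis %in% 0:1))
})

test_that("cohort write/read round-trips through TSV and CSV", {
  coh <- simulate_cohort(n_subjects = 4, n_networks = 6, m = 2,
                         scan_len = 130, level = "bold", seed = 18)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  tc <- read_timecourses(file.path(dir, "S001.tsv"))
  expect_equal(tc$data, coh$subjects$S001$data,
               tolerance = 1e-12, ignore_attr = TRUE)
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  expect_equal(cov$subject_id, coh$covariates$subject_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$scale_ratio, coh$truth$scale_ratio)
})
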