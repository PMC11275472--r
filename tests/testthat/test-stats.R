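test_that("Jarque-Bera separates normal from skewed samples", {
  # symmetric mesokurtic construction: JB ~ 0
  x <- qnorm((1:2000 - 0.5) / 2000)
  expect_lt(jarque_bera(x)$statistic, 0.5)
  set.seed(41)
  expect_lt(jarque_bera(rexp(500))$p_value, 0.001)
  # null calibration at n = 5000
  ps <- sapply(1:100, function(s) {
    set.seed(s)
    jarque_bera(rnorm(5000))$p_value
  })
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("KS two-sample statistic matches ECDF enumeration", {
  set.seed(42)
  x <- rnorm(50)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, x)$p_value, 1)
  expect_equal(ks_two_sample(rnorm(30), rnorm(30) + 100)$statistic, 1)
  ks <- ks_two_sample(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5), exact = FALSE)
  expect_equal(ks$statistic, 0.25)
})

test_that("permutation test: ties give p = 1, separation gives the add-one floor", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(perm_diff_means(x, x, B = 200, seed = 1)$p_value, 1)
  set.seed(43)
  a <- rnorm(20) + 100
  b <- rnorm(20)
  pm <- perm_diff_means(a, b, B = 10000, seed = 2)
  expect_equal(pm$p_value, 1 / 10001)
  expect_gt(pm$effect, 0)   # group1 minus group0 sign convention
  pm_rev <- perm_diff_means(b, a, B = 1000, seed = 2)
  expect_lt(pm_rev$effect, 0)
  # Hedges g: bias-corrected standardized mean difference, hand value
  g <- perm_diff_means(c(1, 2, 3), c(3, 4, 5), B = 100, seed = 3)$effect
  expect_equal(g, -2 * (1 - 3 / (4 * 4 - 1)), tolerance = 1e-12)
})

test_that("Student's t matches the hand-computed pooled form and is antisymmetric", {
  tt <- students_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(tt$statistic, -2.449, tolerance = 1e-3)
  tt_sw <- students_t(c(3, 4, 5), c(1, 2, 3))
  expect_equal(tt_sw$statistic, -tt$statistic)
  expect_equal(tt_sw$p_value, tt$p_value)
  set.seed(44)
  x <- rnorm(40); y <- rnorm(40)
  expect_lt(abs(students_t(x + 10, y + 10 + mean(x) - mean(y))$statistic),
            1e-8)
  expect_error(students_t(rep(1, 5), rep(1, 5)), "variance")
})

test_that("BH step-up reproduces hand-worked q-values", {
  r <- bh_fdr(rep(0.01, 8), alpha = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$q_values, rep(0.01, 8))
  # hand enumeration: thresholds k*alpha/m = .0125/.025/.0375/.05;
  # p(3) = 0.04 > 0.0375, p(2) = 0.02 <= 0.025 -> exactly two rejections,
  # q = p * m / rank with monotone enforcement
  r2 <- bh_fdr(c(0.01, 0.02, 0.04, 0.8), alpha = 0.05)
  expect_equal(r2$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$q_values, c(0.04, 0.04, 0.04 * 4 / 3, 0.8))
  expect_true(all(r2$q_values >= c(0.01, 0.02, 0.04, 0.8)))
})

test_that("OLS regression recovers exact and designed effects", {
  set.seed(45)
  cov <- data.frame(subject_id = sprintf("S%02d", 1:60),
                    diagnosis = rep(0:1, 30),
                    site = sample(1:3, 60, TRUE),
                    age = sample(20:60, 60, TRUE),
                    gender = sample(c("F", "M"), 60, TRUE))
  y <- 0.25 * cov$age
  fit <- suppressWarnings(
    ols_regression(y, cov, predictor = "age", adjust = character()))
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "age"], 0.25,
               tolerance = 1e-8)
  # permuting subject order leaves estimates unchanged
  y2 <- 2 + 0.5 * cov$diagnosis + 0.1 * cov$age + rnorm(60, sd = 0.3)
  f1 <- ols_regression(y2, cov)
  p <- sample(60)
  f2 <- ols_regression(y2[p], cov[p, ])
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-10)
  # aliased terms are named
  cov$dup <- cov$diagnosis
  expect_error(ols_regression(y2, cov, adjust = c("diagnosis", "dup")),
               "dup")
  # rows with missing covariates are dropped and counted
  cov$age[3] <- NA
  f3 <- ols_regression(y2, cov[, 1:5])
  expect_equal(f3$n_dropped, 1)
  expect_equal(f3$n_used, 59)
})

test_that("the report has one row per profile plus joint, with coherent signs", {
  coh <- small_dfnc_cohort()
  srcs <- coh$sources
  names(srcs) <- coh$covariates$subject_id
  tab <- entropy_table(srcs, coh$covariates, k = 3)
  rep_ <- build_report(tab, coh$covariates, B = 500, seed = 9)
  expect_equal(nrow(rep_), coh$truth$m + 1)
  expect_equal(rep_$variable,
               c(paste0("tfncp_", 1:coh$truth$m), "joint"))
  expect_true(all(rep_$p_ks >= 0 & rep_$p_ks <= 1))
  expect_true(all(rep_$p_perm >= 1 / 501))
  expect_true(all(is.na(rep_$q_fdr[rep_$variable == "joint"])))
  expect_true(all(rep_$q_fdr[rep_$variable != "joint"] >=
                    rep_$p_ks[rep_$variable != "joint"] - 1e-12))
  # the designed affected source (3) shows coherent negative direction
  aff <- paste0("tfncp_", coh$truth$affected_sources)
  arow <- rep_[rep_$variable %in% aff, ]
  expect_true(all(arow$beta < 0 & arow$g < 0 & arow$t_reg < 0))
  # t-test is NA-gated by normality or agrees in sign when present
  ok <- !is.na(arow$t_stat)
  expect_true(all(arow$t_stat[ok] < 0))
})

test_that("the t column is NA when a group fails the normality gate", {
  set.seed(46)
  n <- 40
  cov <- data.frame(subject_id = sprintf("S%02d", 1:(2 * n)),
                    diagnosis = rep(0:1, each = n),
                    site = sample(1:2, 2 * n, TRUE),
                    age = sample(20:60, 2 * n, TRUE),
                    gender = sample(c("F", "M"), 2 * n, TRUE))
  tab <- data.frame(subject_id = cov$subject_id,
                    tfncp_1 = c(rexp(n)^3, rexp(n)^3 + 1),  # wildly non-normal
                    tfncp_2 = c(rnorm(n), rnorm(n) + 0.5))
  tab$joint <- tab$tfncp_1 + tab$tfncp_2
  rep_ <- build_report(tab, cov, B = 200, seed = 3)
  expect_true(is.na(rep_$t_stat[1]))
  expect_false(is.na(rep_$t_stat[2]))
})
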