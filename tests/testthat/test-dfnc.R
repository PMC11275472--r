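test_that("taper is the rectangle-Gaussian convolution with the stated shape", {
  tw <- build_taper(40, 3)
  w <- tw$weights
  # length includes the truncated Gaussian tails
  expect_length(w, 40 + 2 * ceiling(4 * 3))
  # symmetric, non-negative, peak-normalized
  expect_lt(max(abs(w - rev(w))), 1e-12)
  expect_true(all(w >= 0))
  expect_equal(max(w), 1)
  # unimodal: non-decreasing then non-increasing
  d <- diff(w)
  peak <- which.max(w)
  expect_true(all(d[seq_len(peak - 1)] >= -1e-12))
  expect_true(all(d[peak:length(d)] <= 1e-12))
  # edges strictly below the center
  expect_lt(w[1], w[peak])
  # convolution conserves the rectangle's mass before peak normalization
  raw <- build_taper(40, 3, peak_normalize = FALSE)
  expect_equal(sum(raw$weights), 40, tolerance = 1e-10)
  # delta-kernel limit: taper reduces to the rectangle
  expect_equal(build_taper(40, 0)$weights, rep(1, 40))
})

test_that("sliding windowed correlations behave on degenerate channels", {
  set.seed(1)
  x <- rnorm(200)
  tc <- subject_timecourses("a", cbind(x, x, -x), tr = 2)
  s <- sliding_fnc(tc, build_taper(20, 2))
  # identical channels -> 1; channel vs its negation -> -1, in every window
  expect_true(all(abs(s$data[, 1] - 1) < 1e-12))
  expect_true(all(abs(s$data[, 2] + 1) < 1e-12))
  expect_true(all(abs(s$data[, 3] + 1) < 1e-12))
})

test_that("window bookkeeping matches floor((T - L_w)/step) + 1 and l = N(N-1)/2", {
  set.seed(2)
  tc <- subject_timecourses("a", matrix(rnorm(70 * 53), 70, 53))
  tw <- build_taper(40, 3)  # L_w = 64
  s <- sliding_fnc(tc, tw)
  expect_equal(ncol(s$data), 53 * 52 / 2)  # 1378 pairs per window
  expect_equal(nrow(s$data), 70 - 64 + 1)
  s2 <- sliding_fnc(subject_timecourses("a", matrix(rnorm(100 * 4), 100, 4)),
                    tw, step = 5)
  expect_equal(nrow(s2$data), floor((100 - 64) / 5) + 1)
})

test_that("uniform taper weights reproduce the plain Pearson correlation", {
  set.seed(3)
  X <- matrix(rnorm(60 * 6), 60, 6)
  tc <- subject_timecourses("a", X)
  flat <- structure(list(weights = rep(1, 60), rect_len = 60, gauss_sd = 0),
                    class = "taper_window")
  s <- sliding_fnc(tc, flat)   # single full-length window
  expect_equal(nrow(s$data), 1)
  expect_lt(max(abs(s$data[1, ] - vectorize_upper(cor(X)))), 1e-10)
  # and that single full window equals the static FNC
  expect_lt(max(abs(s$data[1, ] - vectorize_upper(static_fnc(tc)$matrix))),
            1e-10)
})

test_that("windowed correlation is consistent for a stationary process", {
  set.seed(4)
  n <- 5000
  z <- rnorm(n)
  x <- z
  y <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)   # true correlation 0.5
  tc <- subject_timecourses("a", cbind(x, y))
  flat <- structure(list(weights = rep(1, 40), rect_len = 40, gauss_sd = 0),
                    class = "taper_window")
  s <- sliding_fnc(tc, flat)
  expect_lt(abs(mean(s$data) - 0.5), 0.05)
})

test_that("zero-variance channels are flagged and bounded", {
  set.seed(5)
  x <- c(rep(1, 50), rnorm(100))
  tc <- subject_timecourses("a", cbind(x, rnorm(150)))
  # constant stretch puts > 5% of windows at zero variance -> hard error
  expect_error(sliding_fnc(tc, build_taper(20, 1)), "zero-variance")
})

test_that("static FNC matches cor() and rejects constant channels", {
  set.seed(6)
  X <- matrix(rnorm(10000 * 5), ncol = 5)
  tc <- subject_timecourses("a", X)
  sf <- static_fnc(tc)
  expect_equal(sf$matrix, {R <- cor(X); diag(R) <- 1; R},
               ignore_attr = TRUE)
  off <- sf$matrix[row(sf$matrix) != col(sf$matrix)]
  expect_lt(max(abs(off)), 0.05)  # independent channels at T = 10000
  Xc <- X; Xc[, 3] <- 2
  expect_error(static_fnc(subject_timecourses("a", Xc)), "net_3")
})

test_that("upper-triangle vectorization uses row-major order and round-trips", {
  M <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  expect_equal(vectorize_upper(M), c(.1, .2, .3))
  for (s in 1:3) {
    R <- rand_sym_unitdiag(7, seed = s)
    expect_equal(devectorize(vectorize_upper(R), 7), R)
  }
  expect_length(vectorize_upper(rand_sym_unitdiag(53, 1)), 1378)
  expect_error(devectorize(rep(0, 10), 53), "1378")
  expect_error(vectorize_upper(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("subject concatenation maps blocks and round-trips", {
  coh <- small_dfnc_cohort()
  cc <- concatenate_subjects(coh$subjects[1:2])
  Tn <- nrow(coh$subjects[[1]]$data)
  expect_equal(ncol(cc$X), 2 * Tn)
  expect_equal(cc$index_map$start, c(1, Tn + 1))
  expect_equal(cc$index_map$end, c(Tn, 2 * Tn))
  expect_equal(t(cc$X[, cc$index_map$start[2]:cc$index_map$end[2]]),
               coh$subjects[[2]]$data, ignore_attr = TRUE)
  # single subject: concatenation is the identity
  c1 <- concatenate_subjects(coh$subjects[1])
  expect_equal(c1$X, t(coh$subjects[[1]]$data), ignore_attr = TRUE)
  # heterogeneous window counts are rejected with the offender named
  bad <- coh$subjects[[3]]
  bad$data <- bad$data[1:10, ]
  expect_error(concatenate_subjects(list(coh$subjects[[1]], bad)),
               bad$subject_id)
})
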