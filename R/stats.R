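#' Jarque-Bera normality test
#'
#' `JB = n/6 (skewness^2 + (kurtosis - 3)^2 / 4)`, referred to a
#' chi-squared distribution with 2 degrees of freedom. Used to gate the
#' Student's t-test: groups failing normality are compared only with the
#' distribution-free tests.
#'
#' @param x Numeric sample, `n >= 8`.
#' @return List with `statistic` and `p_value`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  stopifnot(n >= 8)
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  skew <- m3 / m2^1.5
  kurt <- m4 / m2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Kolmogorov-Smirnov two-sample test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic p-value (or the exact
#' small-sample computation when requested and feasible). Thin wrapper
#' over [stats::ks.test()].
#'
#' @param x,y Numeric samples, each `n >= 4`.
#' @param exact Passed to [stats::ks.test()]; `NULL` lets it decide.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 4, length(y) >= 4)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Difference-of-means permutation test with Hedges' g
#'
#' Two-sided pooled-label permutation test of the mean difference
#' (group 1 minus group 0), with `p = (1 + #{|perm| >= |obs|}) / (B + 1)`
#' so the smallest attainable p is `1/(B+1)`. The effect size is Hedges'
#' g: the pooled-SD standardized mean difference times the small-sample
#' bias correction `1 - 3/(4 df - 1)`.
#'
#' @param x Group-1 sample (e.g. patients, contrast 1).
#' @param y Group-0 sample (e.g. controls, contrast 0).
#' @param B Number of permutations (default 10000).
#' @param seed Seed for the permutation draws.
#' @return List with `effect` (Hedges' g), `p_value`, `observed` (raw
#'   mean difference), `B`.
#' @export
perm_diff_means <- function(x, y, B = 10000L, seed = 1L) {
  stopifnot(B >= 100)
  n1 <- length(x); n0 <- length(y)
  z <- c(x, y)
  obs <- mean(x) - mean(y)
  tot <- sum(z); n <- n1 + n0
  perm <- with_seed(seed, vapply(seq_len(B), function(b) {
    s1 <- sum(z[sample.int(n, n1)])
    s1 / n1 - (tot - s1) / n0
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (B + 1)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n0 - 1) * stats::var(y)) / (n - 2))
  df <- n - 2
  g <- if (sp > 0) (obs / sp) * (1 - 3 / (4 * df - 1)) else NA_real_
  list(effect = g, p_value = p, observed = obs, B = B)
}

#' Two-sample Student's t-test
#'
#' Equal-variance two-sample t by default (the classical Student form),
#' with a Welch option. Intended to be invoked only when both groups pass
#' the Jarque-Bera normality gate; [build_report()] reports NA otherwise.
#'
#' @param x,y Numeric samples, each `n >= 3`.
#' @param welch Use the Welch unequal-variance form.
#' @return List with `statistic` and `p_value`.
#' @export
students_t <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment; `q` values are the monotone-adjusted p-values
#' and `reject` flags `q <= alpha`.
#'
#' @param p_values Vector of raw p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `q_values` and `reject` (logical).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= alpha)
}

#' Covariate-adjusted linear regression of entropy
#'
#' Ordinary least squares of an entropy measure on a focal predictor plus
#' the site, age and gender nuisance covariates. Site is dummy-coded with
#' the first site level as reference; the diagnosis contrast is 0 =
#' control, 1 = patient, so its coefficient is the adjusted
#' patient-minus-control difference. The same machinery serves the
#' clinical (PANSS, patients only) and cognitive (CMINDS) regressions by
#' changing `predictor`.
#'
#' @param y Numeric response (one entropy column), aligned with
#'   `covariates` rows.
#' @param covariates Covariate data frame (`site`, `age`, `gender`, and
#'   the predictor column).
#' @param predictor Name of the focal predictor column (default
#'   `"diagnosis"`).
#' @param adjust Nuisance columns to include (default site, age, gender).
#' @return List with `coefficients` (data frame: `term`, `beta`, `se`,
#'   `t`, `p`), `n_used`, `n_dropped`, and the fitted `model`.
#' @export
ols_regression <- function(y, covariates, predictor = "diagnosis",
                           adjust = c("site", "age", "gender")) {
  stopifnot(predictor %in% names(covariates))
  adjust <- intersect(adjust, names(covariates))
  dat <- covariates[, unique(c(predictor, adjust)), drop = FALSE]
  dat$.y <- y
  if ("site" %in% names(dat)) dat$site <- factor(dat$site)
  if ("gender" %in% names(dat)) dat$gender <- factor(dat$gender)
  keep <- stats::complete.cases(dat)
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  # drop single-level factors (e.g. one site) rather than fail
  terms <- unique(c(predictor, adjust))
  terms <- terms[vapply(terms, function(v) {
    x <- dat[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1
    else length(unique(x)) > 1
  }, TRUE)]
  for (v in terms) if (is.factor(dat[[v]])) dat[[v]] <- droplevels(dat[[v]])
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(fml, dat)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(fml, data = dat)
  ct <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(ct), beta = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(coefficients = coefs, n_used = nrow(dat), n_dropped = n_dropped,
       model = fit)
}

#' Full group-comparison report for an entropy table
#'
#' For each temporally independent FNC profile and for the joint entropy:
#' group means and variances; the covariate-adjusted regression
#' (diagnosis coefficient); the Student's t-test, gated to NA when either
#' group fails the Jarque-Bera normality test at `jb_alpha`; the
#' Kolmogorov-Smirnov two-sample test; and the difference-of-means
#' permutation test with Hedges' g. BH-FDR is applied to the per-profile
#' KS p-values (the `m`-test family); the joint entropy is a single
#' pre-specified test outside the family and is reported with its raw p.
#'
#' @param entropy Entropy table from [entropy_table()] (must contain the
#'   `tfncp_*` and `joint` columns and a `diagnosis` column, or be
#'   joinable to `covariates` on `subject_id`).
#' @param covariates Covariate table with `subject_id`, `diagnosis` and
#'   the nuisance columns.
#' @param B Permutations (default 10000).
#' @param alpha FDR level.
#' @param jb_alpha Normality-gate level for the t-test (default 0.05).
#' @param seed Seed for the permutation draws.
#' @return Data frame with one row per profile plus one for the joint
#'   entropy: `variable`, `mean_patient`, `var_patient`, `mean_control`,
#'   `var_control`, `beta`, `se`, `t_reg`, `p_reg`, `t_stat`, `p_t`,
#'   `ks`, `p_ks`, `g`, `p_perm`, `q_fdr`, `flagged`.
#' @export
build_report <- function(entropy, covariates, B = 10000L, alpha = 0.05,
                         jb_alpha = 0.05, seed = 1L) {
  if (!"diagnosis" %in% names(entropy)) {
    missing_ids <- setdiff(entropy$subject_id, covariates$subject_id)
    if (length(missing_ids))
      stop("unmatched subject ids: ", paste(missing_ids, collapse = ", "))
    entropy <- merge(entropy, covariates, by = "subject_id", sort = FALSE)
  }
  stopifnot(all(entropy$diagnosis %in% 0:1))
  vars <- c(grep("^tfncp_", names(entropy), value = TRUE), "joint")
  rows <- lapply(seq_along(vars), function(i) {
    v <- vars[i]
    y <- entropy[[v]]
    pat <- y[entropy$diagnosis == 1]
    con <- y[entropy$diagnosis == 0]
    reg <- ols_regression(y, entropy, predictor = "diagnosis")
    dr <- reg$coefficients[reg$coefficients$term == "diagnosis", ]
    normal <- jarque_bera(pat)$p_value > jb_alpha &&
      jarque_bera(con)$p_value > jb_alpha
    tt <- if (normal) students_t(pat, con)
          else list(statistic = NA_real_, p_value = NA_real_)
    ks <- ks_two_sample(pat, con)
    pm <- perm_diff_means(pat, con, B = B, seed = seed + i)
    data.frame(
      variable = v,
      mean_patient = mean(pat), var_patient = stats::var(pat),
      mean_control = mean(con), var_control = stats::var(con),
      beta = dr$beta, se = dr$se, t_reg = dr$t, p_reg = dr$p,
      t_stat = tt$statistic, p_t = tt$p_value,
      ks = ks$statistic, p_ks = ks$p_value,
      g = pm$effect, p_perm = pm$p_value,
      stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  fam <- rep_$variable != "joint"
  fdr <- bh_fdr(rep_$p_ks[fam], alpha = alpha)
  rep_$q_fdr <- NA_real_
  rep_$q_fdr[fam] <- fdr$q_values
  rep_$flagged <- FALSE
  rep_$flagged[fam] <- fdr$reject
  rep_
}
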