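# Sampling and closed-form differential entropy for the supported source
# families. Laplace is the default: super-Gaussian, so the logistic-score
# InfoMax stage separates it reliably, and its entropy is analytic
# (1 + log(2*scale)), which makes estimator-recovery tests exact.
rlaplace <- function(n, scale = 1) scale * (stats::rexp(n) - stats::rexp(n))

rgengauss <- function(n, scale = 1, shape = 1) {
  g <- stats::rgamma(n, shape = 1 / shape)^(1 / shape)
  scale * sample(c(-1, 1), n, replace = TRUE) * g
}

#' Closed-form differential entropy of a source family
#'
#' @param family One of `"laplace"`, `"gaussian"`, `"gengauss"`.
#' @param scale Scale parameter (Laplace scale b, Gaussian sd, or the
#'   generalized-Gaussian alpha).
#' @param shape Generalized-Gaussian shape (1 = Laplace, 2 = Gaussian up
#'   to reparameterization).
#' @return Entropy in nats. Shifts by `log(a)` when `scale` is multiplied
#'   by `a`, which is how designed group entropy differences are induced.
#' @export
family_entropy <- function(family, scale, shape = 1) {
  switch(family,
    laplace = 1 + log(2 * scale),
    gaussian = 0.5 * log(2 * pi * exp(1) * scale^2),
    gengauss = 1 / shape - log(shape / (2 * scale * gamma(1 / shape))),
    stop("unknown source family: ", family))
}

draw_family <- function(n, family, scale, shape = 1) {
  switch(family,
    laplace = rlaplace(n, scale),
    gaussian = stats::rnorm(n, sd = scale),
    gengauss = rgengauss(n, scale, shape),
    stop("unknown source family: ", family))
}

#' Ground truth for a synthetic cohort
#'
#' Collects everything the generator designs and every quantity needed to
#' verify downstream recovery: the connectivity-space patterns, the
#' source family and its group-level scales, which sources carry the
#' designed patient entropy reduction, the cognition coupling, and the
#' between-subject and between-site scale variability.
#'
#' @param patterns List of `m` symmetric unit-diagonal `N x N` matrices
#'   (see [generate_patterns()]).
#' @param source_family `"laplace"`, `"gaussian"` or `"gengauss"`.
#' @param control_scale Per-source control-group scale (recycled to `m`).
#' @param affected_sources Indices whose patient-group scale is reduced.
#' @param scale_ratio Patient/control scale ratio on affected sources;
#'   the designed true entropy difference is `log(scale_ratio)` nats.
#' @param cognition_coupling List: `source` (index), `slope`, `noise_sd`,
#'   `intercept` linking the cognition score to the subject's log-scale
#'   deviation on that source.
#' @param subject_scale_sd Between-subject sd of the log scale.
#' @param site_scale_sd Between-site sd of the log scale.
#' @param shape Generalized-Gaussian shape, if used.
#' @param seed Generator seed recorded with the truth.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(patterns, source_family = "laplace",
                         control_scale = 0.2, affected_sources = integer(),
                         scale_ratio = 0.5,
                         cognition_coupling = list(source = 1, slope = 3,
                                                   noise_sd = 0.6,
                                                   intercept = 0),
                         subject_scale_sd = 0.15, site_scale_sd = 0.05,
                         shape = 1, seed = 1L) {
  m <- length(patterns)
  stopifnot(m >= 1, all(affected_sources %in% seq_len(m)),
            scale_ratio > 0)
  for (p in patterns) {
    stopifnot(max(abs(p - t(p))) < 1e-10, all(abs(diag(p) - 1) < 1e-12))
    off <- p[row(p) != col(p)]
    stopifnot(all(off >= -1 & off <= 1))
  }
  control_scale <- rep_len(control_scale, m)
  structure(
    list(patterns = patterns, m = m, n_networks = nrow(patterns[[1]]),
         source_family = source_family, control_scale = control_scale,
         affected_sources = as.integer(affected_sources),
         scale_ratio = scale_ratio,
         cognition_coupling = cognition_coupling,
         subject_scale_sd = subject_scale_sd,
         site_scale_sd = site_scale_sd, shape = shape,
         seed = as.integer(seed)),
    class = "ground_truth")
}

#' Generate block-structured connectivity-space patterns
#'
#' Produces `m` symmetric unit-diagonal `N x N` matrices whose
#' off-diagonal structure is constant within blocks of networks
#' (correlated or anticorrelated domain blocks), mimicking the
#' domain-block organisation of empirical FNC patterns. Patterns are
#' redrawn until every pair has absolute vectorized correlation below
#' 0.5, so they are mutually distinguishable.
#'
#' @param m Number of patterns (>= 1).
#' @param n_networks Number of networks (>= 4).
#' @param block_spec Either an integer number of near-equal blocks or a
#'   list of index vectors partitioning `1:n_networks`.
#' @param amplitude Maximum absolute off-diagonal entry.
#' @param hetero_sd Within-block heterogeneity (sd of a symmetric
#'   Gaussian perturbation). The default `NULL` uses `amplitude / 2`,
#'   which keeps the block organisation dominant while giving patterns
#'   enough off-block texture to decorrelate even when the block-pair
#'   space is low-dimensional; `0` gives exactly block-constant patterns.
#' @param min_spread Optional floor on each pattern's spectral spread,
#'   the ratio of its off-diagonal energy to its squared spectral radius
#'   (`sum(v^2) / rho^2`). Patterns with concentrated (near-low-rank)
#'   spectra modulate connectivity with little energy once their
#'   excursions are bounded by the covariance assembly, so studies of
#'   BOLD-level recovery draw patterns with comparable spread; `0`
#'   (default) disables the constraint.
#' @param seed Seed.
#' @param max_tries Redraw limit for the distinguishability constraint.
#' @return List of `m` matrices with attribute `blocks`.
#' @export
generate_patterns <- function(m, n_networks, block_spec = 2,
                              amplitude = 0.25, hetero_sd = NULL,
                              min_spread = 0, seed = 1L,
                              max_tries = 500L) {
  stopifnot(m >= 1, n_networks >= 4, amplitude > 0, amplitude <= 1)
  if (is.null(hetero_sd)) hetero_sd <- amplitude / 2
  if (is.numeric(block_spec) && length(block_spec) == 1) {
    nb <- as.integer(block_spec)
    if (nb > n_networks)
      stop("infeasible block_spec: more blocks than networks")
    blocks <- split(seq_len(n_networks),
                    sort(rep_len(seq_len(nb), n_networks)))
  } else {
    blocks <- block_spec
    idx <- sort(unlist(blocks))
    if (!identical(idx, seq_len(n_networks)))
      stop("infeasible block_spec: blocks must partition 1:n_networks")
  }
  nb <- length(blocks)
  bl <- integer(n_networks)
  for (b in seq_len(nb)) bl[blocks[[b]]] <- b

  make_one <- function(C) {
    M <- C[bl, bl]
    if (hetero_sd > 0) {
      E <- matrix(stats::rnorm(n_networks^2, sd = hetero_sd), n_networks)
      M <- M + (E + t(E)) / 2
      M[M > 1] <- 1; M[M < -1] <- -1
    }
    diag(M) <- 1
    M
  }

  if (m == 1 && nb == 1) {
    # degenerate single all-positive block: all off-diagonals equal
    M <- matrix(amplitude, n_networks, n_networks)
    diag(M) <- 1
    out <- list(M)
    attr(out, "blocks") <- blocks
    return(out)
  }

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      pats <- lapply(seq_len(m), function(j) {
        Cf <- matrix(0, nb, nb)
        vals <- sample(c(-1, 1), nb * (nb + 1) / 2, replace = TRUE) *
          stats::runif(nb * (nb + 1) / 2, 0.3, 1) * amplitude
        Cf[upper.tri(Cf, diag = TRUE)] <- vals
        Cf <- Cf + t(Cf) - diag(diag(Cf))
        make_one(Cf)
      })
      V <- t(vapply(pats, vectorize_upper, numeric(n_networks * (n_networks - 1) / 2)))
      ok <- TRUE
      if (m > 1) {
        cc <- abs(stats::cor(t(V)))
        diag(cc) <- 0
        ok <- all(cc < 0.5)
      }
      if (ok && min_spread > 0) {
        spread <- vapply(pats, function(p) {
          diag(p) <- 0
          ev <- eigen(p, symmetric = TRUE, only.values = TRUE)$values
          sum(vectorize_upper(p)^2) / max(abs(ev))^2
        }, numeric(1))
        ok <- all(spread >= min_spread)
      }
      if (ok) {
        attr(pats, "blocks") <- blocks
        return(pats)
      }
    }
    stop("could not draw ", m, " mutually distinguishable patterns in ",
         max_tries, " tries; loosen block_spec or amplitude")
  })
}

# Per-subject, per-source scales: group scale times exp(site offset +
# subject deviation). Returns scales (m x n), the log deviations
# (m x n, subject component only -- what the cognition score couples to),
# and the site offsets.
draw_subject_scales <- function(truth, group_labels, site = NULL,
                                seed = 1L) {
  m <- truth$m
  n <- length(group_labels)
  base <- matrix(truth$control_scale, m, n)
  ratio <- rep(1, m)
  ratio[truth$affected_sources] <- truth$scale_ratio
  base[, group_labels == 1] <- base[, group_labels == 1] * ratio
  with_seed(seed, {
    dev <- matrix(stats::rnorm(m * n, sd = truth$subject_scale_sd), m, n)
    site_off <- 0
    if (!is.null(site) && truth$site_scale_sd > 0) {
      us <- sort(unique(site))
      off <- stats::rnorm(length(us), sd = truth$site_scale_sd)
      site_off <- matrix(rep(off[match(site, us)], each = m), m, n)
    }
    list(scales = base * exp(dev + site_off), log_dev = dev,
         site_offset = site_off)
  })
}

#' Generate per-subject source time courses
#'
#' Draws each subject's `m x t_windows` source matrix from the designed
#' family: values are independent across sources and, with `dwell = 1`
#' (the default), i.i.d. across time points. `dwell > 1` gives a renewal
#' process that redraws each source value every `dwell` time points while
#' keeping the same marginal, used when sources must persist on the
#' timescale of the sliding window. For sources in
#' `truth$affected_sources` the patient-group scale is
#' `scale_ratio` times the control scale, so the true per-source entropy
#' difference is exactly `log(scale_ratio)` nats.
#'
#' @param n_subjects Number of subjects.
#' @param t_windows Time points per subject (>= 50).
#' @param truth A [ground_truth()] object.
#' @param group_labels 0/1 vector (0 = control, 1 = patient).
#' @param seed Seed.
#' @param dwell Renewal interval in time points (default 1 = i.i.d.).
#' @param scales Optional precomputed `draw_subject_scales()` result (so
#'   covariates can share the same subject scales).
#' @return List of `m x t_windows` matrices with attributes
#'   `subject_scales` (`m x n`), `log_dev`, and `true_entropy`
#'   (`m x n` analytic per-subject entropies).
#' @export
generate_sources <- function(n_subjects, t_windows, truth, group_labels,
                             seed = 1L, dwell = 1L, scales = NULL) {
  stopifnot(t_windows >= 50, all(group_labels %in% 0:1),
            length(group_labels) == n_subjects, dwell >= 1)
  if (!truth$source_family %in% c("laplace", "gaussian", "gengauss"))
    stop("unknown source family: ", truth$source_family)
  if (is.null(scales))
    scales <- draw_subject_scales(truth, group_labels, seed = seed + 1L)
  m <- truth$m
  n_draw <- ceiling(t_windows / dwell)
  out <- with_seed(seed, lapply(seq_len(n_subjects), function(i) {
    S <- matrix(0, m, t_windows)
    for (j in seq_len(m)) {
      v <- draw_family(n_draw, truth$source_family,
                       scales$scales[j, i], truth$shape)
      S[j, ] <- rep(v, each = dwell)[seq_len(t_windows)]
    }
    S
  }))
  H <- matrix(family_entropy(truth$source_family, scales$scales,
                             truth$shape),
              m, n_subjects)
  attr(out, "subject_scales") <- scales$scales
  attr(out, "log_dev") <- scales$log_dev
  attr(out, "true_entropy") <- H
  out
}

#' Assemble a BOLD-level scan from sources and patterns
#'
#' Emits a `scan_len x N` network time course whose time-varying
#' covariance tracks the designed source mixture: at scan volume `tau`
#' the raw covariance is `base + sum_j s_j(w(tau)) * P_j` (patterns with
#' their unit diagonal zeroed, `w(tau)` the window index nearest `tau`),
#' stabilized by convex shrinkage towards the identity with weight
#' `shrink`, and sampled via its Cholesky factor plus white measurement
#' noise.
#'
#' Positive definiteness is guaranteed by construction at the defaults:
#' each zero-diagonal pattern is scaled to unit spectral radius
#' (`pattern_scale = "spectral"`) and source excursions are clipped at
#' `clip`, so the modulation's smallest eigenvalue is bounded below by
#' `-(1 - shrink) * m * clip`, which the defaults keep above `-1`. Both
#' operations are identical for every subject and group, so group scale
#' ratios -- and hence the designed entropy differences -- are untouched.
#' If a covariance still fails (custom settings), the offending window
#' index is reported.
#'
#' @param sources `m x t_windows` source matrix; `t_windows` must equal
#'   `scan_len - L_w + 1` for the window length `L_w` the downstream
#'   analysis will use.
#' @param patterns List of `m` symmetric unit-diagonal pattern matrices.
#' @param scan_len Number of scan volumes.
#' @param noise_sd White measurement-noise sd (default 0.1).
#' @param shrink Identity-shrinkage weight in `[0, 1)` (default 0.5).
#' @param base Baseline covariance (default identity).
#' @param clip Source clipping bound (default 0.45).
#' @param pattern_scale `"spectral"` (default) rescales each
#'   zero-diagonal pattern to unit spectral radius before modulation;
#'   `"none"` uses the raw pattern entries.
#' @param tr Repetition time in seconds.
#' @param seed Seed.
#' @param subject_id Identifier for the emitted time courses.
#' @return A [subject_timecourses()] object.
#' @export
assemble_bold <- function(sources, patterns, scan_len, noise_sd = 0.1,
                          shrink = 0.5, base = NULL, clip = 0.45,
                          pattern_scale = c("spectral", "none"), tr = 2,
                          seed = 1L, subject_id = "S001") {
  pattern_scale <- match.arg(pattern_scale)
  sources <- as.matrix(sources)
  m <- nrow(sources); tw <- ncol(sources)
  N <- nrow(patterns[[1]])
  Lw <- scan_len - tw + 1L
  if (Lw < 1)
    stop("t_windows inconsistent with scan_len: need t_windows = scan_len - L_w + 1")
  if (is.null(base)) base <- diag(N)
  P0 <- lapply(patterns, function(p) { p <- as.matrix(p); diag(p) <- 0; p })
  if (pattern_scale == "spectral")
    P0 <- lapply(P0, function(p)
      p / max(abs(eigen(p, symmetric = TRUE, only.values = TRUE)$values)))
  s_clip <- pmin(pmax(sources, -clip), clip)
  widx <- pmin(pmax(seq_len(scan_len) - Lw %/% 2L, 1L), tw)
  chol_cache <- vector("list", tw)
  X <- with_seed(seed, {
    Z <- matrix(stats::rnorm(scan_len * N), scan_len, N)
    E <- matrix(stats::rnorm(scan_len * N, sd = noise_sd), scan_len, N)
    out <- matrix(0, scan_len, N)
    for (tau in seq_len(scan_len)) {
      u <- widx[tau]
      if (is.null(chol_cache[[u]])) {
        Sig <- base
        for (j in seq_len(m)) Sig <- Sig + s_clip[j, u] * P0[[j]]
        Sig <- shrink * diag(N) + (1 - shrink) * Sig
        L <- tryCatch(chol(Sig), error = function(e)
          stop(sprintf("covariance not positive definite at window %d", u),
               call. = FALSE))
        chol_cache[[u]] <- L
      }
      out[tau, ] <- Z[tau, ] %*% chol_cache[[u]]
    }
    out + E
  })
  subject_timecourses(subject_id, X, tr = tr)
}

# Direct dFNC-level trajectory record: window sample t is the source
# mixture in vectorized connectivity space plus white noise. Fast path
# for decomposition/entropy tests that bypasses BOLD assembly and
# windowed estimation.
dfnc_level_series <- function(sources, patterns, noise_sd = 0.05,
                              seed = 1L, subject_id = "S001") {
  sources <- as.matrix(sources)
  m <- nrow(sources); tw <- ncol(sources)
  N <- nrow(patterns[[1]])
  l <- N * (N - 1) / 2
  V <- t(vapply(patterns, function(p) {
    p <- as.matrix(p); diag(p) <- 0; vectorize_upper(p)
  }, numeric(l)))                      # m x l
  Y <- t(sources) %*% V
  Y <- Y + with_seed(seed, matrix(stats::rnorm(tw * l, sd = noise_sd), tw, l))
  structure(
    list(subject_id = subject_id, data = Y, window_centers = seq_len(tw),
         n_networks = N, taper = NULL, step = 1L, fisher_z = FALSE),
    class = "dfnc_series")
}

#' Generate the subject covariate table
#'
#' Assigns balanced-ish site and gender labels, ages drawn from 18-65,
#' the 0/1 diagnosis contrast, PANSS positive/negative scores for
#' patients only (controls are NA), and a cognition score linearly
#' coupled to the subjects' log-scale deviation on the designed source:
#' `cminds = intercept + slope * dev + noise`.
#'
#' @param n_subjects Number of subjects.
#' @param n_sites Number of collection sites (>= 1).
#' @param truth A [ground_truth()] object.
#' @param group_labels 0/1 diagnosis vector.
#' @param seed Seed.
#' @param log_dev Optional `m x n` matrix of subject log-scale deviations
#'   (from [generate_sources()]'s `log_dev` attribute) so the cognition
#'   score couples to the same draw that produced the sources.
#' @param site Optional pre-assigned site vector.
#' @return Data frame: `subject_id`, `diagnosis`, `site`, `age`,
#'   `gender`, `panss_pos`, `panss_neg`, `cminds`.
#' @export
generate_covariates <- function(n_subjects, n_sites, truth, group_labels,
                                seed = 1L, log_dev = NULL, site = NULL) {
  stopifnot(n_sites >= 1, length(group_labels) == n_subjects)
  cc <- truth$cognition_coupling
  with_seed(seed, {
    if (is.null(site))
      site <- sample(rep_len(seq_len(n_sites), n_subjects))
    gender <- sample(rep_len(c("F", "M"), n_subjects))
    age <- sample(18:65, n_subjects, replace = TRUE)
    pat <- group_labels == 1
    panss_pos <- panss_neg <- rep(NA_real_, n_subjects)
    panss_pos[pat] <- pmin(pmax(round(stats::rnorm(sum(pat), 15, 5)), 7), 49)
    panss_neg[pat] <- pmin(pmax(round(stats::rnorm(sum(pat), 15, 5)), 7), 49)
    dev <- if (is.null(log_dev)) rep(0, n_subjects) else log_dev[cc$source, ]
    cminds <- cc$intercept + cc$slope * dev +
      stats::rnorm(n_subjects, sd = cc$noise_sd)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      diagnosis = as.integer(group_labels), site = site, age = age,
      gender = gender, panss_pos = panss_pos, panss_neg = panss_neg,
      cminds = cminds, stringsAsFactors = FALSE)
  })
}

# Population slope of the regression of (true) entropy on the cognition
# score implied by the generative coupling: entropy dev = d,
# cminds = a + b d + e  =>  beta = b var(d) / (b^2 var(d) + var(e)).
implied_cminds_slope <- function(truth) {
  b <- truth$cognition_coupling$slope
  vd <- truth$subject_scale_sd^2
  ve <- truth$cognition_coupling$noise_sd^2
  b * vd / (b^2 * vd + ve)
}

#' Simulate a complete two-group cohort
#'
#' The study-condition generator: a balanced two-group cohort whose
#' patient group carries a designed entropy reduction of
#' `-log(scale_ratio)` nats on the affected sources, with site/age/gender
#' nuisance structure and a cognition score coupled to one source.
#' Defaults define the package's reference validation study: 60 subjects
#' (30 per group), 20 networks, 160 scan volumes, 4 sources of which 2
#' are affected at scale ratio 1/2 (entropy reduction `log 2`), seven
#' collection sites, Laplace sources.
#'
#' At `level = "bold"` subjects are full scans assembled via
#' [assemble_bold()], with sources persisting `dwell` TRs (default 40, on
#' the order of the analysis window, as dFNC state dwell times are); at
#' `level = "dfnc"` subjects are direct trajectory records (i.i.d.
#' sources, `dwell = 1`), the fast path for decomposition and entropy
#' testing.
#'
#' @param n_subjects Even subject count (half controls, half patients).
#' @param n_networks,m,scan_len,rect_len,gauss_sd Study dimensions.
#' @param level `"bold"` or `"dfnc"`.
#' @param t_windows Trajectory length for `level = "dfnc"` (default 300).
#' @param n_sites Number of sites.
#' @param affected_sources Indices with the designed reduction (default
#'   the last two sources).
#' @param scale_ratio Patient/control scale ratio on affected sources.
#' @param control_scale Control-group source scale.
#' @param dwell Source renewal interval; `NULL` picks 40 for BOLD, 1 for
#'   dFNC level.
#' @param noise_sd Measurement-noise sd at the chosen level.
#' @param amplitude Pattern off-diagonal amplitude.
#' @param block_spec,min_spread Passed to [generate_patterns()].
#' @param source_family,shape Source marginal family.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `synthetic_cohort`: `subjects` (named list),
#'   `covariates`, `truth`, `level`, plus generator bookkeeping. The
#'   truth carries `subject_scales` and the analytic `true_entropy`
#'   matrix (`m x n` nats).
#' @export
simulate_cohort <- function(n_subjects = 60, n_networks = 20, m = 4,
                            scan_len = 160, level = c("bold", "dfnc"),
                            t_windows = 300, n_sites = 7,
                            affected_sources = NULL, scale_ratio = 0.5,
                            control_scale = 0.2, dwell = NULL,
                            noise_sd = NULL, amplitude = 0.25,
                            block_spec = 2, min_spread = 0,
                            source_family = "laplace",
                            shape = 1, rect_len = 40, gauss_sd = 3,
                            seed = 1L) {
  level <- match.arg(level)
  stopifnot(n_subjects >= 4, n_subjects %% 2 == 0, m >= 2)
  if (is.null(affected_sources))
    affected_sources <- seq.int(m - 1L, m)
  if (is.null(dwell)) dwell <- if (level == "bold") 40L else 1L
  if (is.null(noise_sd)) noise_sd <- if (level == "bold") 0.1 else 0.05
  group_labels <- rep(0:1, each = n_subjects / 2)
  site <- with_seed(seed + 5L,
                    sample(rep_len(seq_len(n_sites), n_subjects)))
  patterns <- generate_patterns(m, n_networks, block_spec = block_spec,
                                amplitude = amplitude,
                                min_spread = min_spread, seed = seed + 1L)
  truth <- ground_truth(patterns, source_family = source_family,
                        control_scale = control_scale,
                        affected_sources = affected_sources,
                        scale_ratio = scale_ratio, shape = shape,
                        seed = seed)
  if (level == "bold") {
    taper <- build_taper(rect_len, gauss_sd)
    Lw <- length(taper$weights)
    if (scan_len < Lw + 50)
      stop("scan_len too short for the analysis window")
    t_windows <- scan_len - Lw + 1L
  }
  scales <- draw_subject_scales(truth, group_labels,
                                site = site, seed = seed + 2L)
  sources <- generate_sources(n_subjects, t_windows, truth, group_labels,
                              seed = seed + 3L, dwell = dwell,
                              scales = scales)
  covariates <- generate_covariates(n_subjects, n_sites, truth,
                                    group_labels, seed = seed + 4L,
                                    log_dev = scales$log_dev, site = site)
  ids <- covariates$subject_id
  subjects <- lapply(seq_len(n_subjects), function(i) {
    if (level == "bold")
      assemble_bold(sources[[i]], patterns, scan_len,
                    noise_sd = noise_sd, seed = seed + 100L + i,
                    subject_id = ids[i])
    else
      dfnc_level_series(sources[[i]], patterns, noise_sd = noise_sd,
                        seed = seed + 100L + i, subject_id = ids[i])
  })
  names(subjects) <- ids
  truth$subject_scales <- scales$scales
  truth$log_dev <- scales$log_dev
  truth$true_entropy <- attr(sources, "true_entropy")
  truth$group_labels <- group_labels
  structure(
    list(subjects = subjects, covariates = covariates, truth = truth,
         sources = sources, level = level, dwell = dwell,
         noise_sd = noise_sd, scan_len = if (level == "bold") scan_len else NA,
         t_windows = t_windows, rect_len = rect_len, gauss_sd = gauss_sd,
         seed = as.integer(seed)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d patients), %d networks, %d sources, level = %s\n",
    length(x$subjects), sum(x$covariates$diagnosis), x$truth$n_networks,
    x$truth$m, x$level))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per-subject time courses as TSV (header row of network names),
#' covariates as CSV, ground truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result (`level = "bold"`).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    if (!inherits(s, "subject_timecourses"))
      stop("write_cohort requires a BOLD-level cohort")
    utils::write.table(
      s$data, file.path(dir, paste0(s$subject_id, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  truth <- unclass(cohort$truth)
  truth$patterns <- lapply(truth$patterns, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one subject's time courses from TSV
#'
#' @param path TSV file, `T_scan` rows by `N` named network columns.
#' @param tr Repetition time in seconds.
#' @param subject_id Identifier; defaults to the file name sans extension.
#' @return A [subject_timecourses()] object.
#' @export
read_timecourses <- function(path, tr = 2, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  dat <- utils::read.delim(path, check.names = FALSE)
  subject_timecourses(subject_id, as.matrix(dat), tr = tr)
}

#' Read a covariate table from CSV
#'
#' @param path CSV with at least `subject_id` and `diagnosis` columns.
#' @return Data frame.
#' @export
read_covariates <- function(path) {
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "diagnosis") %in% names(cov)))
    stop("covariate table must contain subject_id and diagnosis columns")
  cov
}
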