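#' Build the tapered sliding-window weights
#'
#' Convolves a rectangle of `rect_len` TRs with a Gaussian kernel of
#' standard deviation `gauss_sd` TRs (truncated at +/- 4 sd and
#' renormalized to unit mass), the taper used to weight samples inside
#' each sliding window. The default 40-TR rectangle with sd 3 is the
#' standard dFNC choice.
#'
#' @param rect_len Rectangle length in TRs (>= 2).
#' @param gauss_sd Gaussian standard deviation in TRs; `0` gives a plain
#'   rectangular window (delta kernel).
#' @param peak_normalize Scale weights so the maximum equals 1 (default).
#'   With `FALSE` the raw convolution is returned, whose mass equals
#'   `rect_len` (rectangle mass times the unit-mass kernel).
#' @return An object of class `taper_window` with fields `weights`,
#'   `rect_len`, `gauss_sd`.
#' @export
build_taper <- function(rect_len = 40, gauss_sd = 3, peak_normalize = TRUE) {
  stopifnot(rect_len >= 2, gauss_sd >= 0)
  rect <- rep(1, rect_len)
  if (gauss_sd > 0) {
    h <- ceiling(4 * gauss_sd)
    kern <- stats::dnorm(seq(-h, h), mean = 0, sd = gauss_sd)
    kern <- kern / sum(kern)
    # full ("open") discrete convolution
    w <- stats::convolve(rect, rev(kern), type = "open")
    w[w < 0] <- 0  # guard tiny negative FFT round-off
  } else {
    w <- rect
  }
  if (peak_normalize) w <- w / max(w)
  structure(list(weights = as.numeric(w), rect_len = rect_len,
                 gauss_sd = gauss_sd),
            class = "taper_window")
}

#' @export
print.taper_window <- function(x, ...) {
  cat(sprintf("<taper_window> length %d (rect %d TR, Gaussian sd %g TR)\n",
              length(x$weights), x$rect_len, x$gauss_sd))
  invisible(x)
}

# Taper-weighted Pearson correlation of the columns of X.
# With uniform weights this reduces exactly to cor(X) (the n vs n-1
# divisors cancel in the correlation ratio). Channels with zero weighted
# variance yield NA rows/columns.
weighted_corr <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu, "-")
  C <- crossprod(Xc * sqrt(w))
  v <- diag(C)
  sd <- sqrt(pmax(v, 0))
  # constant channels leave only round-off variance; flag relative to level
  bad <- !is.finite(sd) | v <= 1e-20 * (1 + mu^2)
  sd[bad] <- NA_real_
  R <- C / tcrossprod(sd)
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- ifelse(bad, NA_real_, 1)
  R
}

#' Tapered sliding-window dynamic FNC
#'
#' Slides the taper along the scan in steps of `step` TRs and computes, at
#' each position, the taper-weighted Pearson correlation matrix of the `N`
#' network channels, vectorized to its strictly upper triangle (row-major;
#' see [vectorize_upper()]). The resulting `T x l` record, with
#' `l = N(N-1)/2`, is the subject's trajectory through connectivity space.
#' Windows are fully interior: `T = floor((T_scan - L_w)/step) + 1` where
#' `L_w` is the full taper length including the Gaussian tails.
#'
#' @param tc A [subject_timecourses()] object.
#' @param taper A [build_taper()] window.
#' @param step Window step in TRs (default 1).
#' @param fisher_z Apply the Fisher z-transform to the windowed
#'   correlations (off by default; provided for sensitivity analysis).
#' @return An object of class `dfnc_series` with fields `subject_id`,
#'   `data` (`T x l`), `window_centers` (TR indices), `n_networks`.
#' @export
sliding_fnc <- function(tc, taper = build_taper(), step = 1,
                        fisher_z = FALSE) {
  stopifnot(inherits(tc, "subject_timecourses"),
            inherits(taper, "taper_window"), step >= 1)
  X <- tc$data
  Tn <- nrow(X); N <- ncol(X)
  w <- taper$weights
  Lw <- length(w)
  if (Tn < Lw)
    stop(sprintf("scan length %d shorter than window length %d", Tn, Lw))
  starts <- seq(1L, Tn - Lw + 1L, by = as.integer(step))
  l <- N * (N - 1) / 2
  out <- matrix(NA_real_, length(starts), l)
  n_flagged <- 0L
  for (i in seq_along(starts)) {
    win <- X[starts[i]:(starts[i] + Lw - 1L), , drop = FALSE]
    R <- weighted_corr(win, w)
    if (anyNA(R)) n_flagged <- n_flagged + 1L
    out[i, ] <- t(R)[lower.tri(R)]
  }
  if (n_flagged > 0) {
    if (n_flagged / length(starts) > 0.05)
      stop(sprintf("%d of %d windows (>5%%) have zero-variance channels",
                   n_flagged, length(starts)))
    warning(sprintf("%d window(s) contain zero-variance channels; affected entries set to NA",
                    n_flagged))
  }
  if (fisher_z) out <- atanh(pmin(pmax(out, -1 + 1e-12), 1 - 1e-12))
  structure(
    list(subject_id = tc$subject_id, data = out,
         window_centers = starts + (Lw - 1) / 2, n_networks = N,
         taper = taper, step = step, fisher_z = fisher_z),
    class = "dfnc_series"
  )
}

#' @export
print.dfnc_series <- function(x, ...) {
  cat(sprintf("<dfnc_series> %s: %d windows x %d pairs (%d networks)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$n_networks))
  invisible(x)
}

#' Static (whole-scan) functional network connectivity
#'
#' Full-scan Pearson correlation matrix of the network time courses.
#'
#' @param tc A [subject_timecourses()] object.
#' @return Object of class `static_fnc`: list with `subject_id` and the
#'   `N x N` correlation `matrix`.
#' @export
static_fnc <- function(tc) {
  stopifnot(inherits(tc, "subject_timecourses"))
  X <- tc$data
  if (nrow(X) < ncol(X) + 1)
    stop("scan too short for a full-rank correlation estimate")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant channel(s): ",
         paste(tc$network_names[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  diag(R) <- 1
  structure(list(subject_id = tc$subject_id, matrix = R),
            class = "static_fnc")
}

#' Concatenate subject trajectory records for group decomposition
#'
#' Stacks the vectorized windowed-correlation records of all subjects into
#' a single `l x K` matrix (`K = n_subjects * T`), columns being window
#' samples, together with an index map locating each subject's contiguous
#' block.
#'
#' @param series List of [sliding_fnc()] results sharing `n_networks` and
#'   window count.
#' @return List with `X` (`l x K` matrix), `index_map` (data frame:
#'   `subject_id`, `start`, `end`), `n_networks`, `t_windows`.
#' @export
concatenate_subjects <- function(series) {
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, TRUE, "dfnc_series")))
  ns <- vapply(series, function(s) s$n_networks, 1L)
  ts <- vapply(series, function(s) nrow(s$data), 1L)
  if (length(unique(ns)) > 1 || length(unique(ts)) > 1) {
    ids <- vapply(series, function(s) s$subject_id, "")
    bad <- ids[ns != ns[1] | ts != ts[1]]
    stop("heterogeneous dimensions for subjects: ",
         paste(bad, collapse = ", "))
  }
  Tn <- ts[1]
  X <- do.call(cbind, lapply(series, function(s) t(s$data)))
  ends <- cumsum(rep(Tn, length(series)))
  index_map <- data.frame(
    subject_id = vapply(series, function(s) s$subject_id, ""),
    start = ends - Tn + 1L, end = ends,
    stringsAsFactors = FALSE)
  list(X = X, index_map = index_map, n_networks = ns[1], t_windows = Tn)
}
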