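# Optional per-network time-series cleaning, run in the fixed order
# detrend -> nuisance regression -> despike -> band-pass, matching the
# noise-removal sequence applied upstream of FNC estimation in
# resting-state pipelines. Every stage preserves the matrix shape and
# subject metadata.

#' Polynomial detrending
#'
#' Removes the least-squares polynomial fit of order up to `max_order`
#' (including the mean) from each network column. Orders 1-3 remove
#' linear, quadratic and cubic scanner drift.
#'
#' @param tc A [subject_timecourses()] object.
#' @param max_order 1, 2 or 3 (default 3).
#' @return The detrended [subject_timecourses()].
#' @export
detrend_poly <- function(tc, max_order = 3) {
  stopifnot(inherits(tc, "subject_timecourses"), max_order %in% 1:3)
  Tn <- nrow(tc$data)
  if (Tn <= max_order + 1)
    stop("degenerate fit: scan length must exceed max_order + 1")
  X <- cbind(1, stats::poly(seq_len(Tn), max_order))
  tc$data <- stats::lm.fit(X, tc$data)$residuals
  colnames(tc$data) <- tc$network_names
  tc
}

#' Nuisance regression
#'
#' Regresses each network column on an intercept plus the nuisance design
#' (e.g. the six realignment parameters and their temporal derivatives)
#' and keeps the residuals.
#'
#' @param tc A [subject_timecourses()] object.
#' @param design `T_scan x p` numeric matrix of nuisance regressors.
#' @return The residual [subject_timecourses()].
#' @export
regress_nuisance <- function(tc, design) {
  stopifnot(inherits(tc, "subject_timecourses"))
  design <- as.matrix(design)
  if (nrow(design) != nrow(tc$data))
    stop("design has ", nrow(design), " rows; expected ", nrow(tc$data))
  X <- cbind(`(intercept)` = 1, design)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    cn <- colnames(X)
    if (is.null(cn)) cn <- paste0("col", seq_len(ncol(X)))
    aliased <- cn[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  tc$data <- qr.resid(qrx, tc$data)
  colnames(tc$data) <- tc$network_names
  tc
}

#' Despiking by robust-z median replacement
#'
#' Flags samples whose robust z-score (median/MAD) exceeds `z_thresh` and
#' replaces each with the median of a centered 5-sample window of the
#' original column (clamped at the scan edges). Columns with zero MAD
#' (constant or near-constant) are left untouched.
#'
#' @param tc A [subject_timecourses()] object.
#' @param z_thresh Robust-z threshold (default 3.5).
#' @return The despiked [subject_timecourses()].
#' @export
despike <- function(tc, z_thresh = 3.5) {
  stopifnot(inherits(tc, "subject_timecourses"), z_thresh > 0)
  Tn <- nrow(tc$data)
  for (j in seq_len(ncol(tc$data))) {
    x <- tc$data[, j]
    md <- stats::median(x)
    s <- stats::mad(x)
    if (s == 0) next
    bad <- which(abs(x - md) / s > z_thresh)
    for (i in bad) {
      lo <- max(1L, i - 2L); hi <- min(Tn, i + 2L)
      tc$data[i, j] <- stats::median(x[lo:hi])
    }
  }
  tc
}

#' Zero-phase band-pass filtering
#'
#' Forward-backward (zero-phase) Butterworth band-pass, selecting the
#' resting-state band (default contract 0.01-0.15 Hz upstream). Zero
#' phase avoids shifting the signal relative to the sliding windows
#' downstream.
#'
#' @param tc A [subject_timecourses()] object.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @param order Butterworth order (default 5).
#' @return The filtered [subject_timecourses()].
#' @export
bandpass <- function(tc, low_hz = 0.01, high_hz = 0.15, order = 5) {
  stopifnot(inherits(tc, "subject_timecourses"))
  nyq <- 1 / (2 * tc$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("infeasible band [%g, %g] Hz for TR = %gs (Nyquist %g Hz)",
                 low_hz, high_hz, tc$tr, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  tc$data <- apply(tc$data, 2, function(x)
    signal::filtfilt(bf, x - mean(x)))
  colnames(tc$data) <- tc$network_names
  tc
}

#' Run the full cleaning sequence
#'
#' Applies detrend, optional nuisance regression, despiking and band-pass
#' in the fixed upstream order.
#'
#' @param tc A [subject_timecourses()] object.
#' @param design Optional nuisance design matrix.
#' @param max_order,z_thresh,low_hz,high_hz,order Stage parameters.
#' @return The cleaned [subject_timecourses()].
#' @export
preprocess_timecourses <- function(tc, design = NULL, max_order = 3,
                                   z_thresh = 3.5, low_hz = 0.01,
                                   high_hz = 0.15, order = 5) {
  tc <- detrend_poly(tc, max_order)
  if (!is.null(design)) tc <- regress_nuisance(tc, design)
  tc <- despike(tc, z_thresh)
  bandpass(tc, low_hz, high_hz, order)
}
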