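#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state; restores .Random.seed afterwards so
# seeded package functions never clobber the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a subject time-course container
#'
#' Holds one subject's network time courses (rows = scan volumes, columns =
#' networks), the repetition time, and network labels. This is the raw input
#' to the connectivity stages.
#'
#' @param subject_id Character scalar identifier.
#' @param data Numeric matrix, `T_scan` rows by `N` network columns; no
#'   missing values.
#' @param tr Repetition time in seconds.
#' @param network_names Character vector of length `N`; defaults to the
#'   matrix column names or `net_1..N`.
#' @return An object of class `subject_timecourses`.
#' @export
subject_timecourses <- function(subject_id, data, tr = 2,
                                network_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("time courses contain missing values")
  if (is.null(network_names)) {
    network_names <- colnames(data)
    if (is.null(network_names))
      network_names <- paste0("net_", seq_len(ncol(data)))
  }
  if (length(network_names) != ncol(data))
    stop("length(network_names) must equal ncol(data)")
  colnames(data) <- network_names
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr = as.numeric(tr), network_names = network_names),
    class = "subject_timecourses"
  )
}

#' @export
print.subject_timecourses <- function(x, ...) {
  cat(sprintf("<subject_timecourses> %s: %d volumes x %d networks (TR = %gs)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Uses a fixed row-major ordering of the strictly upper triangle,
#' `(1,2), (1,3), ..., (1,n), (2,3), ...`; the same ordering is used
#' everywhere patterns are reshaped, so connectivity vectors and matrices
#' are always mutually consistent.
#'
#' @param mat Square numeric matrix, symmetric within `tol`.
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length `n(n-1)/2`.
#' @seealso [devectorize()]
#' @export
vectorize_upper <- function(mat, tol = 1e-8) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) != n) stop("matrix must be square")
  if (max(abs(mat - t(mat)), na.rm = TRUE) > tol)
    stop("matrix is not symmetric within tolerance ", tol)
  # row-major upper triangle == column-major lower triangle of the transpose
  t(mat)[lower.tri(mat)]
}

#' Rebuild a symmetric matrix from an upper-triangle vector
#'
#' Inverse of [vectorize_upper()] off the diagonal; the diagonal is set to
#' `diag_value` (1 for correlation matrices, 0 for connectivity-space
#' loading patterns).
#'
#' @param vec Numeric vector of length `n(n-1)/2`.
#' @param n Matrix dimension.
#' @param diag_value Value placed on the diagonal.
#' @return `n` by `n` symmetric matrix.
#' @export
devectorize <- function(vec, n, diag_value = 1) {
  l <- n * (n - 1) / 2
  if (length(vec) != l) {
    n_inferred <- (1 + sqrt(1 + 8 * length(vec))) / 2
    stop(sprintf(
      "vector length %d does not match n = %d (l must be %d; length implies n = %.2f)",
      length(vec), n, l, n_inferred))
  }
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- vec
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Match estimated components to reference components
#'
#' Greedy one-to-one assignment of estimated to reference components by
#' absolute correlation of their row vectors (patterns or source time
#' courses), resolving ICA's permutation and sign indeterminacy for
#' recovery assessment.
#'
#' @param est,ref Matrices with one component per row, same dimensions.
#' @return List with `perm` (`perm[j]` is the estimated row matched to
#'   reference row `j`), `abs_cor` (matched absolute correlations) and
#'   `sign` (matched correlation signs).
#' @export
match_components <- function(est, ref) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  stopifnot(nrow(est) == nrow(ref), ncol(est) == ncol(ref))
  m <- nrow(est)
  cmat <- stats::cor(t(est), t(ref))
  perm <- integer(m); corr <- numeric(m); sgn <- numeric(m)
  amat <- abs(cmat)
  for (step in seq_len(m)) {
    ij <- arrayInd(which.max(amat), dim(amat))
    i <- ij[1]; j <- ij[2]
    perm[j] <- i
    corr[j] <- amat[i, j]
    sgn[j] <- sign(cmat[i, j])
    amat[i, ] <- -Inf; amat[, j] <- -Inf
  }
  list(perm = perm, abs_cor = corr, sign = sgn)
}
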