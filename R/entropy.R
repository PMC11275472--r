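# Volume of the m-dimensional Euclidean unit ball: pi^(m/2)/Gamma(m/2+1).
# c1(1) = 2, c1(2) = pi.
unit_ball_volume <- function(m) {
  stopifnot(m >= 1)
  pi^(m / 2) / gamma(m / 2 + 1)
}

#' k-th nearest-neighbor distances
#'
#' Euclidean distance from each sample point to its `k`-th nearest
#' neighbor among the remaining points (self excluded). One-dimensional
#' input uses an O(N k) sorted-neighborhood scan; higher dimensions use a
#' chunked brute-force distance computation.
#'
#' @param samples Numeric vector (1-D) or `N x d` matrix of points.
#' @param k Neighbor order, `1 <= k < N`.
#' @return Numeric vector of length `N` of k-th neighbor distances, in the
#'   original sample order.
#' @export
knn_distances <- function(samples, k) {
  X <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  n <- nrow(X)
  stopifnot(k >= 1, k < n)
  if (ncol(X) == 1L) {
    x <- X[, 1]
    ord <- order(x)
    xs <- x[ord]
    cand <- matrix(Inf, n, 2L * k)
    for (j in seq_len(k)) {
      idx <- seq_len(n)
      lo <- idx - j; hi <- idx + j
      dl <- ifelse(lo >= 1, xs - xs[pmax(lo, 1)], Inf)
      dh <- ifelse(hi <= n, xs[pmin(hi, n)] - xs, Inf)
      cand[, 2L * j - 1L] <- dl
      cand[, 2L * j] <- dh
    }
    rho_sorted <- apply(cand, 1, function(r) sort(r, partial = k)[k])
    rho <- numeric(n)
    rho[ord] <- rho_sorted
    return(rho)
  }
  rs <- rowSums(X^2)
  rho <- numeric(n)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    D2 <- outer(rs[s:e], rs, "+") - 2 * X[s:e, , drop = FALSE] %*% t(X)
    D2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    D2[D2 < 0] <- 0
    rho[s:e] <- apply(D2, 1, function(r) sort(r, partial = k)[k])
  }
  sqrt(rho)
}

#' Kozachenko-Leonenko differential entropy estimate
#'
#' Nonparametric k-nearest-neighbor estimator of the differential entropy
#' of a continuous distribution from samples:
#' `H = m * log(geometric mean of k-th NN distances) + log(N - 1) -
#' digamma(k) + log c1(m)`, with `c1(m)` the volume of the
#' `m`-dimensional Euclidean unit ball. Returned in nats. The estimator is
#' exactly scale-equivariant: `H(a X) = H(X) + m log|a|`.
#'
#' Exact duplicate points (which would make the geometric mean of
#' distances degenerate) are broken by a seeded Gaussian jitter of
#' standard deviation `jitter_sd` (default `1e-10` times the sample
#' standard deviation), applied only when duplicates exist.
#'
#' @param samples Numeric vector or `N x m` matrix of samples.
#' @param k Neighbor order (default 3).
#' @param jitter_sd Tie-breaking jitter standard deviation; `NULL` for the
#'   default relative scale.
#' @param seed Seed for the tie-breaking jitter.
#' @return Entropy estimate in nats.
#' @export
kl_entropy <- function(samples, k = 3, jitter_sd = NULL, seed = 0L) {
  X <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  storage.mode(X) <- "double"
  n <- nrow(X); m <- ncol(X)
  if (n < k + 2) stop("need at least k + 2 samples")
  if (anyDuplicated(asplit(X, 1))) {
    if (is.null(jitter_sd)) {
      s <- stats::sd(as.vector(X))
      jitter_sd <- 1e-10 * if (s > 0) s else 1
    }
    if (jitter_sd > 0)
      X <- X + with_seed(seed, matrix(stats::rnorm(n * m, sd = jitter_sd), n, m))
  }
  rho <- knn_distances(X, k)
  if (any(rho == 0))
    stop("zero k-th neighbor distance; increase jitter_sd to break exact ties")
  m * mean(log(rho)) + log(n - 1) - digamma(k) + log(unit_ball_volume(m))
}

#' Per-source entropy of one subject's trajectory
#'
#' Applies the Kozachenko-Leonenko estimator to each source time course
#' of a subject's `m x T` source matrix, treating the `T` window samples
#' of a source as scalar draws from its marginal.
#'
#' @param sources `m x T` numeric matrix (rows = sources).
#' @param k Neighbor order.
#' @param jitter_sd,seed Passed to [kl_entropy()].
#' @return Numeric vector of `m` entropies (nats).
#' @export
subject_entropy <- function(sources, k = 3, jitter_sd = NULL, seed = 0L) {
  sources <- as.matrix(sources)
  stopifnot(ncol(sources) >= k + 2)
  vapply(seq_len(nrow(sources)), function(j) {
    tryCatch(
      kl_entropy(sources[j, ], k = k, jitter_sd = jitter_sd, seed = seed),
      error = function(e) stop(sprintf("source %d: %s", j, conditionMessage(e)),
                               call. = FALSE))
  }, numeric(1))
}

#' Joint entropy of independent sources
#'
#' Sum of the per-source entropies. Valid as a joint-entropy estimate only
#' because the upstream ICA stage maximizes the temporal independence of
#' the sources; dependence between sources would make the sum an upper
#' bound rather than an estimate.
#'
#' @param per_source Numeric vector of per-source entropies (nats).
#' @return Scalar joint entropy (nats).
#' @export
joint_entropy <- function(per_source) {
  if (!all(is.finite(per_source)))
    stop("non-finite per-source entropy")
  sum(per_source)
}

#' Build the subject-by-source entropy table
#'
#' Computes every subject's per-source and joint entropy and joins the
#' covariate table on `subject_id`.
#'
#' @param subject_sources Named list (by subject id) of `m x T` source
#'   matrices, e.g. from [split_subject_sources()].
#' @param covariates Optional covariate data frame with a `subject_id`
#'   column; joined onto the result.
#' @param k,jitter_sd,seed Passed to [kl_entropy()].
#' @return Data frame: `subject_id`, `tfncp_1..m`, `joint`, then any
#'   covariates. The `joint` column equals the row sum of the per-source
#'   columns exactly.
#' @export
entropy_table <- function(subject_sources, covariates = NULL, k = 3,
                          jitter_sd = NULL, seed = 0L) {
  stopifnot(length(subject_sources) >= 1)
  ids <- names(subject_sources)
  if (is.null(ids)) ids <- paste0("S", seq_along(subject_sources))
  H <- t(vapply(subject_sources, subject_entropy,
                numeric(nrow(subject_sources[[1]])),
                k = k, jitter_sd = jitter_sd, seed = seed))
  m <- ncol(H)
  tab <- data.frame(subject_id = ids, H, joint = rowSums(H),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(tab)[1 + seq_len(m)] <- paste0("tfncp_", seq_len(m))
  if (!is.null(covariates)) {
    missing_ids <- setdiff(tab$subject_id, covariates$subject_id)
    if (length(missing_ids))
      stop("subjects missing from covariates: ",
           paste(missing_ids, collapse = ", "))
    tab <- merge(tab, covariates, by = "subject_id", sort = FALSE)
  }
  tab
}
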