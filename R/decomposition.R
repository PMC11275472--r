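#' PCA whitening of the concatenated trajectory record
#'
#' Centers the `l x K` group record (rows = connectivity pairs, columns =
#' window samples) and projects it onto the top `m` principal axes,
#' scaling each to unit variance, so the whitened rows have identity
#' covariance. ICA then only has to find an `m x m` rotation.
#'
#' @param X `l x K` numeric matrix.
#' @param m Number of components to retain; must not exceed the numerical
#'   rank of the centered data.
#' @return List with `model` (class `pca_model`: `mean`, `basis` `l x m`,
#'   `whitener` `m x l`, `eigenvalues`, `explained_variance`) and
#'   `whitened` (`m x K`).
#' @export
pca_whiten <- function(X, m) {
  X <- as.matrix(X)
  l <- nrow(X); K <- ncol(X)
  stopifnot(m >= 1, m <= min(l, K), K > m)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / (K - 1)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  if (m > rank)
    stop(sprintf("m = %d exceeds numerical rank %d of the data", m, rank))
  U <- eg$vectors[, seq_len(m), drop = FALSE]
  lam <- ev[seq_len(m)]
  whitener <- sweep(t(U), 1, sqrt(lam), "/")
  model <- structure(
    list(mean = mu, basis = U, whitener = whitener, eigenvalues = lam,
         explained_variance = lam / sum(ev)),
    class = "pca_model")
  list(model = model, whitened = whitener %*% Xc)
}

# Symmetric decorrelation: project W onto the nearest matrix with
# orthonormal rows, W <- (W W^T)^{-1/2} W. On whitened data this makes the
# estimated sources exactly decorrelated with exactly unit variance.
sym_decorrelate <- function(W) {
  M <- tcrossprod(W)
  eg <- eigen(M, symmetric = TRUE)
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values)) %*% W
}

#' InfoMax ICA by natural-gradient ascent
#'
#' Square ICA on whitened data with the logistic score
#' `g(u) = 1 - 2/(1 + exp(-u))` (suited to super-Gaussian sources) and the
#' natural-gradient mini-batch update `W <- W + lrate (I + g(u) u^T) W`.
#' The learning rate anneals by 0.9 whenever the angle between successive
#' weight updates exceeds 60 degrees; on divergence the run restarts with
#' a halved rate (at most 5 times). After convergence the unmixing matrix
#' is symmetrically decorrelated so the sources come out exactly unit
#' variance and mutually uncorrelated, and each source's sign and scale
#' are fixed downstream when patterns are formed.
#'
#' @param Xw `m x K` whitened matrix.
#' @param seed Seed for the weight initialization and batch shuffling.
#' @param lrate Initial learning rate for the batch-averaged natural
#'   gradient; default `1e-2 / log(m)`.
#' @param max_iter Maximum full passes over the data.
#' @param tol Convergence threshold on the Frobenius norm of the weight
#'   change per pass.
#' @param batch_size Mini-batch size.
#' @return List with `unmixing` (`m x m`, orthonormal rows), `sources`
#'   (`m x K`, unit variance), `iterations`, `converged`.
#' @export
infomax_ica <- function(Xw, seed = 1L, lrate = NULL, max_iter = 512L,
                        tol = 1e-6, batch_size = 256L) {
  Xw <- as.matrix(Xw)
  m <- nrow(Xw); K <- ncol(Xw)
  stopifnot(m >= 2, max_iter >= 1, K > m)
  if (is.null(lrate)) lrate <- 1e-2 / log(m)
  batch_size <- min(batch_size, K)
  Im <- diag(m)

  run_once <- function(lr0, attempt) {
    with_seed(seed + 7919L * attempt, {
      W <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
      lr <- lr0
      prev_delta <- NULL
      iters <- 0L
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        iters <- it
        perm <- sample.int(K)
        W_old <- W
        for (s in seq(1L, K, by = batch_size)) {
          idx <- perm[s:min(K, s + batch_size - 1L)]
          U <- W %*% Xw[, idx, drop = FALSE]
          G <- 1 - 2 / (1 + exp(-U))
          W <- W + lr * (Im + tcrossprod(G, U) / length(idx)) %*% W
          if (!all(is.finite(W)) || max(abs(W)) > 1e9) return(NULL)
        }
        delta <- W - W_old
        change <- sqrt(sum(delta^2))
        if (!is.null(prev_delta)) {
          denom <- sqrt(sum(delta^2)) * sqrt(sum(prev_delta^2))
          if (denom > 0) {
            cosang <- sum(delta * prev_delta) / denom
            if (cosang < cos(60 * pi / 180)) lr <- lr * 0.9
          }
        }
        prev_delta <- delta
        if (change < tol) { converged <- TRUE; break }
      }
      list(W = W, iterations = iters, converged = converged)
    })
  }

  res <- NULL
  lr0 <- lrate
  for (attempt in 0:5) {
    res <- run_once(lr0, attempt)
    if (!is.null(res)) break
    lr0 <- lr0 / 2
  }
  if (is.null(res))
    stop("InfoMax diverged after 5 learning-rate restarts")
  W <- sym_decorrelate(res$W)
  S <- W %*% Xw
  # whitened rows have exact unit sample variance; so do the rotated rows,
  # up to round-off -- normalize the residual away
  sds <- sqrt(rowSums((S - rowMeans(S))^2) / (K - 1))
  W <- W / sds
  S <- S / sds
  list(unmixing = W, sources = S, iterations = res$iterations,
       converged = res$converged)
}

#' ICASSO-style consolidation of repeated ICA runs
#'
#' Pools the components of `R` ICA runs on identical whitened data,
#' measures pairwise similarity as the absolute correlation of source
#' time courses, clusters them into `m` groups by average-linkage
#' agglomeration, and returns each cluster's centrotype (the member with
#' the largest within-cluster similarity sum). The stability index of a
#' cluster is its mean within-cluster similarity minus its mean similarity
#' to components outside the cluster; compact, well-separated clusters
#' score near 1.
#'
#' @param runs List of [infomax_ica()] results (length >= 2).
#' @param m Number of components.
#' @return List with `sources` (`m x K` centrotype sources), `unmixing`
#'   (`m x m` centrotype rows), `stability` (length `m`), `cluster_sizes`.
#' @export
icasso_consolidate <- function(runs, m) {
  stopifnot(length(runs) >= 2)
  R <- length(runs)
  stack <- do.call(rbind, lapply(runs, `[[`, "sources"))
  stopifnot(nrow(stack) == R * m)
  sim <- abs(stats::cor(t(stack)))
  diag(sim) <- 1
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = m)
  cent <- integer(m); stab <- numeric(m); csize <- integer(m)
  for (c in seq_len(m)) {
    members <- which(cl == c)
    csize[c] <- length(members)
    within <- sim[members, members, drop = FALSE]
    if (length(members) > 1) {
      w_mean <- mean(within[upper.tri(within)])
    } else w_mean <- 1
    outside <- sim[members, -members, drop = FALSE]
    b_mean <- if (ncol(outside) > 0) mean(outside) else 0
    stab[c] <- w_mean - b_mean
    cent[c] <- members[which.max(rowSums(sim[members, members, drop = FALSE]))]
  }
  run_of <- (cent - 1L) %/% m + 1L
  comp_of <- (cent - 1L) %% m + 1L
  W <- do.call(rbind, lapply(seq_len(m), function(c)
    runs[[run_of[c]]]$unmixing[comp_of[c], , drop = FALSE]))
  S <- stack[cent, , drop = FALSE]
  cc <- abs(stats::cor(t(S)))
  diag(cc) <- 0
  if (any(cc > 0.95))
    warning("cluster collapse: two centrotypes have |correlation| > 0.95")
  list(sources = S, unmixing = W, stability = stab, cluster_sizes = csize)
}

#' Decompose a concatenated trajectory record into temporally independent
#' FNC profiles
#'
#' The full decomposition stage: PCA-whitens the `l x K` group record to
#' `m` dimensions, runs InfoMax ICA `R` times from different seeded
#' initializations, consolidates the runs ICASSO-style, maps the
#' consolidated unmixing back to connectivity space to obtain the `m`
#' pattern loadings (tFNCPs), applies the sign convention (each pattern's
#' largest-magnitude entry made positive), and orders components by
#' decreasing pattern norm (variance explained). Group-level source time
#' courses have exactly unit variance; subject-level variance is left
#' unnormalized and carries the between-subject signal.
#'
#' @param X `l x K` concatenated record (e.g. `concatenate_subjects()$X`).
#' @param m Model order.
#' @param R Number of ICA runs to consolidate (>= 2).
#' @param seed Master seed; run `i` uses `seed + i`.
#' @param ... Passed to [infomax_ica()].
#' @return Object of class `decomposition_result`: `patterns` (`m x l`),
#'   `unmixing` (`m x m` on whitened space), `sources` (`m x K`),
#'   `stability`, `pca` (the [pca_whiten()] model), `source_order`.
#' @export
ica_decompose <- function(X, m, R = 150L, seed = 1L, ...) {
  stopifnot(R >= 2)
  pw <- pca_whiten(X, m)
  runs <- lapply(seq_len(R), function(i)
    infomax_ica(pw$whitened, seed = seed + i, ...))
  cons <- icasso_consolidate(runs, m)
  # mixing in whitened space is the transpose of the (orthonormal-row)
  # unmixing; map through the PCA basis to connectivity space
  A_w <- t(cons$unmixing)
  A <- pw$model$basis %*% (A_w * sqrt(pw$model$eigenvalues))
  patterns <- t(A)                       # m x l loadings
  S <- cons$sources
  # sign convention: largest-|entry| of each pattern positive
  for (j in seq_len(m)) {
    s <- sign(patterns[j, which.max(abs(patterns[j, ]))])
    if (s < 0) { patterns[j, ] <- -patterns[j, ]; S[j, ] <- -S[j, ] }
  }
  ord <- order(rowSums(patterns^2), decreasing = TRUE)
  structure(
    list(patterns = patterns[ord, , drop = FALSE],
         unmixing = cons$unmixing[ord, , drop = FALSE],
         sources = S[ord, , drop = FALSE],
         stability = cons$stability[ord],
         cluster_sizes = cons$cluster_sizes[ord],
         pca = pw$model, m = m, R = R, seed = seed,
         source_order = "pattern-norm-desc"),
    class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> m = %d (R = %d runs); stability: %s\n",
              x$m, x$R, paste(sprintf("%.3f", x$stability), collapse = ", ")))
  invisible(x)
}

#' Split group-level sources into per-subject blocks
#'
#' Extracts each subject's contiguous block of source time courses from
#' the concatenated `m x K` source matrix, without re-scaling: group-level
#' unit variance is preserved and subject-level variance carries the
#' between-subject signal.
#'
#' @param sources `m x K` source matrix.
#' @param index_map Data frame with `subject_id`, `start`, `end` columns
#'   (from [concatenate_subjects()]).
#' @return Named list of `m x T` matrices, one per subject.
#' @export
split_subject_sources <- function(sources, index_map) {
  sources <- as.matrix(sources)
  if (max(index_map$end) != ncol(sources) || min(index_map$start) != 1)
    stop("index map does not cover the source columns")
  out <- lapply(seq_len(nrow(index_map)), function(i)
    sources[, index_map$start[i]:index_map$end[i], drop = FALSE])
  names(out) <- index_map$subject_id
  out
}

#' Reshape pattern loadings to connectivity-matrix form
#'
#' Devectorizes each `l`-vector pattern into an `N x N` symmetric matrix
#' with zero diagonal (patterns are loadings in connectivity space, not
#' correlation matrices).
#'
#' @param patterns `m x l` matrix of pattern loadings.
#' @param n Number of networks.
#' @return List of `m` symmetric `n x n` matrices.
#' @export
reshape_patterns <- function(patterns, n) {
  patterns <- as.matrix(patterns)
  lapply(seq_len(nrow(patterns)), function(j)
    devectorize(patterns[j, ], n, diag_value = 0))
}

#' Scan candidate model orders
#'
#' Runs a reduced ICASSO consolidation at each candidate order and
#' summarizes cluster stability; when an entropy/covariate pathway is
#' supplied (via `index_map` and `covariates`), also counts the
#' FDR-significant group differences at each order.
#'
#' @param X `l x K` concatenated record.
#' @param orders Integer vector of candidate orders (distinct, within
#'   2..20).
#' @param R Runs per order (default 10).
#' @param seed Master seed.
#' @param index_map,covariates Optional; enable the group-difference
#'   count via [entropy_table()] and [build_report()].
#' @param k Entropy estimator neighbor order.
#' @param ... Passed to [infomax_ica()].
#' @return Data frame with one row per order: `order`, `mean_stability`,
#'   `min_stability`, and `n_significant` (NA without covariates).
#' @export
model_order_scan <- function(X, orders, R = 10L, seed = 1L,
                             index_map = NULL, covariates = NULL, k = 3,
                             ...) {
  orders <- as.integer(orders)
  stopifnot(!anyDuplicated(orders), all(orders >= 2), all(orders <= 20))
  rows <- lapply(orders, function(m) {
    dec <- ica_decompose(X, m = m, R = R, seed = seed, ...)
    nsig <- NA_integer_
    if (!is.null(index_map) && !is.null(covariates)) {
      subs <- split_subject_sources(dec$sources, index_map)
      tab <- entropy_table(subs, covariates, k = k)
      rep_ <- build_report(tab, covariates)
      nsig <- sum(rep_$flagged, na.rm = TRUE)
    }
    data.frame(order = m, mean_stability = mean(dec$stability),
               min_stability = min(dec$stability), n_significant = nsig)
  })
  do.call(rbind, rows)
}
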