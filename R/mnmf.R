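## Symmetric nonnegative matrix tri-factorization of the consensus matrix:
## CM ~ N L N', N >= 0 (n x k), L >= 0 (k x k), fitted by multiplicative
## updates from seeded restarts. The orthogonality constraint N'N = I is
## treated as soft — encouraged by the update's denominator structure and
## reported as the diagnostic ||N'N - I||_F — because enforcing a projection
## would change the update rules.

#' MNMF configuration
#'
#' @param k consensus cluster count (>= 2).
#' @param max_iter iteration cap per restart.
#' @param tol relative-objective convergence tolerance: a restart stops when
#'   an iteration fails to decrease `||CM - N L N'||^2` by at least
#'   `tol` relative (such an iteration is rejected, which also guarantees a
#'   non-increasing objective trace).
#' @param eps small positive stabiliser added to update denominators.
#' @param seed integer; restart r uses `seed + r - 1`.
#' @param n_restarts seeded restarts; the restart with the lowest final
#'   objective wins. The default of 100 follows the repeated-run protocol
#'   used to tame clustering variance.
#' @return a list of class `psafl_mnmf_config`.
#' @export
mnmfConfig <- function(k = 3L, max_iter = 500L, tol = 1e-6, eps = 1e-10,
                       seed = 1L, n_restarts = 100L) {
  if (k < 2L) stopConfig("k must be >= 2")
  if (max_iter < 1L) stopConfig("max_iter must be >= 1")
  if (tol <= 0) stopConfig("tol must be > 0")
  if (eps <= 0) stopConfig("eps must be > 0")
  if (n_restarts < 1L) stopConfig("n_restarts must be >= 1")
  structure(list(k = as.integer(k), max_iter = as.integer(max_iter),
                 tol = tol, eps = eps, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "psafl_mnmf_config")
}

#' Tri-factorization objective
#'
#' @param CM consensus matrix (numeric matrix or [ConsensusMatrix-class]).
#' @param N,L current factors.
#' @return `||CM - N L N'||_F^2`.
#' @export
mnmfObjective <- function(CM, N, L) {
  cm <- if (is(CM, "ConsensusMatrix")) CM@values else CM
  sum((cm - N %*% L %*% t(N))^2)
}

#' Initialize MNMF factors
#'
#' `N` starts from the indicator matrix of a seeded k-means partition of the
#' consensus-matrix rows plus a uniform 0.2 offset (strict positivity avoids
#' the zero-locking of multiplicative updates); `L` is the projected
#' interaction `N' CM N` normalised by the outer product of `N`'s column
#' sums.
#'
#' @param CM a [ConsensusMatrix-class] (or numeric matrix).
#' @param config a [mnmfConfig()]; `config$seed` drives the k-means start.
#' @return list with strictly positive matrices `N` (n x k) and `L` (k x k).
#' @export
initializeFactors <- function(CM, config) {
  cm <- if (is(CM, "ConsensusMatrix")) CM@values else CM
  k <- config$k
  n <- nrow(cm)
  if (k > n) stopConfig("k (%d) exceeds the number of points (%d)", k, n)
  withSeed(config$seed, {
    start <- tryCatch(
      suppressWarnings(kmeans(cm, centers = k, nstart = 10L))$cluster,
      error = function(e) {
        ## fewer distinct row patterns than k: seeded balanced assignment
        sample(rep_len(seq_len(k), n))
      })
    N <- matrix(0.2, n, k)
    N[cbind(seq_len(n), start)] <- 1.2
    cs <- colSums(N)
    L <- (t(N) %*% cm %*% N) / outer(cs, cs)
    list(N = N, L = L)
  })
}

#' One multiplicative update step
#'
#' Applies the assignment-factor update
#' `N <- N * (CM N L) / (N N' CM N L + eps)` followed by the interaction
#' update `L <- L * (N' CM N) / (N'N L N'N + eps)` using the updated `N`.
#' Nonnegativity is preserved (products and ratios of nonnegatives), and
#' exact factorizations with orthonormal `N` are fixed points (both update
#' ratios are 1 there). Note the plain ratio carries no descent guarantee;
#' [mnmfFit()] adds a monotonicity safeguard.
#'
#' @param CM consensus matrix (numeric or [ConsensusMatrix-class]).
#' @param N,L current nonnegative factors.
#' @param eps denominator stabiliser.
#' @return list with updated `N` and `L`.
#' @export
updateStep <- function(CM, N, L, eps = 1e-10) {
  cm <- if (is(CM, "ConsensusMatrix")) CM@values else CM
  CMN <- cm %*% N
  num_N <- CMN %*% L
  den_N <- N %*% (crossprod(N, CMN) %*% L) + eps
  N2 <- N * num_N / den_N
  if (any(!is.finite(N2))) stopNumeric("non-finite values in the N update")
  CMN2 <- cm %*% N2
  NtN <- crossprod(N2)
  num_L <- crossprod(N2, CMN2)
  den_L <- NtN %*% L %*% NtN + eps
  L2 <- L * num_L / den_L
  if (any(!is.finite(L2))) stopNumeric("non-finite values in the L update")
  list(N = N2, L = L2)
}

#' Fit the MNMF consensus factorization
#'
#' Runs `n_restarts` seeded restarts of the multiplicative updates and keeps
#' the restart with the lowest final objective. Within a restart, an
#' iteration that does not decrease the objective by at least `tol`
#' (relative) is rejected — the factors revert and the restart stops — so
#' the recorded objective trace is non-increasing. Hard labels are the
#' row-argmax of `N` (ties to the lowest cluster index); empty clusters are
#' repaired by reassigning the points with the weakest assignment margin.
#'
#' @param CM a [ConsensusMatrix-class] (or numeric symmetric nonnegative
#'   matrix).
#' @param features optional [FeatureMatrix-class] over the same subjects;
#'   when supplied, per-cluster feature means are returned as
#'   [ClusterCenters-class].
#' @param config a [mnmfConfig()].
#' @return list with `result` ([MNMFResult-class]) and `centers`
#'   ([ClusterCenters-class] or `NULL`).
#' @export
mnmfFit <- function(CM, features = NULL, config = mnmfConfig()) {
  cm <- if (is(CM, "ConsensusMatrix")) CM@values else CM
  n <- nrow(cm)
  if (!is.null(features) && nrow(featureValues(features)) != n) {
    stopInput("features (%d rows) do not match the consensus matrix (%d)",
              nrow(featureValues(features)), n)
  }
  restart_obj <- rep(NA_real_, config$n_restarts)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    fac <- initializeFactors(cm, cfg_r)
    N <- fac$N; L <- fac$L
    trace <- mnmfObjective(cm, N, L)
    converged <- FALSE
    diverged <- FALSE
    for (it in seq_len(config$max_iter)) {
      upd <- tryCatch(updateStep(cm, N, L, config$eps),
                      psafl_numeric_error = function(e) NULL)
      if (is.null(upd)) { diverged <- TRUE; break }
      o_prev <- trace[length(trace)]
      o_new <- mnmfObjective(cm, upd$N, upd$L)
      if (!is.finite(o_new)) { diverged <- TRUE; break }
      rel_drop <- (o_prev - o_new) / max(o_prev, .Machine$double.xmin)
      if (rel_drop < config$tol) {
        ## converged or failed to descend: accept only a true decrease
        if (o_new < o_prev) trace <- c(trace, o_new) else upd <- list(N = N, L = L)
        N <- upd$N; L <- upd$L
        converged <- TRUE
        break
      }
      N <- upd$N; L <- upd$L
      trace <- c(trace, o_new)
    }
    if (diverged) { restart_obj[r] <- Inf; next }
    restart_obj[r] <- trace[length(trace)]
    if (is.null(best) || restart_obj[r] < best$objective) {
      best <- list(N = N, L = L, trace = trace, converged = converged,
                   objective = restart_obj[r])
    }
  }
  if (is.null(best)) {
    stopNumeric("all %d restarts diverged to non-finite values",
                config$n_restarts)
  }
  labels <- max.col(best$N, ties.method = "first")
  labels <- repairEmptyClusters(labels, best$N, config$k)
  ntn_dev <- norm(crossprod(best$N) - diag(config$k), "F")
  result <- new("MNMFResult", N = best$N, L = best$L,
                objective_trace = best$trace,
                hard_labels = as.integer(labels),
                converged = best$converged,
                restart_objectives = restart_obj,
                ntn_deviation = ntn_dev)
  centers <- if (!is.null(features)) {
    computeCenters(features, labels, config$k)
  } else NULL
  list(result = result, centers = centers)
}

## Give every empty cluster the unassigned point with the weakest assignment
## margin (top minus second N entry); deterministic, lowest index on ties.
repairEmptyClusters <- function(labels, N, k) {
  moved <- logical(length(labels))
  for (c in seq_len(k)) {
    if (any(labels == c)) next
    margin <- apply(N, 1L, function(row) {
      s <- sort(row, decreasing = TRUE)
      s[1] - if (length(s) > 1L) s[2] else 0
    })
    margin[moved] <- Inf
    ## do not strip a cluster down to nothing
    counts <- tabulate(labels, nbins = k)
    margin[counts[labels] <= 1L] <- Inf
    pick <- which.min(margin)
    labels[pick] <- c
    moved[pick] <- TRUE
  }
  labels
}

#' Per-cluster feature means
#'
#' @param features a [FeatureMatrix-class].
#' @param labels integer hard labels in `1..k`.
#' @param k cluster count.
#' @return a [ClusterCenters-class]; row c is `colMeans` of the rows with
#'   label c.
#' @export
computeCenters <- function(features, labels, k) {
  x <- featureValues(features)
  counts <- tabulate(labels, nbins = k)
  if (any(counts == 0L)) stopEval("empty cluster(s): %s",
                                  paste(which(counts == 0L), collapse = ", "))
  centers <- matrix(0, k, ncol(x), dimnames = list(NULL, colnames(x)))
  for (c in seq_len(k)) {
    centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
  }
  new("ClusterCenters", centers = centers, counts = as.integer(counts))
}
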