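## The eight-method base clustering ensemble under one contract:
## runMethod(features, spec, k) -> BasePartition with labels in 1..k.
##
## Centroid/model methods (k-means, fuzzy c-means, SOM, GMM, hierarchical,
## spectral) take k directly. Density methods (DBSCAN, OPTICS) do not; their
## noise points are reassigned to the nearest non-noise centroid and, if more
## than k clusters emerge, centroids are merged hierarchically down to k.

#' The eight base clustering method names
#' @export
BASE_METHODS <- c("fuzzy-c-means", "k-means", "som", "gmm", "dbscan",
                  "hierarchical", "spectral", "optics")

#' Base clustering method specification
#'
#' @param name one of `"fuzzy-c-means"`, `"k-means"`, `"som"`, `"gmm"`,
#'   `"dbscan"`, `"hierarchical"`, `"spectral"`, `"optics"`.
#' @param params method-specific settings: `eps`/`minPts` for the density
#'   methods (defaults are data-driven, see [runMethod()]), `linkage` for
#'   hierarchical (default `"ward.D2"`), `modelNames` for the GMM (default:
#'   the diagonal-covariance family), `nstart` for k-means (default 10).
#' @param seed integer seed; the same spec run twice yields identical labels.
#' @return a list of class `psafl_method_spec`.
#' @export
methodSpec <- function(name, params = list(), seed = 1L) {
  if (!name %in% BASE_METHODS) {
    stopConfig("unknown method '%s'; expected one of: %s",
               name, paste(BASE_METHODS, collapse = ", "))
  }
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "psafl_method_spec")
}

## ---- density methods (hand-written: no DBSCAN/OPTICS dependency) ----

## Median distance to the (minPts-1)-th nearest neighbour: a deterministic
## data-driven radius when the caller supplies none.
epsHeuristic <- function(d, minPts) {
  kth <- pmin(minPts - 1L, ncol(d) - 1L)
  knn <- apply(d, 1L, function(row) sort(row)[kth + 1L])  # +1 skips self
  stats::median(knn)
}

## Classic DBSCAN on a precomputed distance matrix. Returns labels with 0 for
## noise.
dbscanLabels <- function(d, eps, minPts) {
  n <- nrow(d)
  labels <- integer(n)           # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    neigh <- which(d[i, ] <= eps)
    if (length(neigh) < minPts) next   # noise (may be claimed later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neigh, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        jn <- which(d[j, ] <= eps)
        if (length(jn) >= minPts) queue <- c(queue, setdiff(jn, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

## OPTICS reachability ordering (eps = Inf), clusters extracted by cutting
## the reachability profile at eps_cl (the extraction used with DBSCAN-style
## thresholds). Returns labels with 0 for noise.
opticsLabels <- function(d, minPts, eps_cl) {
  n <- nrow(d)
  core <- apply(d, 1L, function(row) sort(row)[minPts])  # core distance
  reach <- rep(Inf, n)
  processed <- logical(n)
  order_out <- integer(n)
  seeds <- rep(Inf, n)
  for (pos in seq_len(n)) {
    i <- if (pos == 1L) 1L else {
      cand <- which(!processed)
      cand[which.min(seeds[cand])]
    }
    processed[i] <- TRUE
    order_out[pos] <- i
    reach[i] <- if (pos == 1L) Inf else seeds[i]
    newreach <- pmax(core[i], d[i, ])
    upd <- !processed & newreach < seeds
    seeds[upd] <- newreach[upd]
  }
  labels <- integer(n)
  cl <- 0L
  for (pos in seq_len(n)) {
    i <- order_out[pos]
    if (reach[i] > eps_cl) {
      if (core[i] <= eps_cl) {
        cl <- cl + 1L
        labels[i] <- cl
      }                                 # else noise
    } else if (cl > 0L) {
      labels[i] <- cl
    }
  }
  labels
}

## Harmonise raw labels (0 = noise) to 1..k-compatible labels:
## noise -> nearest non-noise centroid; > k clusters -> Ward-merge centroids.
harmoniseLabels <- function(labels, x, k) {
  if (all(labels == 0L)) {
    return(list(labels = rep(1L, length(labels)), n_found = 1L))
  }
  n_found <- length(unique(labels[labels > 0L]))
  labels <- match(labels, sort(unique(labels[labels > 0L])))  # NA for noise
  centroids <- function() {
    cents <- matrix(0, n_found, ncol(x))
    for (c in seq_len(n_found)) {
      cents[c, ] <- colMeans(x[which(labels == c), , drop = FALSE])
    }
    cents
  }
  if (anyNA(labels)) {
    cents <- centroids()
    for (i in which(is.na(labels))) {
      d2 <- rowSums(sweep(cents, 2L, x[i, ])^2)
      labels[i] <- which.min(d2)
    }
  }
  if (n_found > k) {
    merge_map <- cutree(hclust(dist(centroids()), method = "ward.D2"), k)
    labels <- merge_map[labels]
  }
  list(labels = as.integer(labels), n_found = as.integer(n_found))
}

## ---- the uniform contract ----

#' Run one base clustering method
#'
#' Dispatches to the requested method and returns a harmonised partition.
#' Fuzzy c-means is hardened by maximal membership (ties to the lowest
#' index); the SOM is a 1 x k map whose units are the clusters; the GMM
#' defaults to the diagonal-covariance model family. Density methods use
#' `eps`/`minPts` from `spec$params` or a deterministic median-kNN-distance
#' heuristic, and may find a cluster count different from `k` (reported in
#' `n_clusters_found`); labels are always harmonised into `1..k`.
#'
#' @param features a [FeatureMatrix-class].
#' @param spec a [methodSpec()].
#' @param k requested cluster count (>= 2).
#' @return a [BasePartition-class].
#' @export
runMethod <- function(features, spec, k) {
  if (!inherits(spec, "psafl_method_spec")) {
    stopConfig("spec must be created by methodSpec()")
  }
  x <- featureValues(features)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2L) stopConfig("k must be >= 2")
  if (n < k) stopInput("need n >= k (n = %d, k = %d)", n, k)
  if (any(!is.finite(x))) stopData("features contain non-finite values")
  if (all(apply(x, 2L, sd) < 1e-12)) {
    stopData("degenerate features: zero variance in every column")
  }
  p <- spec$params
  res <- withSeed(spec$seed, {
    switch(spec$name,
      "k-means" = {
        if (n == k) {
          ## every point is its own cluster; Hartigan-Wong needs k < n
          list(labels = seq_len(n), n_found = k)
        } else {
          fit <- kmeans(x, centers = k, nstart = p$nstart %||% 10L,
                        iter.max = p$iter.max %||% 100L)
          list(labels = as.integer(fit$cluster), n_found = k)
        }
      },
      "fuzzy-c-means" = {
        fit <- e1071::cmeans(x, centers = k, iter.max = p$iter.max %||% 200L,
                             m = p$m %||% 2)
        list(labels = max.col(fit$membership, ties.method = "first"),
             n_found = k)
      },
      "som" = {
        grid <- class::somgrid(xdim = 1L, ydim = k, topo = "rectangular")
        init <- x[sample(n, k), , drop = FALSE]
        fit <- class::batchSOM(x, grid, radii = c(2, 1, 0.5, 0.1),
                               init = init)
        labels <- as.integer(class::knn1(fit$codes, x,
                                         factor(seq_len(k))))
        list(labels = labels, n_found = length(unique(labels)))
      },
      "gmm" = {
        mn <- p$modelNames %||% c("EII", "VII", "EEI", "VEI", "EVI", "VVI")
        fit <- mclust::Mclust(x, G = k, modelNames = mn, verbose = FALSE)
        if (is.null(fit)) stopData("GMM fit failed for k = %d", k)
        list(labels = as.integer(fit$classification), n_found = k)
      },
      "hierarchical" = {
        labels <- cutree(hclust(dist(x), method = p$linkage %||% "ward.D2"),
                         k)
        list(labels = as.integer(labels), n_found = k)
      },
      "spectral" = {
        ## deterministic RBF width from the median pairwise distance
        ## (kernlab's automatic sigma search is fragile on small n)
        sig <- p$sigma %||% {
          dd <- as.vector(dist(x))
          dd <- dd[dd > 0]
          if (!length(dd)) stopData("spectral clustering needs non-identical points")
          1 / (2 * stats::median(dd)^2)
        }
        fit <- kernlab::specc(x, centers = k, kernel = "rbfdot",
                              kpar = list(sigma = sig))
        list(labels = as.integer(fit@.Data), n_found = k)
      },
      "dbscan" = {
        d <- as.matrix(dist(x))
        minPts <- p$minPts %||% 5L
        eps <- p$eps %||% epsHeuristic(d, minPts)
        harmoniseLabels(dbscanLabels(d, eps, minPts), x, k)
      },
      "optics" = {
        d <- as.matrix(dist(x))
        minPts <- p$minPts %||% 5L
        eps_cl <- p$eps_cl %||% epsHeuristic(d, minPts)
        harmoniseLabels(opticsLabels(d, minPts, eps_cl), x, k)
      }
    )
  })
  new("BasePartition", method = unclass(spec),
      labels = res$labels, n_clusters_found = as.integer(res$n_found))
}

#' Connectivity matrix of one partition
#'
#' Binary n x n matrix with entry (i, j) = 1 exactly when subjects i and j
#' share a cluster; symmetric with unit diagonal.
#'
#' @param partition a [BasePartition-class] or integer label vector.
#' @return a binary numeric matrix.
#' @examples
#' connectivityMatrix(c(1, 1, 2))
#' @export
connectivityMatrix <- function(partition) {
  labels <- if (is(partition, "BasePartition")) partition@labels else
    as.integer(partition)
  outer(labels, labels, `==`) + 0
}

#' Consensus (co-association) matrix of a partition ensemble
#'
#' Element-wise mean of the per-partition connectivity matrices: entry
#' (i, j) is the fraction of partitions in which i and j co-cluster.
#'
#' @param partitions list of [BasePartition-class] (or label vectors).
#' @return a [ConsensusMatrix-class].
#' @export
consensusMatrix <- function(partitions) {
  if (!length(partitions)) stopInput("need >= 1 partition")
  conn <- lapply(partitions, connectivityMatrix)
  ns <- vapply(conn, nrow, 0L)
  if (length(unique(ns)) != 1L) {
    stopInput("partitions cover different numbers of points: %s",
              paste(unique(ns), collapse = ", "))
  }
  cm <- Reduce(`+`, conn) / length(conn)
  new("ConsensusMatrix", values = cm,
      n_partitions = as.integer(length(conn)))
}

#' Exhaustive search over base-method combinations
#'
#' Enumerates every non-empty subset of the method pool; for each subset it
#' runs the member methods, builds the consensus matrix, fits the MNMF
#' consensus and scores the result. The default `"stability"` objective is
#' the mean adjusted Rand index between the consensus labels and each member
#' partition; the `"reference"` objective is the permutation-invariant
#' agreement with supplied reference labels. Ties break to the smaller
#' subset, then lexicographically by method names.
#'
#' @param features a [FeatureMatrix-class].
#' @param method_pool character vector of method names (<= 8) or a list of
#'   [methodSpec()] objects.
#' @param k cluster count.
#' @param objective `"stability"` or `"reference"`.
#' @param reference reference labels (required for `objective =
#'   "reference"`).
#' @param mnmf_config a [mnmfConfig()] shared by all subsets.
#' @param method_seed seed given to every method spec built from a name.
#' @return list with `best` (character vector of method names), `best_score`,
#'   and `scores` (a data.frame over all subsets).
#' @export
exhaustiveSearch <- function(features, method_pool, k,
                             objective = c("stability", "reference"),
                             reference = NULL,
                             mnmf_config = mnmfConfig(k = k),
                             method_seed = 1L) {
  objective <- match.arg(objective)
  if (!length(method_pool)) stopConfig("method pool must not be empty")
  if (length(method_pool) > 8L) stopConfig("method pool is limited to 8 methods")
  if (objective == "reference" && is.null(reference)) {
    stopConfig("objective 'reference' requires reference labels")
  }
  specs <- if (is.character(method_pool)) {
    lapply(method_pool, methodSpec, seed = method_seed)
  } else method_pool
  names(specs) <- vapply(specs, function(s) s$name, "")
  ## each method runs once; subsets reuse the cached partitions
  parts <- lapply(specs, runMethod, features = features, k = k)
  m <- length(specs)
  subset_names <- character(2^m - 1L)
  subset_size <- integer(2^m - 1L)
  score <- numeric(2^m - 1L)
  for (mask in seq_len(2^m - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    sub <- parts[members]
    cm <- consensusMatrix(sub)
    fit <- mnmfFit(cm, features = NULL, config = mnmf_config)
    labs <- hardLabels(fit$result)
    score[mask] <- if (objective == "stability") {
      mean(vapply(sub, function(p) {
        mclust::adjustedRandIndex(labs, p@labels)
      }, 0))
    } else {
      bestPermutationAgreement(labs, reference)
    }
    subset_names[mask] <- paste(sort(names(specs)[members]), collapse = "+")
    subset_size[mask] <- length(members)
  }
  scores <- data.frame(subset = subset_names, size = subset_size,
                       score = score, stringsAsFactors = FALSE)
  ord <- order(-scores$score, scores$size, scores$subset)
  scores <- scores[ord, , drop = FALSE]
  rownames(scores) <- NULL
  list(best = strsplit(scores$subset[1], "+", fixed = TRUE)[[1]],
       best_score = scores$score[1], scores = scores)
}
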