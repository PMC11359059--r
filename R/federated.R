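## Client-server (horizontal) federation of the consensus pipeline.
##
## Subjects are partitioned across clients; every client runs the identical
## base ensemble + MNMF consensus locally and shares only a ClientSummary
## (centroids, per-cluster trunk displacement, ranks, labels, timing). The
## server aligns clusters across clients by severity rank — ascending mean
## trunk displacement, the only information the clients transmit that is
## comparable across sites — and FedAvg-averages the aligned centroids with
## client-size weights. One aggregation pass over final local centers; there
## is no iterative training loop.

defaultSeverityLabels <- function(k) {
  switch(as.character(k),
         "2" = c("mild", "severe"),
         "3" = c("mild", "moderate", "severe"),
         paste0("level", seq_len(k)))
}

#' Federation configuration
#'
#' @param n_clients number of clients M (>= 1).
#' @param k cluster / severity-level count.
#' @param partition_seed seed for the random subject-to-client assignment.
#' @param participating optional character vector of client ids taking part
#'   in aggregation (default: all).
#' @param severity_labels ordered severity categories, mildest first
#'   (defaults to mild/severe, mild/moderate/severe, or `level1..k`).
#' @param base_methods base ensemble method names shared by every client.
#' @param method_params named list of per-method `params` (see
#'   [methodSpec()]).
#' @param method_seed one seed shared by all clients and methods, so every
#'   client starts its ensemble from the same initialization parameters.
#' @param mnmf a [mnmfConfig()] shared by every client.
#' @return a list of class `psafl_federation_config`.
#' @export
federationConfig <- function(n_clients, k = 3L, partition_seed = 1L,
                             participating = NULL,
                             severity_labels = NULL,
                             base_methods = BASE_METHODS,
                             method_params = list(),
                             method_seed = 1L,
                             mnmf = mnmfConfig(k = k)) {
  if (n_clients < 1L) stopConfig("n_clients must be >= 1")
  if (k < 2L) stopConfig("k must be >= 2")
  if (mnmf$k != k) stopConfig("mnmf config k (%d) must match k (%d)", mnmf$k, k)
  severity_labels <- severity_labels %||% defaultSeverityLabels(k)
  if (length(severity_labels) != k) {
    stopConfig("severity_labels must have length k = %d", k)
  }
  bad <- setdiff(base_methods, BASE_METHODS)
  if (length(bad)) stopConfig("unknown base method(s): %s",
                              paste(bad, collapse = ", "))
  structure(list(n_clients = as.integer(n_clients), k = as.integer(k),
                 partition_seed = as.integer(partition_seed),
                 participating = participating,
                 severity_labels = as.character(severity_labels),
                 base_methods = base_methods,
                 method_params = method_params,
                 method_seed = as.integer(method_seed),
                 mnmf = mnmf),
            class = "psafl_federation_config")
}

#' Partition subjects across clients
#'
#' Seeded uniform random partition of subjects into `n_clients` disjoint,
#' exhaustive client datasets whose sizes differ by at most one. Within each
#' client, subject indices are kept sorted, so a single-client federation
#' sees subjects in exactly the centralized order.
#'
#' @param features a [FeatureMatrix-class] over all subjects.
#' @param td per-subject trunk-displacement data.frame from
#'   [subjectTrunkDisplacement()].
#' @param config a [federationConfig()].
#' @return list of client datasets, each a list with `client_id`, `features`
#'   ([FeatureMatrix-class] subset), `td` and `indices`.
#' @export
partitionClients <- function(features, td, config) {
  x <- featureValues(features)
  n <- nrow(x)
  M <- config$n_clients
  if (n < M * config$k) {
    stopConfig("n = %d subjects cannot give every one of %d clients >= k = %d",
               n, M, config$k)
  }
  if (!identical(rowIds(features), td$subject_id)) {
    stopInput("features and trunk summaries must cover identical subjects in order")
  }
  assign <- withSeed(config$partition_seed, {
    perm <- sample(n)
    sizes <- rep(n %/% M, M) + (seq_len(M) <= n %% M)
    rep(seq_len(M), times = sizes)[order(perm)]
  })
  lapply(seq_len(M), function(m) {
    idx <- sort(which(assign == m))
    list(client_id = sprintf("client%02d", m),
         features = features[idx, seq_len(ncol(x))],
         td = td[idx, , drop = FALSE],
         indices = idx)
  })
}

#' Run the full local pipeline on one client
#'
#' Base ensemble, consensus matrix, MNMF fit, per-cluster mean trunk
#' displacement and severity ranks (ascending displacement = milder). A pure
#' function of its inputs: two clients with identical data and configuration
#' produce identical summaries up to `client_id` and wall time.
#'
#' @param client one element of [partitionClients()] output.
#' @param config a [federationConfig()].
#' @return a [ClientSummary-class].
#' @export
runClient <- function(client, config) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch({
    specs <- lapply(config$base_methods, function(nm) {
      methodSpec(nm, params = config$method_params[[nm]] %||% list(),
                 seed = config$method_seed)
    })
    parts <- lapply(specs, runMethod, features = client$features,
                    k = config$k)
    cm <- consensusMatrix(parts)
    fit <- mnmfFit(cm, features = client$features, config = config$mnmf)
    labels <- hardLabels(fit$result)
    cluster_td <- vapply(seq_len(config$k), function(c) {
      mean(client$td$td[labels == c])
    }, 0)
    ## rank 1 = mildest; order() breaks TD ties toward the lower cluster index
    rank <- integer(config$k)
    rank[order(cluster_td)] <- seq_len(config$k)
    new("ClientSummary",
        client_id = client$client_id,
        n_points = as.integer(nrow(featureValues(client$features))),
        centers = clusterCenters(fit$centers),
        cluster_td = cluster_td,
        severity_rank = rank,
        local_labels = setNames(labels, rowIds(client$features)),
        comp_time_s = 0)
  }, psafl_error = function(e) {
    stopWith(class(e)[1], "[%s] %s", client$client_id, conditionMessage(e))
  })
  out@comp_time_s <- proc.time()[["elapsed"]] - t0
  out
}

#' FedAvg aggregation of client summaries
#'
#' Aligns clusters across clients by severity rank (rank r on every client
#' maps to global cluster r) and averages the aligned centroids with
#' client-size weights `n_client / N_total` over the participating clients.
#' Consumes only [ClientSummary-class] objects — no raw data.
#'
#' @param summaries list of [ClientSummary-class].
#' @param config a [federationConfig()].
#' @return a [GlobalModel-class]; rows of the global centers are ordered
#'   mildest to most severe.
#' @export
fedAvg <- function(summaries, config) {
  t0 <- proc.time()[["elapsed"]]
  if (!length(summaries)) stopInput("need >= 1 client summary")
  if (!is.null(config$participating)) {
    summaries <- Filter(function(s) s@client_id %in% config$participating,
                        summaries)
    if (!length(summaries)) stopConfig("no participating client summaries")
  }
  ## canonical order: aggregation is then invariant to the order in which
  ## client summaries arrive, exactly (fp summation order is fixed)
  summaries <- summaries[order(vapply(summaries, function(s) s@client_id, ""))]
  k <- unique(vapply(summaries, function(s) nrow(s@centers), 0L))
  d <- unique(vapply(summaries, function(s) ncol(s@centers), 0L))
  if (length(k) != 1L || length(d) != 1L) {
    stopInput("client summaries disagree on k or feature dimension")
  }
  if (k != config$k) stopInput("summaries carry k = %d, config has k = %d",
                               k, config$k)
  n_total <- sum(vapply(summaries, function(s) s@n_points, 0L))
  weights <- vapply(summaries, function(s) s@n_points / n_total, 0)
  names(weights) <- vapply(summaries, function(s) s@client_id, "")
  W <- matrix(0, k, d, dimnames = list(NULL, colnames(summaries[[1]]@centers)))
  for (r in seq_len(k)) {
    for (ci in seq_along(summaries)) {
      s <- summaries[[ci]]
      local_cluster <- which(s@severity_rank == r)
      W[r, ] <- W[r, ] + weights[ci] * s@centers[local_cluster, ]
    }
  }
  model <- new("GlobalModel", W = W,
               severity_label_per_cluster = config$severity_labels,
               weights_used = weights, comm_time_s = 0)
  model@comm_time_s <- proc.time()[["elapsed"]] - t0
  model
}

#' Label subjects with the global model
#'
#' Assigns every subject to the nearest global center (Euclidean); ties go
#' to the milder cluster.
#'
#' @param features a [FeatureMatrix-class].
#' @param model a [GlobalModel-class].
#' @return data.frame with `subject_id`, `cluster` (1 = mildest) and
#'   `severity` (factor, levels mildest first).
#' @export
assignGlobal <- function(features, model) {
  x <- featureValues(features)
  W <- model@W
  if (ncol(x) != ncol(W)) {
    stopInput("feature dimension (%d) does not match the model (%d)",
              ncol(x), ncol(W))
  }
  d2 <- vapply(seq_len(nrow(W)), function(r) {
    rowSums(sweep(x, 2L, W[r, ])^2)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) d2 <- matrix(d2, nrow = 1L)
  cluster <- apply(d2, 1L, which.min)  # first minimum = milder cluster
  data.frame(
    subject_id = rownames(x),
    cluster = as.integer(cluster),
    severity = factor(model@severity_label_per_cluster[cluster],
                      levels = model@severity_label_per_cluster),
    stringsAsFactors = FALSE)
}

#' Run the federated pipeline end to end
#'
#' Partition, per-client local pipelines, FedAvg aggregation, global
#' labeling, and timing bookkeeping (CompT = maximum client time, CmT =
#' aggregation time).
#'
#' @param features a [FeatureMatrix-class] over all subjects.
#' @param td per-subject trunk displacement ([subjectTrunkDisplacement()]).
#' @param config a [federationConfig()].
#' @return list with `model` ([GlobalModel-class]), `assignments`
#'   (data.frame from [assignGlobal()]), `summaries` and `timing`
#'   ([TimingReport-class]).
#' @export
runFederated <- function(features, td, config) {
  clients <- partitionClients(features, td, config)
  summaries <- lapply(clients, runClient, config = config)
  model <- fedAvg(summaries, config)
  assignments <- assignGlobal(features, model)
  list(model = model, assignments = assignments, summaries = summaries,
       timing = timingReport(summaries, model@comm_time_s))
}

#' Run the centralized pipeline
#'
#' The degenerate one-client pipeline: the full local pipeline over all
#' subjects, global centers taken directly from the local centroids ordered
#' by severity rank, and labeling by nearest center. A federation with
#' `n_clients = 1` and the same seeds reproduces its centers and labels
#' bit for bit.
#'
#' @param features a [FeatureMatrix-class] over all subjects.
#' @param td per-subject trunk displacement ([subjectTrunkDisplacement()]).
#' @param config a [federationConfig()]; `n_clients` is ignored.
#' @return same shape as [runFederated()].
#' @export
runCentralized <- function(features, td, config) {
  client <- list(client_id = "central", features = features, td = td,
                 indices = seq_len(nrow(featureValues(features))))
  summary <- runClient(client, config)
  k <- config$k
  W <- matrix(0, k, ncol(summary@centers),
              dimnames = list(NULL, colnames(summary@centers)))
  for (r in seq_len(k)) {
    W[r, ] <- 1 * summary@centers[which(summary@severity_rank == r), ]
  }
  model <- new("GlobalModel", W = W,
               severity_label_per_cluster = config$severity_labels,
               weights_used = c(central = 1), comm_time_s = 0)
  assignments <- assignGlobal(features, model)
  list(model = model, assignments = assignments, summaries = list(summary),
       timing = timingReport(list(summary), 0))
}
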