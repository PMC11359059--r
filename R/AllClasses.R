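## Central S4 containers. Configuration objects are validated plain lists
## (see cohortConfig(), filterSpec(), methodSpec(), mnmfConfig(),
## federationConfig()); the classes below hold data flowing between stages.

#' MotionTrial: one subject/task/repetition position recording
#'
#' Time-indexed 3D positions for a set of body channels, sampled at a single
#' rate. Columns of `positions` are named `<channel>_<axis>` with axes
#' `x`, `y`, `z`.
#'
#' @slot subject_id character scalar.
#' @slot group severity category the subject was generated from (or `NA`).
#' @slot task_id character scalar.
#' @slot repetition integer repetition index.
#' @slot sampling_rate_hz samples per second.
#' @slot positions numeric matrix, time by (channel x axis), length units.
#' @slot channel_names character vector of channel identifiers.
#' @slot fma_score optional numeric Fugl-Meyer (FMA-UE) reference score;
#'   `NA_real_` when absent. Reference only, never used by the pipeline.
#' @export
setClass("MotionTrial",
  representation(
    subject_id = "character",
    group = "character",
    task_id = "character",
    repetition = "integer",
    sampling_rate_hz = "numeric",
    positions = "matrix",
    channel_names = "character",
    fma_score = "numeric"
  )
)

setValidity("MotionTrial", function(object) {
  p <- object@positions
  if (nrow(p) < 11L) {
    return("positions must have >= 11 time samples (baseline window 10 + 1)")
  }
  if (ncol(p) != 3L * length(object@channel_names)) {
    return("positions must have 3 columns (x, y, z) per channel")
  }
  if (any(!is.finite(p))) return("positions contain non-finite values")
  if (object@sampling_rate_hz <= 0) return("sampling_rate_hz must be > 0")
  TRUE
})

#' MotionCohort: a set of trials with subject metadata
#'
#' @slot trials list of [MotionTrial-class] objects, ordered by subject,
#'   task, repetition.
#' @slot subjects data.frame with columns `subject_id`, `group`, `fma`.
#' @slot group_names ordered severity categories, mildest first.
#' @slot trunk_channel name of the trunk channel used for displacement.
#' @slot config the generating [cohortConfig()] list (empty for imported data).
#' @export
setClass("MotionCohort",
  representation(
    trials = "list",
    subjects = "data.frame",
    group_names = "character",
    trunk_channel = "character",
    config = "list"
  )
)

setValidity("MotionCohort", function(object) {
  if (!all(c("subject_id", "group", "fma") %in% names(object@subjects))) {
    return("subjects must have columns subject_id, group, fma")
  }
  if (anyDuplicated(object@subjects$subject_id)) {
    return("duplicate subject_id in subjects table")
  }
  TRUE
})

#' FeatureMatrix: subjects by frequency-domain features
#'
#' Rows are subjects in canonical (sorted) order; columns are
#' channel-axis-frequency-bin descriptors. Values are z-scored magnitude
#' spectra of (filtered) position or derived acceleration series.
#'
#' @slot values numeric matrix with rownames (subject ids) and colnames
#'   (feature names).
#' @slot feature_kind `"position-spectrum"` or `"acceleration-spectrum"`.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", feature_kind = "character")
)

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("feature values contain non-finite entries")
  if (is.null(rownames(v))) return("values must carry subject ids as rownames")
  if (is.null(colnames(v))) return("values must carry feature names as colnames")
  if (is.unsorted(rownames(v))) return("rows must be sorted by subject id")
  if (!object@feature_kind %in% c("position-spectrum", "acceleration-spectrum")) {
    return("feature_kind must be position-spectrum or acceleration-spectrum")
  }
  TRUE
})

#' BasePartition: one base clustering result
#'
#' @slot method the [methodSpec()] list that produced the partition.
#' @slot labels integer labels in `1..k` (noise already reassigned).
#' @slot n_clusters_found number of clusters the method actually found
#'   before harmonisation (density methods may differ from the requested k).
#' @export
setClass("BasePartition",
  representation(method = "list", labels = "integer",
                 n_clusters_found = "integer")
)

setValidity("BasePartition", function(object) {
  if (any(object@labels < 1L)) return("labels must be positive integers")
  TRUE
})

#' ConsensusMatrix: co-association matrix of a partition ensemble
#'
#' Entry (i, j) is the fraction of ensemble partitions in which subjects i
#' and j share a cluster.
#'
#' @slot values symmetric numeric matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @slot n_partitions number of partitions averaged.
#' @export
setClass("ConsensusMatrix",
  representation(values = "matrix", n_partitions = "integer")
)

setValidity("ConsensusMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("consensus matrix must be square")
  if (max(abs(v - t(v))) > 1e-12) return("consensus matrix must be symmetric")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12) {
    return("consensus entries must lie in [0, 1]")
  }
  if (max(abs(diag(v) - 1)) > 1e-12) return("diagonal must be 1")
  if (object@n_partitions < 1L) return("n_partitions must be >= 1")
  TRUE
})

#' MNMFResult: symmetric tri-factorization of a consensus matrix
#'
#' Best-of-restarts factorization `CM ~ N L N'` with nonnegative factors,
#' obtained by multiplicative updates with a monotonicity safeguard.
#'
#' @slot N n x k nonnegative cluster-assignment factor.
#' @slot L k x k nonnegative interaction (consensus-centroid) factor.
#' @slot objective_trace per-iteration `||CM - N L N'||^2` of the winning
#'   restart (non-increasing).
#' @slot hard_labels integer labels in `1..k`, the row-argmax of `N`
#'   (ties to the lowest index), after empty-cluster repair.
#' @slot converged logical: did the winning restart stop before the
#'   iteration cap.
#' @slot restart_objectives final objective of every restart.
#' @slot ntn_deviation diagnostic `||N'N - I||_F` of the winning restart
#'   (the orthogonality constraint is encouraged, not enforced).
#' @export
setClass("MNMFResult",
  representation(
    N = "matrix", L = "matrix",
    objective_trace = "numeric",
    hard_labels = "integer",
    converged = "logical",
    restart_objectives = "numeric",
    ntn_deviation = "numeric"
  )
)

setValidity("MNMFResult", function(object) {
  if (min(object@N) < 0 || min(object@L) < 0) {
    return("factors must be nonnegative")
  }
  tr <- object@objective_trace
  if (length(tr) > 1L) {
    rel <- diff(tr) / pmax(tr[-length(tr)], .Machine$double.xmin)
    if (max(rel) > 1e-9) return("objective trace must be non-increasing")
  }
  if (length(object@hard_labels) != nrow(object@N)) {
    return("hard_labels length must equal nrow(N)")
  }
  TRUE
})

#' ClusterCenters: per-cluster feature-space means
#'
#' @slot centers k x d matrix; row c is the mean feature vector of the
#'   subjects with hard label c.
#' @slot counts integer subjects per cluster, summing to n.
#' @export
setClass("ClusterCenters",
  representation(centers = "matrix", counts = "integer")
)

#' ClientSummary: everything a client shares with the server
#'
#' Deliberately excludes raw features and trials: the federation contract is
#' that only centroids, per-cluster trunk-displacement summaries, label
#' vectors and timings leave a client.
#'
#' @slot client_id character scalar.
#' @slot n_points number of subjects held by the client.
#' @slot centers k x d local cluster centers.
#' @slot cluster_td mean trunk displacement per local cluster.
#' @slot severity_rank per-cluster severity rank, 1 = mildest, a permutation
#'   of `1..k` ordered by ascending `cluster_td`.
#' @slot local_labels named integer vector of local hard labels per subject.
#' @slot comp_time_s local wall-clock computation time (seconds).
#' @export
setClass("ClientSummary",
  representation(
    client_id = "character", n_points = "integer",
    centers = "matrix", cluster_td = "numeric",
    severity_rank = "integer", local_labels = "integer",
    comp_time_s = "numeric"
  )
)

setValidity("ClientSummary", function(object) {
  k <- nrow(object@centers)
  if (!identical(sort(object@severity_rank), seq_len(k))) {
    return("severity_rank must be a permutation of 1..k")
  }
  if (length(object@cluster_td) != k) {
    return("cluster_td must have one entry per cluster")
  }
  TRUE
})

#' GlobalModel: FedAvg-aggregated global cluster model
#'
#' @slot W k x d global centers, rows ordered mildest to most severe.
#' @slot severity_label_per_cluster ordered severity categories, one per row
#'   of `W`, mildest first.
#' @slot weights_used per-client aggregation weights (client size fractions),
#'   summing to 1 over participating clients.
#' @slot comm_time_s server-side aggregation (communication) time, seconds.
#' @export
setClass("GlobalModel",
  representation(
    W = "matrix",
    severity_label_per_cluster = "character",
    weights_used = "numeric",
    comm_time_s = "numeric"
  )
)

setValidity("GlobalModel", function(object) {
  if (nrow(object@W) != length(object@severity_label_per_cluster)) {
    return("one severity label per row of W is required")
  }
  if (abs(sum(object@weights_used) - 1) > 1e-9) {
    return("aggregation weights must sum to 1")
  }
  TRUE
})

#' EvalReport: classification metrics against a reference labeling
#'
#' @slot accuracy,precision,recall,f_score support-weighted proportions in
#'   `[0, 1]`.
#' @slot confusion count matrix, rows = reference, columns = predicted.
#' @slot per_class data.frame of per-category precision/recall/F/support.
#' @slot n subjects evaluated.
#' @export
setClass("EvalReport",
  representation(
    accuracy = "numeric", precision = "numeric",
    recall = "numeric", f_score = "numeric",
    confusion = "matrix", per_class = "data.frame", n = "integer"
  )
)

setValidity("EvalReport", function(object) {
  if (sum(object@confusion) != object@n) {
    return("confusion entries must sum to n")
  }
  m <- c(object@accuracy, object@precision, object@recall, object@f_score)
  if (any(m < 0 | m > 1)) return("metrics must lie in [0, 1]")
  TRUE
})

#' TimingReport: computation/communication time decomposition
#'
#' @slot comp_time_s maximum per-client local computation time (CompT).
#' @slot comm_time_s server aggregation time (CmT).
#' @slot total_s `comp_time_s + comm_time_s`, exactly.
#' @export
setClass("TimingReport",
  representation(comp_time_s = "numeric", comm_time_s = "numeric",
                 total_s = "numeric")
)

setValidity("TimingReport", function(object) {
  if (object@comp_time_s < 0 || object@comm_time_s < 0) {
    return("times must be nonnegative")
  }
  if (!identical(object@total_s, object@comp_time_s + object@comm_time_s)) {
    return("total_s must equal comp_time_s + comm_time_s exactly")
  }
  TRUE
})
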