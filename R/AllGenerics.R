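#' @name psafl-accessors
#' @title Accessors for psafl containers
#' @description Slot accessors for the package's S4 classes. Use these rather
#'   than `@` access; slot layout is internal.
#' @param x a psafl S4 object.
#' @param object a psafl S4 object.
#' @param i,j,drop row/column subsetting arguments.
#' @param ... unused.
NULL

#' @rdname psafl-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname psafl-accessors
#' @export
setGeneric("rowIds", function(x) standardGeneric("rowIds"))
#' @rdname psafl-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname psafl-accessors
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))
#' @rdname psafl-accessors
#' @export
setGeneric("cmValues", function(x) standardGeneric("cmValues"))
#' @rdname psafl-accessors
#' @export
setGeneric("nPartitions", function(x) standardGeneric("nPartitions"))
#' @rdname psafl-accessors
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))
#' @rdname psafl-accessors
#' @export
setGeneric("hardLabels", function(x) standardGeneric("hardLabels"))
#' @rdname psafl-accessors
#' @export
setGeneric("factorN", function(x) standardGeneric("factorN"))
#' @rdname psafl-accessors
#' @export
setGeneric("factorL", function(x) standardGeneric("factorL"))
#' @rdname psafl-accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname psafl-accessors
#' @export
setGeneric("restartObjectives", function(x) standardGeneric("restartObjectives"))
#' @rdname psafl-accessors
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname psafl-accessors
#' @export
setGeneric("clusterCounts", function(x) standardGeneric("clusterCounts"))
#' @rdname psafl-accessors
#' @export
setGeneric("globalCenters", function(x) standardGeneric("globalCenters"))
#' @rdname psafl-accessors
#' @export
setGeneric("severityLabels", function(x) standardGeneric("severityLabels"))
#' @rdname psafl-accessors
#' @export
setGeneric("cohortTrials", function(x) standardGeneric("cohortTrials"))
#' @rdname psafl-accessors
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))

#' @rdname psafl-accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname psafl-accessors
#' @export
setMethod("rowIds", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname psafl-accessors
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) colnames(x@values))
#' @rdname psafl-accessors
#' @export
setMethod("featureKind", "FeatureMatrix", function(x) x@feature_kind)

#' @rdname psafl-accessors
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, j, drop = FALSE]
  new("FeatureMatrix", values = v, feature_kind = x@feature_kind)
})

#' @rdname psafl-accessors
#' @export
setMethod("cmValues", "ConsensusMatrix", function(x) x@values)
#' @rdname psafl-accessors
#' @export
setMethod("nPartitions", "ConsensusMatrix", function(x) x@n_partitions)
#' @rdname psafl-accessors
#' @export
setMethod("partitionLabels", "BasePartition", function(x) x@labels)
#' @rdname psafl-accessors
#' @export
setMethod("hardLabels", "MNMFResult", function(x) x@hard_labels)
#' @rdname psafl-accessors
#' @export
setMethod("factorN", "MNMFResult", function(x) x@N)
#' @rdname psafl-accessors
#' @export
setMethod("factorL", "MNMFResult", function(x) x@L)
#' @rdname psafl-accessors
#' @export
setMethod("objectiveTrace", "MNMFResult", function(x) x@objective_trace)
#' @rdname psafl-accessors
#' @export
setMethod("restartObjectives", "MNMFResult", function(x) x@restart_objectives)
#' @rdname psafl-accessors
#' @export
setMethod("clusterCenters", "ClusterCenters", function(x) x@centers)
#' @rdname psafl-accessors
#' @export
setMethod("clusterCounts", "ClusterCenters", function(x) x@counts)
#' @rdname psafl-accessors
#' @export
setMethod("globalCenters", "GlobalModel", function(x) x@W)
#' @rdname psafl-accessors
#' @export
setMethod("severityLabels", "GlobalModel", function(x) {
  x@severity_label_per_cluster
})
#' @rdname psafl-accessors
#' @export
setMethod("cohortTrials", "MotionCohort", function(x) x@trials)
#' @rdname psafl-accessors
#' @export
setMethod("cohortSubjects", "MotionCohort", function(x) x@subjects)

## ---- show methods ----

#' @rdname psafl-accessors
#' @export
setMethod("show", "MotionCohort", function(object) {
  s <- object@subjects
  cat(sprintf("MotionCohort: %d subjects, %d trials\n",
              nrow(s), length(object@trials)))
  cat("  groups (mildest first):",
      paste(sprintf("%s (%d)", object@group_names,
                    as.vector(table(factor(s$group,
                                           levels = object@group_names)))),
            collapse = ", "), "\n")
  cat("  trunk channel:", object@trunk_channel, "\n")
  if (any(!is.na(s$fma))) {
    cat(sprintf("  FMA-UE reference scores: %.1f-%.1f\n",
                min(s$fma, na.rm = TRUE), max(s$fma, na.rm = TRUE)))
  }
})

#' @rdname psafl-accessors
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d subjects x %d features (%s)\n",
              nrow(object@values), ncol(object@values), object@feature_kind))
  cat("  features:", paste(head(colnames(object@values), 3), collapse = ", "),
      if (ncol(object@values) > 3) "..." else "", "\n")
})

#' @rdname psafl-accessors
#' @export
setMethod("show", "ConsensusMatrix", function(object) {
  cat(sprintf("ConsensusMatrix: %d x %d, averaged over %d partitions\n",
              nrow(object@values), ncol(object@values), object@n_partitions))
})

#' @rdname psafl-accessors
#' @export
setMethod("show", "BasePartition", function(object) {
  cat(sprintf("BasePartition (%s): n = %d, %d cluster(s) found\n",
              object@method$name, length(object@labels),
              object@n_clusters_found))
})

#' @rdname psafl-accessors
#' @export
setMethod("show", "MNMFResult", function(object) {
  tr <- object@objective_trace
  cat(sprintf(
    "MNMFResult: n = %d, k = %d, objective %.6g after %d iteration(s)%s\n",
    nrow(object@N), ncol(object@N), tr[length(tr)], length(tr) - 1L,
    if (object@converged) " (converged)" else ""))
  cat(sprintf("  best of %d restart(s); ||N'N - I||_F = %.3g\n",
              length(object@restart_objectives), object@ntn_deviation))
})

#' @rdname psafl-accessors
#' @export
setMethod("show", "GlobalModel", function(object) {
  cat(sprintf("GlobalModel: %d clusters x %d features\n",
              nrow(object@W), ncol(object@W)))
  cat("  severity order (mildest first):",
      paste(object@severity_label_per_cluster, collapse = " < "), "\n")
  cat(sprintf("  aggregated from %d client(s), CmT = %.3g s\n",
              length(object@weights_used), object@comm_time_s))
})

#' @rdname psafl-accessors
#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport (n = %d): accuracy %.1f%%, precision %.1f%%, recall %.1f%%, F %.1f%%\n",
    object@n, 100 * object@accuracy, 100 * object@precision,
    100 * object@recall, 100 * object@f_score))
})

#' @rdname psafl-accessors
#' @export
setMethod("show", "TimingReport", function(object) {
  cat(sprintf("TimingReport: CompT %.3g s + CmT %.3g s = %.3g s\n",
              object@comp_time_s, object@comm_time_s, object@total_s))
})
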