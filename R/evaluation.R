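## Severity labeling against FMA-UE reference categories, classification
## metrics, and computation/communication time bookkeeping.

#' Map an FMA-UE score to a severity category
#'
#' The Fugl-Meyer upper-extremity score ranges 0-66; scores below 29 denote
#' severe impairment. With `k = 2` the single boundary (default 29)
#' separates severe from mild; with `k = 3` the moderate/mild boundary is an
#' additional configurable cut (default 43 — an assumption, since only the
#' 29-point boundary is clinically anchored). The boundaries are half-open:
#' a score exactly at a boundary falls into the milder category.
#'
#' @param score numeric FMA-UE score(s) in `[0, 66]`.
#' @param k 2 or 3 severity levels.
#' @param severe_boundary severe cut (scores strictly below are severe).
#' @param mild_boundary moderate/mild cut for `k = 3`.
#' @param labels ordered category names, mildest first; defaults to those of
#'   [federationConfig()].
#' @return factor with levels ordered mildest first.
#' @examples
#' fmaCategory(17.75, k = 3)  # severe
#' fmaCategory(29, k = 3)     # moderate: boundary is half-open
#' @export
fmaCategory <- function(score, k = 3L, severe_boundary = 29,
                        mild_boundary = 43, labels = NULL) {
  if (any(score < 0 | score > 66)) {
    stopInput("FMA-UE scores must lie in [0, 66]")
  }
  if (!k %in% c(2L, 3L)) stopConfig("k must be 2 or 3 for FMA categorisation")
  labels <- labels %||% defaultSeverityLabels(k)
  cat_idx <- if (k == 2L) {
    ifelse(score < severe_boundary, 2L, 1L)
  } else {
    ifelse(score < severe_boundary, 3L, ifelse(score < mild_boundary, 2L, 1L))
  }
  factor(labels[cat_idx], levels = labels)
}

#' Cluster-to-severity mapping from trunk displacement
#'
#' Orders clusters by the ascending mean trunk displacement of their members
#' and assigns the mildest category to the lowest-displacement cluster, the
#' most severe to the highest. Ties break toward the lower cluster index,
#' keeping the mapping a bijection.
#'
#' @param labels integer cluster labels in `1..k`.
#' @param td per-subject trunk displacements, aligned with `labels` (a
#'   numeric vector or the data.frame from [subjectTrunkDisplacement()]).
#' @return named integer vector: `rank[cluster]`, 1 = mildest.
#' @export
severityMapFromTD <- function(labels, td) {
  tdv <- if (is.data.frame(td)) td$td else td
  if (length(tdv) != length(labels)) {
    stopInput("labels and trunk displacements differ in length")
  }
  k <- max(labels)
  counts <- tabulate(labels, nbins = k)
  if (any(counts == 0L)) {
    stopEval("empty cluster(s): %s", paste(which(counts == 0L), collapse = ", "))
  }
  cluster_td <- vapply(seq_len(k), function(c) mean(tdv[labels == c]), 0)
  rank <- integer(k)
  rank[order(cluster_td)] <- seq_len(k)
  setNames(rank, paste0("cluster", seq_len(k)))
}

#' Classification metrics against a reference labeling
#'
#' Builds the confusion matrix (rows = reference, columns = predicted) over
#' the union of category levels and reports accuracy (trace / n) plus
#' support-weighted precision, recall and F-score (per-class F is the
#' harmonic mean of that class's precision and recall; classes never
#' predicted get precision 0). Support-weighted recall equals accuracy by
#' construction.
#'
#' @param predicted,reference factors or character vectors of equal length
#'   over the same category set.
#' @return an [EvalReport-class].
#' @export
scoreLabels <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    stopInput("predicted and reference labels differ in length (%d vs %d)",
              length(predicted), length(reference))
  }
  levels_all <- if (is.factor(reference)) levels(reference) else
    sort(unique(c(as.character(reference), as.character(predicted))))
  pred <- factor(as.character(predicted), levels = levels_all)
  ref <- factor(as.character(reference), levels = levels_all)
  confusion <- table(reference = ref, predicted = pred)
  confusion <- matrix(as.integer(confusion), nrow(confusion),
                      dimnames = dimnames(confusion))
  n <- length(ref)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_count <- colSums(confusion)
  precision_c <- ifelse(pred_count > 0, tp / pred_count, 0)
  recall_c <- ifelse(support > 0, tp / support, 0)
  f_c <- ifelse(precision_c + recall_c > 0,
                2 * precision_c * recall_c / (precision_c + recall_c), 0)
  w <- support / n
  per_class <- data.frame(class = levels_all, precision = precision_c,
                          recall = recall_c, f_score = f_c,
                          support = as.integer(support),
                          row.names = NULL, stringsAsFactors = FALSE)
  new("EvalReport",
      accuracy = sum(tp) / n,
      precision = sum(w * precision_c),
      recall = sum(w * recall_c),
      f_score = sum(w * f_c),
      confusion = confusion, per_class = per_class, n = as.integer(n))
}

#' Computation/communication timing report
#'
#' CompT is the maximum local computation time across clients (the clients
#' run in parallel, so the slowest one bounds the round); CmT is the server
#' aggregation time; the total is their sum.
#'
#' @param summaries list of [ClientSummary-class].
#' @param comm_time_s server aggregation time in seconds.
#' @return a [TimingReport-class].
#' @export
timingReport <- function(summaries, comm_time_s) {
  if (!length(summaries)) stopInput("need >= 1 client summary")
  times <- vapply(summaries, function(s) s@comp_time_s, 0)
  if (any(times < 0) || comm_time_s < 0) {
    stopInput("times must be nonnegative")
  }
  comp <- max(times)
  new("TimingReport", comp_time_s = comp, comm_time_s = comm_time_s,
      total_s = comp + comm_time_s)
}

#' Evaluate pipeline assignments against FMA-derived reference categories
#'
#' Convenience wrapper: derives reference severity categories from the
#' cohort's FMA-UE scores and scores the pipeline's severity assignments
#' against them.
#'
#' @param assignments data.frame from [assignGlobal()] (or
#'   [runFederated()]`$assignments`).
#' @param cohort a [MotionCohort-class] with FMA scores assigned.
#' @param k 2 or 3 severity levels.
#' @param ... passed to [fmaCategory()].
#' @return an [EvalReport-class].
#' @export
evaluateAgainstFMA <- function(assignments, cohort, k = 3L, ...) {
  subj <- cohortSubjects(cohort)
  m <- match(assignments$subject_id, subj$subject_id)
  if (anyNA(m)) stopInput("assignments contain unknown subjects")
  if (anyNA(subj$fma[m])) {
    stopInput("cohort has no FMA scores; call assignReferenceFMA() first")
  }
  reference <- fmaCategory(subj$fma[m], k = k,
                           labels = levels(assignments$severity), ...)
  scoreLabels(assignments$severity, reference)
}
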