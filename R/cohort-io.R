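## Cohort persistence: one CSV per trial plus a JSON manifest. This is also
## the ingestion path for user-supplied data (CSV exports of device
## recordings): write CSVs in the same layout and point readCohort() at a
## hand-written manifest.

#' Write a cohort to disk
#'
#' One CSV per trial with columns `time_s` and `<channel>_<axis>`, plus a
#' `manifest.json` recording subjects, groups, FMA scores, sampling rate and
#' trial file paths.
#'
#' @param cohort a [MotionCohort-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "MotionCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trial_records <- vector("list", length(cohort@trials))
  for (i in seq_along(cohort@trials)) {
    tr <- cohort@trials[[i]]
    fn <- sprintf("%s_%s_rep%d.csv", tr@subject_id, tr@task_id, tr@repetition)
    n <- nrow(tr@positions)
    df <- data.frame(time_s = (seq_len(n) - 1) / tr@sampling_rate_hz,
                     tr@positions, check.names = FALSE)
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
    trial_records[[i]] <- list(
      subject_id = tr@subject_id, group = tr@group, task_id = tr@task_id,
      repetition = tr@repetition, path = fn,
      sampling_rate_hz = tr@sampling_rate_hz)
  }
  subj <- cohort@subjects
  manifest <- list(
    group_names = cohort@group_names,
    trunk_channel = cohort@trunk_channel,
    channel_names = cohort@trials[[1]]@channel_names,
    subjects = subj,
    trials = trial_records
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by [writeCohort()]
#'   (or hand-written for imported CSV exports in the same layout).
#' @return a [MotionCohort-class].
#' @export
readCohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stopInput("manifest not found: %s", manifest_path)
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  channel_names <- as.character(m$channel_names)
  fma_lookup <- setNames(m$subjects$fma, m$subjects$subject_id)
  trials <- lapply(seq_len(nrow(m$trials)), function(i) {
    rec <- m$trials[i, ]
    df <- utils::read.csv(file.path(dir, rec$path), check.names = FALSE)
    pos <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
    new("MotionTrial",
        subject_id = rec$subject_id,
        group = as.character(rec$group %||% NA_character_),
        task_id = rec$task_id, repetition = as.integer(rec$repetition),
        sampling_rate_hz = rec$sampling_rate_hz,
        positions = pos, channel_names = channel_names,
        fma_score = as.numeric(fma_lookup[rec$subject_id]))
  })
  subjects <- data.frame(subject_id = m$subjects$subject_id,
                         group = m$subjects$group,
                         fma = as.numeric(m$subjects$fma),
                         stringsAsFactors = FALSE)
  subjects <- subjects[order(subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL
  new("MotionCohort", trials = trials, subjects = subjects,
      group_names = as.character(m$group_names),
      trunk_channel = as.character(m$trunk_channel),
      config = list())
}
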