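## Synthetic motion cohorts with known severity-group structure.
##
## The generator plants the group effect exclusively in the trunk channel:
## more severe groups sway with larger trunk amplitude (compensatory
## movement), while all other channels carry task-dependent motion common
## across groups. Severity is therefore recoverable only through
## trunk-linked features, matching the labeling premise of the pipeline.

#' Configuration for a synthetic motion cohort
#'
#' Defaults mirror a wearable upper-limb protocol: 60 Hz sampling, five
#' sensors (hand, shoulder, upper arm, forearm, sternum), four tasks
#' performed three times, three severity groups whose trunk-sway amplitude
#' increases with severity.
#'
#' @param n_subjects_per_group subjects per severity group.
#' @param group_names ordered severity categories, mildest first.
#' @param trunk_amplitude_per_group trunk sinusoid amplitude per group
#'   (length units), strictly increasing with severity.
#' @param base_frequency_hz dominant movement frequency.
#' @param sampling_rate_hz samples per second; must exceed twice
#'   `base_frequency_hz` (Nyquist).
#' @param duration_s seconds per repetition.
#' @param n_tasks,n_repetitions task and repetition counts.
#' @param channel_names 3D channel identifiers; must include `trunk_channel`.
#' @param trunk_channel which channel carries the trunk (compensation) signal.
#' @param noise_sd additive sensor noise standard deviation (length units).
#' @param seed integer; one global seed drives a per-subject seed sequence
#'   (`seed + subject index`) so cohorts extend without reshuffling existing
#'   subjects.
#' @return a validated configuration list of class `psafl_cohort_config`.
#' @examples
#' cfg <- cohortConfig(n_subjects_per_group = 2, n_tasks = 1,
#'                     n_repetitions = 1, duration_s = 1)
#' @export
cohortConfig <- function(n_subjects_per_group = 20,
                         group_names = c("mild", "moderate", "severe"),
                         trunk_amplitude_per_group = c(1, 2, 4),
                         base_frequency_hz = 1,
                         sampling_rate_hz = 60,
                         duration_s = 3,
                         n_tasks = 4,
                         n_repetitions = 3,
                         channel_names = c("hand", "shoulder", "upper_arm",
                                           "forearm", "sternum"),
                         trunk_channel = "sternum",
                         noise_sd = 0.05,
                         seed = 1L) {
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    group_names = as.character(group_names),
    trunk_amplitude_per_group = as.numeric(trunk_amplitude_per_group),
    base_frequency_hz = base_frequency_hz,
    sampling_rate_hz = sampling_rate_hz,
    duration_s = duration_s,
    n_tasks = as.integer(n_tasks),
    n_repetitions = as.integer(n_repetitions),
    channel_names = as.character(channel_names),
    trunk_channel = as.character(trunk_channel),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "psafl_cohort_config"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  if (length(cfg$group_names) != length(cfg$trunk_amplitude_per_group)) {
    stopConfig("trunk_amplitude_per_group must have one value per group")
  }
  if (length(cfg$trunk_amplitude_per_group) > 1 &&
      any(diff(cfg$trunk_amplitude_per_group) <= 0)) {
    stopConfig(
      "invariant violated: trunk_amplitude_per_group must be strictly increasing with severity")
  }
  if (cfg$sampling_rate_hz <= 2 * cfg$base_frequency_hz) {
    stopConfig(
      "invariant violated: sampling_rate_hz must exceed 2 x base_frequency_hz (Nyquist)")
  }
  counts <- c(cfg$n_subjects_per_group, cfg$n_tasks, cfg$n_repetitions)
  if (any(counts < 1L)) {
    stopConfig("invariant violated: all counts must be >= 1")
  }
  if (cfg$noise_sd < 0) stopConfig("invariant violated: noise_sd must be >= 0")
  if (cfg$duration_s * cfg$sampling_rate_hz < 11) {
    stopConfig("duration_s x sampling_rate_hz must give >= 11 samples")
  }
  if (!cfg$trunk_channel %in% cfg$channel_names) {
    stopConfig("channel_names must include the trunk channel '%s'",
               cfg$trunk_channel)
  }
  invisible(TRUE)
}

## Deterministic per-(task, channel, axis) phase and gain for the shared
## (non-trunk) motion; identical across groups and subjects by construction.
sharedPhase <- function(task, channel_idx, axis) {
  ((task * 7 + channel_idx * 3 + axis) %% 12) * (2 * pi / 12)
}
sharedGain <- function(task, channel_idx, axis) {
  (1 + 0.2 * (task - 1)) * (0.5 + 0.1 * channel_idx) * c(1, 0.8, 0.6)[axis]
}

#' Generate a synthetic motion cohort
#'
#' Produces one [MotionTrial-class] per subject x task x repetition. The
#' trunk channel of a subject in severity group g is a sinusoid of amplitude
#' `trunk_amplitude_per_group[g]` (axis weights 1, 0.5, 0.25 for x, y, z)
#' plus Gaussian noise; every other channel carries task-dependent sinusoidal
#' motion identical across groups, plus noise. The trunk phase is fixed, so
#' at `noise_sd = 0` trunk displacement is exactly proportional to the group
#' amplitude and severity order is recoverable for every subject.
#'
#' @param config a [cohortConfig()] object.
#' @return a [MotionCohort-class]; ground-truth groups are in
#'   `cohortSubjects(x)$group` and on each trial.
#' @examples
#' cohort <- generateCohort(cohortConfig(n_subjects_per_group = 2,
#'   n_tasks = 1, n_repetitions = 1, duration_s = 1))
#' cohort
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "psafl_cohort_config")) {
    stopConfig("config must be created by cohortConfig()")
  }
  validateCohortConfig(config)
  G <- length(config$group_names)
  npg <- config$n_subjects_per_group
  n_samp <- round(config$duration_s * config$sampling_rate_hz)
  tt <- (seq_len(n_samp) - 1) / config$sampling_rate_hz
  nchan <- length(config$channel_names)
  trunk_idx <- match(config$trunk_channel, config$channel_names)
  axis_w <- c(1, 0.5, 0.25)  # trunk sway mostly fore-aft (x)
  colnm <- as.vector(t(outer(config$channel_names, c("x", "y", "z"),
                             paste, sep = "_")))

  trials <- vector("list", G * npg * config$n_tasks * config$n_repetitions)
  subj_id <- character(G * npg)
  subj_group <- character(G * npg)
  idx <- 0L
  for (g in seq_len(G)) {
    A <- config$trunk_amplitude_per_group[g]
    for (s in seq_len(npg)) {
      j <- (g - 1L) * npg + s          # global subject index
      sid <- sprintf("S%04d", j)
      subj_id[j] <- sid
      subj_group[j] <- config$group_names[g]
      subject_trials <- withSeed(config$seed + j, {
        out <- vector("list", config$n_tasks * config$n_repetitions)
        ti <- 0L
        for (task in seq_len(config$n_tasks)) {
          for (rep in seq_len(config$n_repetitions)) {
            pos <- matrix(0, n_samp, 3L * nchan, dimnames = list(NULL, colnm))
            for (ch in seq_len(nchan)) {
              for (ax in 1:3) {
                cc <- (ch - 1L) * 3L + ax
                if (ch == trunk_idx) {
                  clean <- A * axis_w[ax] *
                    sin(2 * pi * config$base_frequency_hz * tt)
                } else {
                  clean <- sharedGain(task, ch, ax) *
                    sin(2 * pi * config$base_frequency_hz * tt +
                          sharedPhase(task, ch, ax))
                }
                pos[, cc] <- clean +
                  if (config$noise_sd > 0) {
                    rnorm(n_samp, sd = config$noise_sd)
                  } else 0
              }
            }
            ti <- ti + 1L
            out[[ti]] <- new("MotionTrial",
              subject_id = sid, group = config$group_names[g],
              task_id = sprintf("task%d", task), repetition = as.integer(rep),
              sampling_rate_hz = config$sampling_rate_hz,
              positions = pos, channel_names = config$channel_names,
              fma_score = NA_real_)
          }
        }
        out
      })
      trials[(idx + 1L):(idx + length(subject_trials))] <- subject_trials
      idx <- idx + length(subject_trials)
    }
  }
  subjects <- data.frame(subject_id = subj_id, group = subj_group,
                         fma = NA_real_, stringsAsFactors = FALSE)
  subjects <- subjects[order(subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL
  new("MotionCohort", trials = trials, subjects = subjects,
      group_names = config$group_names,
      trunk_channel = config$trunk_channel,
      config = unclass(config))
}

#' Assign reference Fugl-Meyer (FMA-UE) scores to a cohort
#'
#' Draws one seeded per-subject score from a group-specific range, monotone
#' decreasing in severity: the most severe group draws uniformly from
#' `[15, 29)` (below the severe-impairment boundary of 29), the remaining
#' groups split `[29, 66]` into equal consecutive intervals with the mildest
#' group at the top. Reference only; never consumed by the clustering
#' pipeline.
#'
#' @param cohort a [MotionCohort-class] with group labels.
#' @param severe_boundary FMA-UE boundary below which scores denote severe
#'   impairment.
#' @param mild_boundary moderate/mild boundary used when the cohort has
#'   three groups, matching the default of [fmaCategory()] so reference
#'   categories recover the generating groups exactly.
#' @return the cohort with `fma` filled in (subjects table and trials).
#' @export
assignReferenceFMA <- function(cohort, severe_boundary = 29,
                               mild_boundary = 43) {
  stopifnot(is(cohort, "MotionCohort"))
  groups <- cohort@group_names
  G <- length(groups)
  subj <- cohort@subjects
  if (!all(subj$group %in% groups)) {
    bad <- setdiff(unique(subj$group), groups)
    stopWith("psafl_label_error", "unknown group(s): %s",
             paste(bad, collapse = ", "))
  }
  ## ranges[g, ] = (lo, hi) for severity position g (1 = mildest)
  ranges <- matrix(NA_real_, G, 2)
  if (G == 1L) {
    ranges[1, ] <- c(severe_boundary, 66)
  } else {
    n_mild <- G - 1L
    cuts <- if (G == 3L) {
      c(severe_boundary, mild_boundary, 66)
    } else {
      seq(severe_boundary, 66, length.out = n_mild + 1L)
    }
    for (g in seq_len(n_mild)) {
      ranges[g, ] <- c(cuts[n_mild + 1L - g], cuts[n_mild + 2L - g])
    }
    ranges[G, ] <- c(max(15, severe_boundary - 14), severe_boundary)
  }
  seed0 <- (cohort@config$seed %||% 0L) + 100000L
  fma <- numeric(nrow(subj))
  for (i in seq_len(nrow(subj))) {
    g <- match(subj$group[i], groups)
    fma[i] <- withSeed(seed0 + i, {
      lo <- ranges[g, 1]; hi <- ranges[g, 2]
      lo + (hi - lo) * 0.999 * runif(1)   # keep strictly below the upper cut
    })
  }
  subj$fma <- fma
  cohort@subjects <- subj
  lookup <- setNames(fma, subj$subject_id)
  cohort@trials <- lapply(cohort@trials, function(tr) {
    tr@fma_score <- unname(lookup[tr@subject_id])
    tr
  })
  cohort
}
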