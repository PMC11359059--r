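## Preprocessing: zero-phase Butterworth filtering, acceleration derivation,
## trunk displacement, and the frequency-domain feature matrix.

#' Low-pass filter specification
#'
#' Defaults follow common motion-capture practice for wearable data: a
#' second-order Butterworth low-pass at 10 Hz (use 20 Hz for high-rate
#' camera data).
#'
#' @param order filter order (>= 1).
#' @param cutoff_hz cutoff frequency; must be below the Nyquist frequency of
#'   the series it is applied to.
#' @param kind only `"low"` is supported.
#' @return a list of class `psafl_filter_spec`.
#' @export
filterSpec <- function(order = 2L, cutoff_hz = 10, kind = "low") {
  if (order < 1L) stopConfig("filter order must be >= 1")
  if (cutoff_hz <= 0) stopConfig("cutoff_hz must be > 0")
  if (!identical(kind, "low")) stopConfig("only low-pass filtering is supported")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = kind),
            class = "psafl_filter_spec")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward-backward
#' (zero phase), so movement events are not delayed; the effective magnitude
#' response is the single-pass response squared. The series is extended by
#' odd reflection at both ends before filtering and trimmed afterwards, so
#' start-up transients of the recursive filter decay inside the padding
#' rather than corrupting the data (plain zero-initialised forward-backward
#' filtering leaves a large artifact at the series end).
#'
#' @param series numeric vector (one channel-axis time series).
#' @param sampling_rate_hz samples per second.
#' @param spec a [filterSpec()].
#' @return filtered series, same length as the input.
#' @export
lowpassFilter <- function(series, sampling_rate_hz, spec = filterSpec()) {
  if (!inherits(spec, "psafl_filter_spec")) {
    stopConfig("spec must be created by filterSpec()")
  }
  nyq <- sampling_rate_hz / 2
  if (spec$cutoff_hz >= nyq) {
    stopConfig("cutoff_hz (%g) must be below the Nyquist frequency (%g)",
               spec$cutoff_hz, nyq)
  }
  n <- length(series)
  if (n < 3L * spec$order) {
    stopInput("series too short (%d) for order-%d filtering", n, spec$order)
  }
  b <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  ## pad long enough for the start-up transient (~ fs / cutoff samples)
  npad <- min(n - 1L,
              max(3L * (spec$order + 1L),
                  ceiling(6 * sampling_rate_hz / spec$cutoff_hz)))
  pre <- 2 * series[1] - series[seq(npad + 1L, 2L)]
  post <- 2 * series[n] - series[seq(n - 1L, n - npad)]
  padded <- c(pre, series, post)
  fwd <- signal::filter(b, padded)
  bwd <- rev(as.numeric(signal::filter(b, rev(as.numeric(fwd)))))
  bwd[(npad + 1L):(npad + n)]
}

#' Linear acceleration from position by central second differences
#'
#' Interior points use the central second difference
#' `a_t = (p_{t+1} - 2 p_t + p_{t-1}) * fs^2` (exact for quadratics);
#' endpoints use the one-sided second difference of the three nearest
#' samples, keeping the output aligned with the input time base.
#'
#' @param positions numeric vector or time-by-columns matrix.
#' @param sampling_rate_hz samples per second.
#' @return acceleration, same shape as the input.
#' @export
deriveAcceleration <- function(positions, sampling_rate_hz) {
  vec <- is.null(dim(positions))
  p <- if (vec) matrix(positions, ncol = 1L) else positions
  n <- nrow(p)
  if (n < 3L) stopInput("need >= 3 samples to derive acceleration, got %d", n)
  fs2 <- sampling_rate_hz^2
  a <- p
  a[2:(n - 1), ] <- (p[3:n, , drop = FALSE] - 2 * p[2:(n - 1), , drop = FALSE] +
                       p[1:(n - 2), , drop = FALSE]) * fs2
  a[1, ] <- (p[3, ] - 2 * p[2, ] + p[1, ]) * fs2
  a[n, ] <- (p[n, ] - 2 * p[n - 1, ] + p[n - 2, ]) * fs2
  if (vec) drop(a) else a
}

#' Trunk displacement relative to a resting baseline
#'
#' The per-axis baseline is the mean of the first `baseline_n` samples; for
#' every later step the displacement is the sum of absolute per-axis
#' deviations from that baseline, `TD = TD_x + TD_y + TD_z`. With multiple
#' trunk markers (a list of matrices), the per-step TD is averaged across
#' markers. Absolute deviations make TD a nonnegative magnitude, so it can
#' serve directly as a severity score (signed sums could cancel).
#'
#' @param positions a time-by-3 matrix (columns x, y, z) or a list of such
#'   matrices (one per trunk marker).
#' @param baseline_n number of leading samples averaged into the baseline.
#' @return a list with `td` (per-step displacement series), `components`
#'   (per-step TD_x/TD_y/TD_z matrix, averaged over markers) and `mean_td`
#'   (mean per-step TD).
#' @examples
#' p <- rbind(matrix(rep(c(1, 2, 3), each = 10), 10), c(2, 4, 6))
#' trunkDisplacement(p)$td  # 6
#' @export
trunkDisplacement <- function(positions, baseline_n = 10L) {
  markers <- if (is.list(positions)) positions else list(positions)
  n <- nrow(markers[[1]])
  if (any(vapply(markers, nrow, 0L) != n)) {
    stopInput("all trunk markers must share one time base")
  }
  if (n < baseline_n + 1L) {
    stopInput("need >= baseline_n + 1 = %d samples, got %d",
              baseline_n + 1L, n)
  }
  per_marker <- lapply(markers, function(p) {
    if (ncol(p) != 3L) stopInput("trunk positions must have 3 columns (x, y, z)")
    baseline <- colMeans(p[seq_len(baseline_n), , drop = FALSE])
    dev <- abs(sweep(p[(baseline_n + 1L):n, , drop = FALSE], 2L, baseline))
    dev
  })
  components <- Reduce(`+`, per_marker) / length(per_marker)
  colnames(components) <- c("TD_x", "TD_y", "TD_z")
  td <- rowSums(components)
  list(td = td, components = components, mean_td = mean(td))
}

## All columns of a trial belonging to the trunk channel, as a t x 3 matrix.
trunkColumns <- function(trial, trunk_channel) {
  cols <- paste(trunk_channel, c("x", "y", "z"), sep = "_")
  missing <- setdiff(cols, colnames(trial@positions))
  if (length(missing)) {
    stopInput("trunk channel columns not found: %s",
              paste(missing, collapse = ", "))
  }
  trial@positions[, cols, drop = FALSE]
}

#' Per-subject trunk-displacement summary
#'
#' Computes the mean per-step trunk displacement of every trial and averages
#' it across each subject's tasks and repetitions.
#'
#' @param cohort a [MotionCohort-class] (or list of [MotionTrial-class]).
#' @param trunk_channel trunk channel name; defaults to the cohort's.
#' @param baseline_n baseline window length, see [trunkDisplacement()].
#' @return data.frame with columns `subject_id`, `td`, sorted by subject.
#' @export
subjectTrunkDisplacement <- function(cohort, trunk_channel = NULL,
                                     baseline_n = 10L) {
  trials <- if (is(cohort, "MotionCohort")) cohort@trials else cohort
  trunk_channel <- trunk_channel %||%
    if (is(cohort, "MotionCohort")) cohort@trunk_channel else
      stopConfig("trunk_channel is required for a bare trial list")
  per_trial <- vapply(trials, function(tr) {
    trunkDisplacement(trunkColumns(tr, trunk_channel), baseline_n)$mean_td
  }, 0)
  sid <- vapply(trials, function(tr) tr@subject_id, "")
  out <- aggregate(list(td = per_trial), by = list(subject_id = sid), mean)
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequency-domain feature matrix
#'
#' Per trial, each channel-axis series is low-pass filtered (zero phase),
#' optionally differentiated twice into acceleration, and transformed with
#' the real discrete Fourier transform; the first `n_bins` amplitude-scaled
#' spectral magnitudes per channel-axis (`|FFT|/n`, doubled for non-DC bins,
#' so a sinusoid of amplitude A contributes A at its frequency bin) form the
#' trial's feature vector. Feature vectors are averaged across each
#' subject's tasks and repetitions; columns are then normalised per
#' `scale`. Rows are subjects in sorted order.
#'
#' All features share one physical unit, so the default normalisation is
#' centering only: scaling every column to unit variance (`"zscore"`) would
#' inflate noise-floor bins to the same weight as movement-band bins and
#' bury the between-subject signal. `"zscore"` remains available for
#' heterogeneous imports (zero-variance columns are centered to 0).
#'
#' @param cohort a [MotionCohort-class] or list of [MotionTrial-class].
#' @param spec a [filterSpec()].
#' @param feature_kind `"position"` or `"acceleration"`.
#' @param n_bins spectral magnitudes kept per channel-axis; at most
#'   `floor(samples / 2) + 1`.
#' @param scale column normalisation: `"center"` (default), `"zscore"` or
#'   `"none"`.
#' @return a [FeatureMatrix-class] with `channels x 3 x n_bins` columns.
#' @export
frequencyFeatures <- function(cohort, spec = filterSpec(),
                              feature_kind = c("position", "acceleration"),
                              n_bins = 8L,
                              scale = c("center", "zscore", "none")) {
  feature_kind <- match.arg(feature_kind)
  scale <- match.arg(scale)
  trials <- if (is(cohort, "MotionCohort")) cohort@trials else cohort
  if (!length(trials)) stopInput("no trials supplied")
  fs <- vapply(trials, function(tr) tr@sampling_rate_hz, 0)
  if (length(unique(fs)) != 1L) {
    stopInput("trials have mixed sampling rates: %s",
              paste(sort(unique(fs)), collapse = ", "))
  }
  fs <- fs[1]
  n_samp <- nrow(trials[[1]]@positions)
  if (n_bins > floor(n_samp / 2) + 1L) {
    stopInput("n_bins (%d) exceeds floor(samples/2) + 1 = %d",
              n_bins, floor(n_samp / 2) + 1L)
  }
  trial_feats <- t(vapply(trials, function(tr) {
    p <- tr@positions
    feat <- numeric(ncol(p) * n_bins)
    for (cc in seq_len(ncol(p))) {
      x <- lowpassFilter(p[, cc], fs, spec)
      if (feature_kind == "acceleration") x <- deriveAcceleration(x, fs)
      mag <- Mod(fft(x))[seq_len(n_bins)] / length(x)
      if (n_bins > 1L) mag[-1L] <- 2 * mag[-1L]  # one-sided amplitude scale
      feat[((cc - 1L) * n_bins + 1L):(cc * n_bins)] <- mag
    }
    feat
  }, numeric(3L * length(trials[[1]]@channel_names) * n_bins)))
  if (any(!is.finite(trial_feats))) {
    stopData("non-finite values after frequency transform")
  }
  sid <- vapply(trials, function(tr) tr@subject_id, "")
  subj_ids <- sort(unique(sid))
  feats <- t(vapply(subj_ids, function(s) {
    colMeans(trial_feats[sid == s, , drop = FALSE])
  }, numeric(ncol(trial_feats))))
  if (scale != "none") {
    feats <- sweep(feats, 2L, colMeans(feats))
    if (scale == "zscore") {
      sdev <- apply(feats, 2L, sd)
      pos_sd <- sdev > 1e-12
      feats[, pos_sd] <- sweep(feats[, pos_sd, drop = FALSE], 2L,
                               sdev[pos_sd], "/")
      feats[, !pos_sd] <- 0  # zero-variance: centered only
    }
  }
  chan <- trials[[1]]@channel_names
  fname <- as.vector(t(outer(
    as.vector(t(outer(chan, c("x", "y", "z"), paste, sep = "_"))),
    paste0("bin", seq_len(n_bins)), paste, sep = "_")))
  dimnames(feats) <- list(subj_ids, fname)
  new("FeatureMatrix", values = feats,
      feature_kind = paste0(feature_kind, "-spectrum"))
}

#' Write / read a feature matrix as CSV
#'
#' Plain CSV with a leading `subject_id` column and named feature columns;
#' the feature kind travels in a `# kind:` comment line.
#'
#' @param features a [FeatureMatrix-class].
#' @param path CSV path.
#' @return `writeFeatures`: the path, invisibly. `readFeatures`: a
#'   [FeatureMatrix-class].
#' @export
writeFeatures <- function(features, path) {
  v <- featureValues(features)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", featureKind(features)), con)
  utils::write.csv(data.frame(subject_id = rownames(v), v,
                              check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stopInput("feature file not found: %s", path)
  first <- readLines(path, n = 1L)
  kind <- if (startsWith(first, "# kind:")) {
    trimws(sub("^# kind:", "", first))
  } else "position-spectrum"
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$subject_id
  new("FeatureMatrix", values = v[order(rownames(v)), , drop = FALSE],
      feature_kind = kind)
}
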