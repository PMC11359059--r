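# Fixtures are built in code at test time; nothing is read from disk.

# Small three-group cohort: one task, one repetition, 2 s at 60 Hz.
tinyCohortConfig <- function(n_per_group = 4, noise_sd = 0.05, seed = 7,
                             groups = c("mild", "moderate", "severe"),
                             amplitudes = c(1, 2, 4), ...) {
  cohortConfig(n_subjects_per_group = n_per_group, group_names = groups,
               trunk_amplitude_per_group = amplitudes,
               n_tasks = 1, n_repetitions = 1, duration_s = 2,
               noise_sd = noise_sd, seed = seed, ...)
}

# Gaussian blobs around the given center rows; returns a FeatureMatrix.
toyFeatures <- function(centers, n_per_cluster = 10, sd = 0.2, seed = 1) {
  centers <- as.matrix(centers)
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c) {
    matrix(rnorm(n_per_cluster * ncol(centers), sd = sd),
           n_per_cluster) + matrix(centers[c, ], n_per_cluster,
                                   ncol(centers), byrow = TRUE)
  }))
  dimnames(x) <- list(sprintf("S%03d", seq_len(nrow(x))),
                      sprintf("f%02d", seq_len(ncol(x))))
  new("FeatureMatrix", values = x, feature_kind = "position-spectrum")
}

toyTruth <- function(n_clusters, n_per_cluster = 10) {
  rep(seq_len(n_clusters), each = n_per_cluster)
}

asPartition <- function(labels, name = "k-means") {
  new("BasePartition", method = list(name = name, params = list(), seed = 1L),
      labels = as.integer(labels),
      n_clusters_found = length(unique(labels)))
}

# A trial list with an arbitrary channel count (for feature-dimension checks).
flatTrials <- function(n_subjects, n_channels, n_samples = 40, fs = 60,
                       value = 0) {
  chan <- sprintf("ch%02d", seq_len(n_channels))
  cols <- as.vector(t(outer(chan, c("x", "y", "z"), paste, sep = "_")))
  lapply(seq_len(n_subjects), function(s) {
    pos <- matrix(value, n_samples, 3 * n_channels,
                  dimnames = list(NULL, cols))
    new("MotionTrial", subject_id = sprintf("S%03d", s), group = "mild",
        task_id = "task1", repetition = 1L, sampling_rate_hz = fs,
        positions = pos, channel_names = chan, fma_score = NA_real_)
  })
}

# Hand-built ClientSummary for aggregation closed-form tests.
mkSummary <- function(id, n, centers, td = seq_len(nrow(centers)),
                      comp_time = 0) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  rank <- integer(k); rank[order(td)] <- seq_len(k)
  new("ClientSummary", client_id = id, n_points = as.integer(n),
      centers = centers, cluster_td = as.numeric(td),
      severity_rank = rank,
      local_labels = setNames(rep(1L, n), sprintf("%s_S%d", id, seq_len(n))),
      comp_time_s = comp_time)
}
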