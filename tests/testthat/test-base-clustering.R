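test_that("every base method recovers well-separated groups and is seed-deterministic", {
  fm <- toyFeatures(rbind(c(0, 0, 0), c(8, 8, 8)), n_per_cluster = 12,
                    sd = 0.3, seed = 2)
  truth <- toyTruth(2, 12)
  for (nm in c("fuzzy-c-means", "k-means", "som", "gmm", "dbscan",
               "hierarchical", "spectral", "optics")) {
    spec <- methodSpec(nm, seed = 5)
    p1 <- runMethod(fm, spec, k = 2)
    p2 <- runMethod(fm, spec, k = 2)
    expect_identical(partitionLabels(p1), partitionLabels(p2), label = nm)
    expect_equal(bestPermutationAgreement(partitionLabels(p1), truth), 1,
                 label = nm)
    expect_true(all(partitionLabels(p1) %in% 1:2), label = nm)
  }
})

test_that("k-means with n = k puts every point in its own cluster", {
  fm <- toyFeatures(diag(4) * 10, n_per_cluster = 1, sd = 0, seed = 1)
  p <- runMethod(fm, methodSpec("k-means", seed = 1), k = 4)
  expect_equal(sort(partitionLabels(p)), 1:4)
})

test_that("method validation catches unknown names and degenerate features", {
  expect_error(methodSpec("affinity-propagation"),
               class = "psafl_config_error")
  flat <- new("FeatureMatrix",
              values = matrix(1, 6, 3,
                              dimnames = list(sprintf("S%d", 1:6),
                                              c("a", "b", "c"))),
              feature_kind = "position-spectrum")
  expect_error(runMethod(flat, methodSpec("k-means"), k = 2),
               class = "psafl_data_error")
  fm <- toyFeatures(rbind(0, 5), n_per_cluster = 2, seed = 1)
  expect_error(runMethod(fm, methodSpec("k-means"), k = 5),
               class = "psafl_input_error")
})

test_that("density methods reassign noise and harmonise to at most k clusters", {
  # two tight groups plus one far outlier that DBSCAN flags as noise
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 5, 0.1), 10, 2),
             c(50, 50))
  dimnames(x) <- list(sprintf("S%03d", 1:21), c("f1", "f2"))
  fm <- new("FeatureMatrix", values = x, feature_kind = "position-spectrum")
  for (nm in c("dbscan", "optics")) {
    p <- runMethod(fm, methodSpec(nm, params = list(minPts = 4), seed = 1),
                   k = 2)
    expect_true(all(partitionLabels(p) %in% 1:2), label = nm)
    # the outlier joins the cluster whose centroid is nearest
    expect_equal(partitionLabels(p)[21], partitionLabels(p)[20], label = nm)
    expect_equal(bestPermutationAgreement(partitionLabels(p)[1:20],
                                          toyTruth(2, 10)), 1, label = nm)
  }
})

test_that("connectivity matrices follow the co-membership definition", {
  expect_equal(connectivityMatrix(c(1, 1, 2)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(connectivityMatrix(rep(1, 4)), matrix(1, 4, 4))
  expect_equal(connectivityMatrix(1:4), diag(4))
})

test_that("the consensus matrix is the element-wise mean of connectivities", {
  cm <- consensusMatrix(list(asPartition(c(1, 1, 2)), asPartition(c(1, 2, 2))))
  expect_equal(cmValues(cm),
               rbind(c(1, 0.5, 0), c(0.5, 1, 0.5), c(0, 0.5, 1)))
  expect_equal(nPartitions(cm), 2L)
  # t identical partitions collapse to the single connectivity matrix
  same <- replicate(5, asPartition(c(1, 2, 1, 2)), simplify = FALSE)
  expect_equal(cmValues(consensusMatrix(same)),
               connectivityMatrix(c(1, 2, 1, 2)))
  expect_error(consensusMatrix(list(asPartition(1:3), asPartition(1:4))),
               class = "psafl_input_error")
  expect_error(consensusMatrix(list()), class = "psafl_input_error")
})

test_that("consensus entries are exact co-clustering fractions, any order", {
  set.seed(42)
  for (trial in 1:5) {
    n <- sample(10:50, 1)
    t <- sample(2:8, 1)
    parts <- replicate(t, asPartition(sample(1:3, n, replace = TRUE)),
                       simplify = FALSE)
    cm <- cmValues(consensusMatrix(parts))
    # brute-force pair-by-pair co-membership count
    brute <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      m <- sum(vapply(parts, function(p) {
        p@labels[i] == p@labels[j]
      }, logical(1)))
      brute[i, j] <- m / t
    }
    expect_equal(cm, brute, tolerance = 0)
    expect_true(all(diag(cm) == 1))
    # permuting partition order changes nothing
    cm2 <- cmValues(consensusMatrix(rev(parts)))
    expect_identical(cm, cm2)
  }
})

test_that("exhaustive search enumerates all subsets with the stated tie-break", {
  fm <- toyFeatures(rbind(c(0, 0), c(6, 6)), n_per_cluster = 8, sd = 0.3,
                    seed = 4)
  res <- exhaustiveSearch(fm, c("k-means", "hierarchical", "gmm"), k = 2,
                          mnmf_config = mnmfConfig(k = 2, n_restarts = 2))
  expect_equal(nrow(res$scores), 7)  # 2^3 - 1
  # trivially separable data: every subset scores 1, so the tie-break
  # must pick a single method, the lexicographically first one
  expect_equal(res$scores$score, rep(1, 7), tolerance = 1e-12)
  expect_equal(res$best, "gmm")
  expect_equal(res$scores$size[1], 1)
})

test_that("exhaustive search can optimise agreement with reference labels", {
  fm <- toyFeatures(rbind(c(0, 0), c(6, 6)), n_per_cluster = 8, sd = 0.3,
                    seed = 4)
  res <- exhaustiveSearch(fm, c("k-means", "hierarchical"), k = 2,
                          objective = "reference",
                          reference = toyTruth(2, 8),
                          mnmf_config = mnmfConfig(k = 2, n_restarts = 2))
  expect_equal(res$best_score, 1)
  expect_error(exhaustiveSearch(fm, character(0), k = 2),
               class = "psafl_config_error")
  expect_error(exhaustiveSearch(fm, "k-means", k = 2,
                                objective = "reference"),
               class = "psafl_config_error")
})
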