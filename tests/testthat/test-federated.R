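# Shared small-cohort pipeline inputs for the federation tests.
fedFixture <- function(n_per_group = 10, seed = 31) {
  cohort <- generateCohort(tinyCohortConfig(n_per_group = n_per_group,
                                            seed = seed))
  feats <- frequencyFeatures(cohort, n_bins = 4)
  list(cohort = cohort, feats = feats, td = subjectTrunkDisplacement(cohort))
}

test_that("subjects are split evenly, disjointly and reproducibly across clients", {
  fx <- fedFixture()
  cfg <- federationConfig(n_clients = 15, k = 2, partition_seed = 9,
                          mnmf = mnmfConfig(k = 2))
  clients <- partitionClients(fx$feats, fx$td, cfg)
  expect_length(clients, 15)
  sizes <- vapply(clients, function(cl) length(cl$indices), 0L)
  expect_true(all(sizes == 2))
  all_idx <- sort(unlist(lapply(clients, `[[`, "indices")))
  expect_equal(all_idx, 1:30)
  clients2 <- partitionClients(fx$feats, fx$td, cfg)
  expect_identical(lapply(clients, `[[`, "indices"),
                   lapply(clients2, `[[`, "indices"))
  # M = 1 holds everything in the original order
  cfg1 <- federationConfig(n_clients = 1, k = 2, mnmf = mnmfConfig(k = 2))
  one <- partitionClients(fx$feats, fx$td, cfg1)
  expect_equal(one[[1]]$indices, 1:30)
  expect_error(partitionClients(fx$feats, fx$td,
                                federationConfig(n_clients = 20, k = 2,
                                                 mnmf = mnmfConfig(k = 2))),
               class = "psafl_config_error")
})

test_that("a client run is a pure function of its data and configuration", {
  fx <- fedFixture(n_per_group = 6)
  cfg <- federationConfig(n_clients = 1, k = 3)
  client <- list(client_id = "clientA", features = fx$feats, td = fx$td,
                 indices = seq_len(18))
  s1 <- runClient(client, cfg)
  client$client_id <- "clientB"
  s2 <- runClient(client, cfg)
  expect_identical(s1@centers, s2@centers)
  expect_identical(s1@local_labels, s2@local_labels)
  expect_identical(s1@severity_rank, s2@severity_rank)
  expect_false(s1@client_id == s2@client_id)
  # severity ranks follow ascending per-cluster trunk displacement
  expect_identical(order(s1@cluster_td), order(s1@severity_rank))
})

test_that("client summaries carry no raw data, only model summaries", {
  slots <- slotNames("ClientSummary")
  expect_true(all(c("centers", "cluster_td", "severity_rank",
                    "local_labels", "n_points", "comp_time_s") %in% slots))
  expect_false(any(c("features", "positions", "trials", "td") %in% slots))
  # and fedAvg consumes nothing but those summaries
  expect_equal(names(formals(fedAvg)), c("summaries", "config"))
})

test_that("FedAvg reproduces hand-computed size-weighted centroid means", {
  cfg <- federationConfig(n_clients = 2, k = 2, mnmf = mnmfConfig(k = 2))
  a <- mkSummary("clientA", 2, rbind(0, 100), td = c(1, 2))
  b <- mkSummary("clientB", 6, rbind(2, 104), td = c(1, 2))
  model <- fedAvg(list(a, b), cfg)
  expect_equal(unname(globalCenters(model)[1, ]), (2 * 0 + 6 * 2) / 8)
  expect_equal(unname(globalCenters(model)[2, ]), (2 * 100 + 6 * 104) / 8)
  expect_equal(sum(model@weights_used), 1, tolerance = 1e-12)
  # single client: identity aggregation
  solo <- fedAvg(list(a), cfg)
  expect_equal(unname(globalCenters(solo)), unname(a@centers))
  # identical centers: convexity fixes the result regardless of weights
  same <- fedAvg(list(mkSummary("c1", 3, rbind(1, 5)),
                      mkSummary("c2", 9, rbind(1, 5))), cfg)
  expect_equal(unname(globalCenters(same)), rbind(1, 5))
})

test_that("FedAvg aligns clusters by severity rank before averaging", {
  cfg <- federationConfig(n_clients = 2, k = 2, mnmf = mnmfConfig(k = 2))
  # client B's cluster 1 is the *severe* one (higher TD): must align with
  # client A's cluster 2
  a <- mkSummary("clientA", 4, rbind(0, 10), td = c(1, 9))
  b <- mkSummary("clientB", 4, rbind(12, 2), td = c(8, 1))
  model <- fedAvg(list(a, b), cfg)
  expect_equal(unname(globalCenters(model)[1, ]), (0 + 2) / 2)   # mildest
  expect_equal(unname(globalCenters(model)[2, ]), (10 + 12) / 2) # severe
})

test_that("aggregation is exactly invariant to client order", {
  cfg <- federationConfig(n_clients = 3, k = 2, mnmf = mnmfConfig(k = 2))
  s <- list(mkSummary("c1", 3, rbind(0.1, 1.7)),
            mkSummary("c2", 5, rbind(0.3, 2.9)),
            mkSummary("c3", 2, rbind(0.7, 3.3)))
  m1 <- fedAvg(s, cfg)
  m2 <- fedAvg(s[c(3, 1, 2)], cfg)
  expect_identical(globalCenters(m1), globalCenters(m2))
  expect_identical(m1@weights_used, m2@weights_used)
})

test_that("mismatched summaries and empty participation are rejected", {
  cfg <- federationConfig(n_clients = 2, k = 2, mnmf = mnmfConfig(k = 2))
  a <- mkSummary("clientA", 2, rbind(0, 1))
  bad <- mkSummary("clientB", 2, rbind(c(0, 0), c(1, 1)))
  expect_error(fedAvg(list(a, bad), cfg), class = "psafl_input_error")
  cfg$participating <- "nobody"
  expect_error(fedAvg(list(a), cfg), class = "psafl_config_error")
})

test_that("global labeling picks the nearest center with ties to the milder", {
  model <- new("GlobalModel", W = rbind(c(0, 0), c(4, 0), c(8, 0)),
               severity_label_per_cluster = c("mild", "moderate", "severe"),
               weights_used = c(central = 1), comm_time_s = 0)
  x <- rbind(c(0, 0),    # exactly the mild center
             c(2, 0),    # equidistant mild/moderate -> milder wins
             c(7.9, 0))
  dimnames(x) <- list(c("S1", "S2", "S3"), c("f1", "f2"))
  fm <- new("FeatureMatrix", values = x, feature_kind = "position-spectrum")
  got <- assignGlobal(fm, model)
  expect_equal(got$cluster, c(1L, 1L, 3L))
  expect_equal(as.character(got$severity), c("mild", "mild", "severe"))
  expect_error(assignGlobal(fm, new("GlobalModel", W = matrix(0, 2, 5),
                                    severity_label_per_cluster = c("a", "b"),
                                    weights_used = 1, comm_time_s = 0)),
               class = "psafl_input_error")
})

test_that("points near well-separated centers are labeled by their center", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(c) {
    sweep(matrix(rnorm(20, sd = 0.5), 10, 2), 2, centers[c, ], `+`)
  }))
  dimnames(x) <- list(sprintf("S%02d", 1:30), c("f1", "f2"))
  fm <- new("FeatureMatrix", values = x, feature_kind = "position-spectrum")
  model <- new("GlobalModel", W = centers,
               severity_label_per_cluster = c("mild", "moderate", "severe"),
               weights_used = c(central = 1), comm_time_s = 0)
  expect_equal(assignGlobal(fm, model)$cluster, rep(1:3, each = 10))
})

test_that("a single-client federation reproduces the centralized pipeline bit for bit", {
  fx <- fedFixture(n_per_group = 8, seed = 17)
  cfg <- federationConfig(n_clients = 1, k = 3, partition_seed = 5,
                          method_seed = 2,
                          mnmf = mnmfConfig(k = 3, n_restarts = 3, seed = 2))
  fed <- runFederated(fx$feats, fx$td, cfg)
  cen <- runCentralized(fx$feats, fx$td, cfg)
  expect_identical(globalCenters(fed$model), globalCenters(cen$model))
  expect_identical(fed$assignments$cluster, cen$assignments$cluster)
  expect_identical(fed$assignments$severity, cen$assignments$severity)
})

test_that("the federated pipeline recovers the generating groups end to end", {
  fx <- fedFixture(n_per_group = 10, seed = 23)
  cfg <- federationConfig(n_clients = 3, k = 3, partition_seed = 4,
                          method_seed = 6,
                          mnmf = mnmfConfig(k = 3, n_restarts = 5, seed = 6))
  fed <- runFederated(fx$feats, fx$td, cfg)
  truth <- cohortSubjects(fx$cohort)$group
  expect_gte(bestPermutationAgreement(fed$assignments$cluster,
                                      factor(truth)), 0.9)
  # severity direction: severe subjects get the severe label
  sev <- as.character(fed$assignments$severity[truth == "severe"])
  expect_gte(mean(sev == "severe"), 0.9)
  expect_s4_class(fed$timing, "TimingReport")
  expect_equal(fed$timing@total_s,
               fed$timing@comp_time_s + fed$timing@comm_time_s)
})
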