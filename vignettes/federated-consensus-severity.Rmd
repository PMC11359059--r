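---
title: "Federated consensus clustering for post-stroke severity assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated consensus clustering for post-stroke severity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psafl)
```

## The problem

Clinical staging of post-stroke motor impairment (e.g., with the Fugl-Meyer
upper-extremity score, FMA-UE, 0–66) requires trained assessors and is hard
to scale. Motion recordings from wearable inertial sensors or marker-based
cameras capture the same information implicitly: stroke survivors recruit
compensatory *trunk* movement during upper-limb tasks, and the amount of
trunk displacement grows with impairment severity. `psafl` stages subjects
from such recordings **without labels**, and does so across multiple
rehabilitation sites **without pooling raw data**: each site shares only
cluster centroids and summary statistics with a server (horizontal federated
learning).

The pipeline has five stages:

1. **Preprocessing** — zero-phase Butterworth low-pass filtering of each 3D
   position series, optional double differentiation into acceleration, and a
   frequency-domain feature vector per subject.
2. **Base ensemble** — eight clustering methods (fuzzy c-means, k-means,
   SOM, Gaussian mixtures, DBSCAN, hierarchical, spectral, OPTICS) under one
   contract.
3. **Consensus** — a co-association matrix over the ensemble, factorized by
   symmetric nonnegative matrix tri-factorization (MNMF) into consensus
   labels and local centroids.
4. **Severity ranking** — clusters ordered by mean trunk displacement;
   lowest displacement = mildest.
5. **Federation** — FedAvg aggregation of severity-aligned local centroids
   into a global model that labels every subject.

## The consensus model

Each base method $t$ yields a partition; its *connectivity matrix* is
$\mathrm{CM}_{ij}(b_t) = 1$ if subjects $i,j$ share a cluster, else $0$. The
*consensus matrix* is the element-wise mean over the $T$ partitions, so
$\mathrm{CM}_{ij}$ is the co-clustering frequency — entries in $[0,1]$, unit
diagonal. (The combination rule is a design choice; the element-wise mean is
the classic evidence-accumulation co-association rule and matches the
interpretation of the matrix as an agreement level.)

MNMF factorizes $\mathrm{CM} \approx N L N^{\top}$ with $N \in
\mathbb{R}^{n\times k}_{\ge 0}$ (cluster assignment) and $L \in
\mathbb{R}^{k\times k}_{\ge 0}$ (cluster interaction), minimising
$\lVert \mathrm{CM} - N L N^{\top} \rVert_F^2$ by alternating multiplicative
updates

$$N_{oi} \leftarrow N_{oi}\,
  \frac{(\mathrm{CM}\, N L)_{oi}}{(N N^{\top} \mathrm{CM}\, N L)_{oi} + \varepsilon},
  \qquad
  L_{ie} \leftarrow L_{ie}\,
  \frac{(N^{\top} \mathrm{CM}\, N)_{ie}}{(N^{\top}N\, L\, N^{\top}N)_{ie} + \varepsilon},$$

with the $L$ update applied after (and using) the updated $N$. Hard labels
are the row argmax of $N$ (ties to the lowest index). An orthogonality
condition $N^{\top}N = I$ is associated with the ideal indicator structure
of $N$; it is treated as *soft* here — the denominators already penalise
overlapping columns — and $\lVert N^{\top}N - I\rVert_F$ is reported as a
diagnostic instead of being enforced by projection, which would change the
update rules.

### Monotonicity safeguard

The plain ratio updates above carry **no descent guarantee** (the provably
monotone variant of symmetric tri-factorization applies a square root to the
update ratio). Empirically they descend almost always, but can enter small
limit cycles near a stationary point (relative objective oscillations around
$10^{-6}$–$10^{-5}$). `mnmfFit()` therefore accepts an iteration only if it
decreases the objective by at least `tol` (relative); an iteration that
fails to do so is rejected — the factors revert — and the run stops. The
recorded objective trace is consequently non-increasing by construction,
and the stopping rule doubles as the convergence criterion. This is an
algorithmic safeguard chosen at design time, not a post-hoc patch: it keeps
the update formulas exactly as stated while restoring the monotone-descent
property expected of an NMF fit.

### Restarts, empty clusters, degenerate input

* `n_restarts = 100` seeded restarts (restart $r$ uses `seed + r − 1`), the
  restart with the lowest final objective wins, and all restart objectives
  are retained so dispersion can be inspected. The default follows the
  repeated-run protocol used to tame clustering variance.
* $N$ is initialised from a seeded k-means partition of the consensus-matrix
  rows (indicator + 0.2, so strictly positive — multiplicative updates
  cannot escape exact zeros); $L = (N^\top \mathrm{CM} N)$ normalised by the
  outer product of $N$'s column sums. If the consensus matrix has fewer than
  $k$ distinct row patterns, k-means cannot start and a seeded balanced
  random assignment is used instead.
* Empty clusters after the argmax are repaired by donating the points with
  the weakest assignment margin (smallest gap between their top two $N$
  entries), never emptying another cluster.
* $\varepsilon = 10^{-10}$ stabilises denominators; `tol = 10^{-6}`
  (relative) and `max_iter = 500` bound each restart.

## Preprocessing choices

* **Filtering.** Second-order Butterworth low-pass, 10 Hz cutoff for 60 Hz
  wearable data (20 Hz for 200 Hz camera data), applied forward–backward so
  movement events suffer no phase lag; the effective attenuation is the
  single-pass response squared. The input is extended by odd reflection at
  both ends (about `6 fs / cutoff` samples) and trimmed after filtering:
  zero-initialised recursive filtering would otherwise leave a large
  artifact at the series end.
* **Acceleration.** Central second differences,
  $a_t = (p_{t+1} - 2p_t + p_{t-1})\,f_s^2$, exact for quadratics; endpoints
  use the one-sided second difference of the three nearest samples so the
  output stays aligned with the time base.
* **Trunk displacement.** Per-axis baseline = mean of the first 10 samples;
  for each later step $\mathrm{TD} = \mathrm{TD}_x + \mathrm{TD}_y +
  \mathrm{TD}_z$ with **absolute** per-axis deviations. Signed deviations
  could cancel across axes and invert the severity ordering; the absolute
  convention makes TD a nonnegative compensation magnitude. With several
  trunk markers, per-step TD is averaged across markers. TD is translation
  invariant by construction.
* **Features.** Magnitude of the real DFT per filtered channel-axis series,
  amplitude-scaled ($|X_j|/n$, doubled off-DC, so a sinusoid of amplitude
  $A$ contributes $A$ at its bin), first `n_bins` bins kept (default 8),
  averaged across each subject's tasks and repetitions, one row per subject
  in sorted order. `n_bins` must cover the movement band: the bin of a
  frequency $f$ is $1 + f \cdot \mathrm{duration}$, so keeping too few bins
  silently discards the discriminating signal.
* **Column normalisation.** Default is **centering only**. All features are
  spectral magnitudes in one physical unit; scaling every column to unit
  variance would amplify noise-floor bins to the same weight as
  movement-band bins and bury the severity signal (on synthetic cohorts this
  single choice moves group recovery from ~0.67 to 1.0). `scale = "zscore"`
  is available for heterogeneous imports, with zero-variance columns
  centered to 0; `scale = "none"` disables normalisation.
* **Pooling level.** Features are pooled per *subject* (averaged over tasks
  and repetitions), since severity is a subject-level attribute; per-trial
  clustering would let the ensemble split on task identity instead.

## Base ensemble choices

All eight methods run under one contract: `runMethod(features, spec, k)`
returns labels in `1..k`, deterministic for a fixed seed, with hyper
parameters shared across sites via a single configuration. Specifics:

* fuzzy c-means is hardened by maximal membership (ties to the lowest
  index); the SOM is a $1 \times k$ map whose units are the clusters; the
  GMM defaults to the diagonal-covariance model family (appropriate for
  spectra, and stable when $d$ approaches $n$); spectral clustering uses a
  deterministic RBF width $\sigma = 1/(2\,\mathrm{med}^2)$ from the median
  pairwise distance (the automatic width search is fragile on small sites).
* DBSCAN and OPTICS take no $k$. Defaults `minPts = 5` and a deterministic
  radius (median distance to the `minPts − 1`-th neighbour) are used when
  none are given; noise points are reassigned to the nearest non-noise
  centroid; if more than $k$ clusters emerge their centroids are Ward-merged
  down to $k$; if fewer, the partition enters the consensus as-is (the
  co-association average tolerates heterogeneous cluster counts). These
  harmonisation rules are an explicit artifact decision — no published rule
  exists for folding density methods into a $k$-cluster consensus.
* `exhaustiveSearch()` scores every non-empty subset of the pool (at most
  $2^8 - 1 = 255$), by default with an internal stability objective (mean
  adjusted Rand index between the consensus labels and each member
  partition) and optionally against supplied reference labels; ties break to
  the smaller subset, then lexicographically.

## Federation choices

* **Alignment before averaging.** FedAvg of centroids is meaningless while
  cluster indices are arbitrary per site. Clusters are aligned by
  *severity rank*: each client orders its clusters by ascending mean trunk
  displacement (rank 1 = mildest, ties to the lower index), and rank $r$
  everywhere maps to global cluster $r$. This uses only quantities a client
  already shares (centroids and their displacement summaries) and no raw
  data.
* **Weights.** The global center is the client-size-weighted mean
  $W_r = \sum_c (n_c / N)\, X^{(c)}_r$; weights sum to 1 over participating
  clients. Aggregation iterates clients in a canonical (id-sorted) order so
  the result is exactly invariant to arrival order.
* **One round.** Local pipelines are pure functions of their inputs; a
  single FedAvg pass over the final local centers is performed (no iterative
  training rounds). A one-client federation is bit-identical to the
  centralized pipeline under the same seeds — `partitionClients()` keeps
  each client's subjects sorted precisely so this degenerate case is exact.
* **Timing.** CompT is the maximum per-client wall time (clients run
  conceptually in parallel; serial execution is an equivalent fallback given
  purity), CmT is the aggregation time, and the total is their sum.

## Severity labeling and evaluation

The cluster with the lowest mean trunk displacement is the mildest level,
the highest the most severe. Reference categories come from FMA-UE scores:
below 29 is severe (the clinically anchored boundary); for three levels the
moderate/mild cut defaults to 43, which is an *assumption* exposed as a
parameter. Both boundaries are half-open (a score exactly at the cut falls
into the milder category).

Metrics are support-weighted: per-class precision, recall and F (harmonic
mean) are combined with class-frequency weights, which makes weighted recall
identical to accuracy — the same identity visible in published evaluations
of this design. Never-predicted classes contribute precision 0.

## The synthetic cohort generator

`generateCohort()` emulates the study conditions so the whole pipeline is
testable without external recordings: 60 Hz sampling, five channels (hand,
shoulder, upper arm, forearm, sternum), four tasks performed three times,
2–3 s repetitions, three severity groups with trunk sinusoid amplitudes
(1, 2, 4) length units and additive Gaussian sensor noise (default sd 0.05).
The group effect lives **only** in the trunk channel amplitude — every other
channel carries task-dependent motion identical across groups — so severity
is recoverable exactly and only through trunk-linked features, matching the
labeling premise. The trunk phase is fixed; at zero noise, trunk
displacement is strictly proportional to the group amplitude, so the
severity ordering is recoverable for 100% of subjects. One global seed
drives a per-subject seed sequence (`seed + subject index`). Reference
FMA-UE scores are drawn per subject from group-specific ranges (severe
strictly below 29; for three groups the 29/43 cuts match `fmaCategory()`'s
defaults, so reference categories recover the generating groups exactly).

What the generator does **not** emulate: biomechanically realistic limb
kinematics, sensor drift and soft-tissue artifacts, marker occlusion,
inter-subject movement-style variability, or any particular distribution of
trunk displacement within clinical severity categories — the
sinusoidal-amplitude model is a stand-in, not a claim about real cohorts.
Passing tests therefore demonstrate that the *pipeline machinery* recovers
planted structure under stated noise, not that the method attains any
particular accuracy on clinical data.

## Problem sizes used by the test suite

The packaged checks run, among others: the multiplicative-update oracle on a
6×6 consensus matrix; objective monotonicity over 50 random symmetric
matrices (n = 30, k = 3); unanimous-ensemble recovery (n = 60, k = 3, 10
seeds); and full-pipeline group recovery over 20 seeds with 300 subjects
(100 per group), 5 clients, k = 3, one task and repetition of 2 s, 4
spectral bins and 10 MNMF restarts — sizes chosen to exercise the stated
properties at meaningful scale while keeping the suite fast. The
`scripts/acceptance.R` run uses the generator defaults (60 subjects, 4 tasks
× 3 repetitions) with 5 clients and the full 100-restart protocol.

## Known limitations

* Severity-rank alignment assumes every site observes all $k$ severity
  levels; a site whose patients span fewer levels will still produce $k$
  clusters and its mislabeled ranks are averaged in.
* $k$ is user input (2 or 3 in practice); no cluster-count selection is
  attempted.
* Federation is simulated in-process. The no-raw-data contract is enforced
  structurally (the server consumes only `ClientSummary` objects), but there
  is no transport, encryption, straggler handling or differential privacy.
* The acceleration formula (second differences) and the spectrum/pooling
  conventions are reasonable standards, stated here explicitly because
  field pipelines vary on them.

## A worked example

```{r example, eval = FALSE}
cohort <- assignReferenceFMA(generateCohort(cohortConfig(seed = 1)))
feats <- frequencyFeatures(cohort, n_bins = 4)
td <- subjectTrunkDisplacement(cohort)
cfg <- federationConfig(n_clients = 5, k = 3, partition_seed = 1,
                        method_seed = 1,
                        mnmf = mnmfConfig(k = 3, n_restarts = 100, seed = 1))
fed <- runFederated(feats, td, cfg)
fed$model
evaluateAgainstFMA(fed$assignments, cohort, k = 3)
bestPermutationAgreement(fed$assignments$cluster,
                         cohortSubjects(cohort)$group)
```
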