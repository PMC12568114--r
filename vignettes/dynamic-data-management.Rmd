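---
title: "Dynamic data management for retraining wearable exercise recommenders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic data management for retraining wearable exercise recommenders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmr)
library(dplyr)
```

## The problem

Recommenders that run against wearable sensor streams degrade as the serving
data drift away from the data they were trained on: users change sports,
fitness levels shift heart-rate profiles, and behaviour evolves season to
season. Periodic retraining on all accumulated history is the safe answer but
scales poorly, and most of the accumulated history is redundant — people
repeat their workouts. `ddmr` implements a dynamic data management (DDM)
strategy for this setting: before each retraining cycle, it consolidates
near-duplicate historical sessions down to representatives, learns which
features currently carry predictive signal, and packages the result as an
immutable, versioned training dataset with full lineage metadata.

The package treats everything as tabular data: a *session table* is a
long-format tibble with one row per timestep (session id, user id, sport,
UTC timestamp, heart rate, speed, altitude, GPS coordinates), and every
pipeline stage takes a data frame first and returns a tibble, so stages
compose with the pipe.

## The reduction model

Each variable-length session is condensed to a fixed-length vector: per
channel (heart rate, speed, altitude) the mean, standard deviation
(population form, divisor $N$ — the session is the whole population of its
own samples), minimum and maximum, concatenated with six derived scalars
(duration, total distance, peak and mean heart rate, recovery speed,
exercise intensity). After removing sports with too little support, the
summary matrix is standardized column-wise and projected onto its leading
principal components. Redundancy is then defined *within a (user, sport)
group*: two sessions are redundant when the cosine similarity of their
embedded summaries reaches a threshold $\tau$. Candidate pairs come from an
approximate nearest-neighbour index (random-projection trees over the
angular metric); every candidate similarity is recomputed exactly before
thresholding, so $\tau$ has exact semantics and the approximation can only
miss pairs, never invent them. Pairs at or above $\tau$ form a graph, and
each connected component keeps exactly one representative: the session with
the most recorded timesteps, ties broken by earliest start. Connected-
component consolidation (rather than greedy sequential merging) makes the
result independent of processing order.

Restricting similarity to within-user, within-sport groups is deliberate:
consolidating across users would erase exactly the per-user behavioural
distributions the recommender needs, and the sport filter runs first so that
heterogeneous channel profiles (running versus rowing heart-rate envelopes)
do not meet in one embedding cloud. Every user keeps at least one session by
construction, since each component elects a representative.

### Tunables

| Parameter | Default | Meaning |
|---|---|---|
| `similarity_threshold` | 0.99 | cosine $\tau$; lower removes more |
| `pca_components` | 5 | embedding dimension (or `variance_target`, e.g. 0.98) |
| `min_sessions_per_sport` | 0 | sport-support filter |
| `ann_trees` | 10 | trees in the approximate index |
| `ann_search_k` | 100 | candidates gathered per query |

The defaults are the operating point used throughout the package's own
experiments: $\tau = 0.99$ removes only near-identical sessions; five
components retain the bulk of the summary variance on the synthetic cohorts;
and the (10, 100) index configuration reaches ~99% neighbour recall against
brute-force search while inspecting a tenth of the data per query
(`scripts/acceptance.R` recomputes this). `run_threshold_sweep()` exposes the
$\tau$ trade-off curve directly.

### The approximate index

No Annoy binding is available in R, and the index's behaviour (recall as a
function of trees and `search_k`) is part of what this package studies, so
the forest is implemented here: vectors are L2-normalized; each tree splits
recursively by a hyperplane obtained from a short two-means refinement of a
random point pair, thresholded at the median projection so trees stay
balanced; queries walk all trees with a single priority queue ordered by
hyperplane margin until `search_k` distinct candidates are gathered. Exact
cosine rescoring orders the candidates. Zero vectors are excluded at
indexing time with a warning, since cosine similarity is undefined for them.

## The feature-weight controller

Features are partitioned into four groups — attribute (e.g. sport),
contextual (duration, distance, intensity), health metrics (heart-rate
statistics, recovery speed) and sequential (per-user session order
statistics). A two-layer perceptron with ReLU activation and dropout 0.2 on
the hidden layer maps a latent vector $z$ to one sigmoid-bounded weight
$a_{nm} \in [0,1]$ per feature. $z$ is defined here as the per-batch mean of
the standardized, encoded feature columns — a cheap summary of where the
current data sit; the definition is localized in `fit_bilevel()` and easy to
swap.

Fitting is bi-level: the inner loop fits a downstream model (a linear
heart-rate regressor on the weighted features) by gradient descent on the
training split; the outer loop updates the controller by the first-order
gradient of the *validation* loss with respect to the weights, holding the
inner coefficients fixed. First-order rather than fully unrolled
differentiation is the usual desk-scale approximation in this AutoML
lineage; it is cheaper by an order of magnitude and recovers planted
informative features reliably (the test suite checks 10 seeded simulations).
Weights multiply features during fitting — hard selection happens only in
`select_important_features()`, which ranks deterministically with ties
broken by schema order. Dropout is active only during fitting; evaluation
passes are deterministic.

Two points the interface leaves open, and the defaults chosen: weights are
per-feature (with group bookkeeping), not per-(user, feature); and the
downstream model inside the bi-level loop is the heart-rate predictor
rather than the recommender, because its loss is dense, smooth and fast to
differentiate, while the ranking objective is piecewise-constant.

## Packaging and versioning

`package_data_version()` concatenates the reduced old sessions with the new
ones (session ids must be disjoint), attaches the session-level feature
table, and applies the weight policy: features below `weight_floor`
(default 0.1) are dropped from the version's feature schema, with all
weights recorded in the metadata regardless, so the decision is reversible;
an alternative mode scales numeric features by their weights instead.
Column-dropping (not row-dropping) is the natural reading of per-feature
weights. Versions are stored one directory each — records and features as
CSV, metadata as JSON — which keeps the store diff-able and database-free.
`read_version()` verifies that recorded counts match the records, and
`version_lineage()` walks parents back to the root, refusing cycles.

## Models and the evaluation protocol

Two deliberately small learners stand in for the production models:

* a single-layer recurrent regressor (tanh cell, linear head, full-batch
  backpropagation through time) that predicts the next heart-rate sample
  from a sliding window of standardized channels; its per-session mean
  prediction is the contextual feature fed to the recommender, and warm
  starts resume from a donor model's parameters — the retraining path;
* a neural collaborative-filtering recommender: user and item embedding
  tables (dimension 16) plus a one-hidden-layer perceptron over
  (user, item, context), trained with binary cross-entropy on positives and
  uniformly sampled negatives.

The evaluation protocol is fixed: interactions (one positive per session,
item = sport) are split chronologically 80/10/10 with floor sizes and the
remainder to train, so no test interaction predates a training one; each
training positive is paired with 4 negatives sampled uniformly from the
whole catalog (deliberately not positive-excluding — uniform means uniform,
and an option flag enables exclusion); ranking metrics use $K = 10$ against
the set of items the user actually consumed in the test block. Predicted
heart rate enters the recommender only as a context feature; the module
boundary keeps the recommender's task recommendation, not heart-rate
regression. Unknown users at inference raise a cold-start error rather than
backing off silently, so protocol violations surface in tests.

Metrics are the standard ones: MAE and RMSE for prediction; Recall@K,
Precision@K (denominator = items returned, i.e. $K$ unless the catalog is
smaller), F1 (harmonic mean, 0 when both components are 0) and NDCG@K with
binary relevance, where DCG gains are $(2^{rel_i}-1)/\log_2(i+1)$ and an
empty ideal list yields NDCG 0 by convention. Empty ground truth makes
recall undefined and is an error: per-user evaluation runs over users with
test items.

## The staged retraining experiment

`plan_stages()` slices the cohort chronologically 55% / 15% / 15% / 15%;
stage $N$'s old data is the union of all earlier slices, i.e. data
accumulate raw between stages ($old_{N+1} = old_N + new_N$) and reduction at
each stage re-reduces the cumulative raw history rather than compounding on
the previous reduced set. Three strategies are compared under identical
seeds: retraining from scratch on everything; *simple data merging*, which
subsamples old sessions uniformly at random down to exactly the DDM-reduced
count (so any quality difference is attributable to *which* sessions are
kept, not how many); and the full DDM path. The orchestration is an
in-process sequential runner — the production counterpart would be a
workflow DAG, but that is deployment, not method. Elapsed retraining time is
recorded for bookkeeping and never asserted, since it is hardware-bound.

## What the synthetic generator does and does not emulate

`generate_cohort()` produces cohorts with: per-user heart-rate baselines and
per-sport exertion envelopes (baseline + ramp + recovery tail + Gaussian
jitter), piecewise-constant speed per sport, altitude as a slow random walk,
GPS integrated from speed along a wandering heading, sessions scattered over
a simulated 180-day calendar, and — the key lever — planted near-duplicates:
exactly `round(duplicate_rate * n_sessions)` sessions are full copies of a
same-user session with per-channel jitter of `noise_scale` times the
channel's spread, flagged in a provenance column (written to a sidecar file
so the main schema matches real logs). This gives reduction a known ground
truth: each planting adds exactly one redundant session, so the expected
removal rate equals the duplicate rate. `inject_drift()` adds change-point
drift: additive channel-mean shifts and optional sport-preference
relabelling after an onset fraction of the timeline (labels only — channels
are not re-simulated for the new sport, a documented simplification).

What it does not emulate: realistic marginal distributions of any particular
wearable dataset, sensor dropout and GPS noise artefacts, dozens of sport
types, or seasonal periodicity. Passing tests therefore demonstrate that the
machinery is correct and that the method recovers planted structure under
controlled redundancy and drift — not that any particular accuracy level
transfers to a specific real dataset.

## Numerical choices and degenerate inputs

Constant summary columns are dropped before PCA (a message says which); an
all-constant matrix is an error. Standard deviations used for scaling are
floored at $10^{-8}$. The recovery-speed feature is defined as
(peak − final heart rate)/(time from peak to end), 0 when the peak falls on
the final sample; near-plateau sessions make the peak position, and hence
this feature, sensitive to jitter — visible in tests as occasional planted
duplicates whose summary similarity dips below $\tau$, and absorbed by the
±3-point tolerance on the recovery check. Sessions with a single timestep
have undefined duration and are rejected. Cleaning drops sessions with any
missing channel value whole rather than imputing: for redundancy analysis a
partially observed session is better absent than fabricated. Tie-breaks are
specified everywhere a ranking could be ambiguous (record count then start
time then id for representatives; score then catalog order for
recommendations; weight then schema order for feature selection), which is
what makes end-to-end runs reproducible bit-for-bit under a fixed seed.

## Problem sizes

The test suite and the acceptance script run on cohorts of 40–1,000 sessions
(5–50 users), chosen so the full suite completes in a few minutes while
every property — oracle equivalence on ≤ 50 sessions, neighbour recall on
1,000 embeddings, four-stage experiments over three seeds — is exercised on
sizes where its failure modes can actually appear.

## Limitations

The learners are stand-ins sized for verification, not production accuracy;
reduction operates in batch, not streaming; cross-user deduplication and
learned similarity metrics are out of scope; and the bi-level controller
uses a first-order approximation whose fixed points can differ from the
fully unrolled objective's. The similarity threshold is global — per-sport
thresholds would be a natural extension, and `per_sport_pca` in
`reduction_config()` already allows fitting the embedding per sport.
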