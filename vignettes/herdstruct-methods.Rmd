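---
title: "Inferring multilevel social structure from collective movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring multilevel social structure from collective movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Harem-living equids such as Przewalski's horses organise into a nested
("multilevel") society: an adult female and her pre-dispersal offspring form
a *family*; families and unrelated females gather around a single breeding
stallion in a *harem*; and the harems, together with bachelor-male groups,
travel as one cohesive *herd*. `herdstruct` asks how much of this structure
can be read directly from fine-scale movement — time-stamped planar
positions of every animal while the herd is on the move — and how the
movement-derived structure relates to two decades of demographic monitoring
(pedigree, harem-membership records).

The package has three ingredients:

1. **Dyadic movement variables.** For every pair of individuals in a
   recording session, the mean pairwise distance and the *movement
   similarity* — the delayed directional correlation of their unit heading
   vectors, maximised over a grid of time delays. Both are averaged over
   sessions recorded on different days.
2. **Structure detection.** The distribution of session-averaged pairwise
   distances is strongly bimodal in a multilevel herd (a harem mode and a
   herd mode); single-linkage clustering cut at the valley between the modes
   classifies individuals into harems from movement alone. Thresholding the
   same distances yields a two-layer proximity network (harems;
   individuals within harems) on which hop distances and closeness
   centrality are computed.
3. **Demography joins and inference.** Pedigree kinship classes, shared
   harem days before/after the observations (familiarity), female transfer
   counts, Jaccard-linked harem lineages and stallion harem-keeping
   experience are joined to the dyadic movement table, and hypotheses are
   tested with seeded one-sided randomisation tests.

The real monitoring data for this kind of study are access-restricted, so
the package ships a synthetic herd and population generator with complete
ground truth; every claim the package makes about its own correctness is a
property of that generator plus small hand-built cases and brute-force
oracles.

# Movement variables

## Smoothing and headings

Raw tracks carry ~0.2 m positional noise, which central-difference
velocities would amplify. Positions are therefore convolved, per coordinate,
with a Gaussian kernel of standard deviation `sigma = 1.2` s, truncated at
4 sigma and renormalised over the available observation mask. The
renormalisation means constants are preserved exactly, also at session edges
and across tracking gaps; a pure sinusoid is attenuated by the usual
Gaussian transfer factor `exp(-2 pi^2 f^2 sigma^2)` (checked in the tests at
f = 0.1 Hz). Tracks shorter than the kernel support are returned unsmoothed
with a warning rather than smoothed with a mostly-missing window.

Velocities are estimated by central differences on the smoothed positions;
the heading is the unit velocity wherever speed is at least `min_speed`.
The threshold default is 0.05 m/s: herd travel speed in the regime the
package targets is around 0.85 m/s, so this only removes near-stationary
stretches where direction is undefined. Headings at frames lacking either
neighbour are invalid.

## Delayed directional correlation

For a dyad (i, j) and delay tau on a grid of 1-frame steps in
[-`tau_max`, `tau_max`] (default 16 s, i.e. 0.08 s resolution at 12.5
positions/s),

    C_ij(tau) = mean over valid overlapping frames t of
                dot(heading_i(t), heading_j(t + tau))

with both endpoints required to lie inside the session (no padding). The
movement similarity `c_5min` is the maximum over the grid and `best_delay_s`
its argmax; a positive delay means j's headings match i's earlier ones, i.e.
j follows i. Numerical choices:

* **Tie-breaking.** Ties in the maximum go to the smallest `|tau|`, then to
  the negative delay — a deterministic rule that matters only for
  constructed inputs (e.g. constant headings).
* **Minimum overlap.** A delay competes only if at least `min_overlap`
  (default 25 frames = 2 s) valid overlapping frames support it; a dyad
  with no qualifying delay has `c_5min` absent. Counting the overlap per
  delay, rather than once per dyad, avoids maxima estimated from a handful
  of frames at extreme delays.
* **Negative maxima are omitted** (set absent) at session level, before any
  cross-session averaging, so `c_5min` lives in [0, 1] where present.

Session averaging is unweighted over the sessions where a dyad is present,
separately for distance and similarity (a dyad can contribute a distance but
no similarity in a session). Unidentified bachelor tracks cannot be matched
across days and are excluded from averaged metrics; they remain in
session-level metrics, which is all the bachelor analyses use.

# Structure detection

## Distance distribution, peaks, valley

The dyadic distance sample is summarised by a Gaussian kernel density
(4096 grid points, tails cut at 8 bandwidths, curve renormalised to unit
mass on its grid). Two non-obvious choices:

* **Bandwidth.** The default is the Sheather–Jones plug-in rather than
  Silverman's rule of thumb. The sample mixes a ~15 m harem mode with a
  herd mode spread over hundreds of metres; a global rule-of-thumb
  bandwidth (~20 m on study-scale data) is driven by the herd spread and
  can smooth the harem mode away entirely. Sheather–Jones adapts to the
  narrow mode and resolves both. The bandwidth remains a user parameter.
* **Peaks by prominence.** Raw local maxima above 5% of the density maximum
  are merged by topographic prominence: two maxima are distinct peaks only
  if the density between them dips below 0.15 times the lower of the two.
  The herd-level mode of a many-harem herd is a sum of hundreds of
  harem-pair distance clumps and inevitably carries shallow ripples;
  prominence merging reports it as the single mode it is, while the
  harem/herd pair — separated by a near-empty gap — always stays distinct.
  The 0.15 default was set during method development by inspecting dip
  ratios on generated herds: the harem/herd dip sits below ~0.2 of the
  harem peak while within-mode ripples dip only to ~0.5–0.95 of their
  flanking bumps.
* **Valley.** The cut between social levels is the density minimum between
  the *first* (lowest-distance) peak and the highest peak beyond it. On a
  clean two-peak density this is identical to "between the two highest
  peaks", but it stays correct when a minor far-distance mode survives
  peak detection.

## Movement-only classification

`classifySubunits()` runs single-linkage agglomerative clustering on the
averaged distances and cuts the dendrogram at the valley (or a user cut).
Single linkage is chosen deliberately: cutting it at c is exactly the
connected components of the graph joining dyads closer than c — the same
construction as the proximity networks, so the classification and the
network layer are two views of one rule (the equivalence is asserted in the
tests). Dyads with no measured distance are parked beyond any plausible cut
rather than imputed. If the density has no valley the function stops and
asks for a manual cut — on unimodal data a movement-only classification is
not defensible.

## Proximity networks

The harem gap matrix takes the *minimum* averaged distance over cross-harem
member dyads ("distance between any of their members"). The network
threshold is chosen by the single-connected-component rule: the smallest
threshold at which the harem graph is connected, computed exactly as the
maximum edge of a minimum spanning tree of the gap graph. Edges use
`distance <= threshold`: under a strict inequality the smallest connecting
threshold would be an unattained infimum, while with `<=` the MST max edge
is the exact answer. Within-harem thresholds are computed per harem over its
members' distances, excluding individuals that changed harem during the
observation period (they are kept as nodes). Network distance is the
unweighted hop count; closeness is the reachable-set form,
`(number of reachable nodes) / (sum of hop distances to them)`, with 0 for
an isolated node. The `thresholdRobustness()` report rebuilds the network at
±10% of the threshold and gives Spearman rank correlations of closeness
against the base network; a disconnected lower variant is reported, not an
error.

# Demography

* **Kinship classes** from parent links, in precedence order:
  parent-offspring (restricted to mother–daughter), full sibling, maternal
  half sibling, paternal half sibling, distant. Unknown parents never
  match. Mother–son and father–child links therefore fall through to the
  sibling/distant logic — the female-dyad analyses this classification
  serves never need them.
* **Familiarity** (`t_past`, `t_future`) is the number of days a dyad spent
  in the same harem inside a two-year window before/after the observation
  date, summed over all common harems. Membership intervals are half-open
  `[start, end)` and piecewise-constant between records (monitoring is
  monthly; nothing finer is knowable). Stallion familiarity `t_past*`
  restricts the count to spells where both held the subadult role.
* **Transfers** compare each adult female's harem at the two window
  endpoints; a move adds one count to the unordered harem pair, and moves
  out of the natal harem (first breeding dispersal) are excluded. Endpoint
  comparison collapses multi-step moves within the window into one pair —
  a documented limitation; an event-scan variant is available via
  `method = "events"`.
* **Lineage.** Yearly adult snapshots (adult females and the stallion,
  taken at 1 September) are linked by the Jaccard rule: the ancestor of a
  harem in year i is the year i-1 harem with maximal Jaccard index over
  adult members, requiring at least two common adults. If several year-i
  harems claim one ancestor, the claimant with the most common adults wins;
  at equal common size the oldest lineage (earliest start, then
  lexicographic id — a determinism tie-break) wins and the losers start new
  lineages. Harem age is counted from the lineage start date in whole
  years; ages and stallion experience use 365.25-day years.

# Randomisation tests

Three schemes — pooled two-sample mean difference, paired sign flips, and
y-permutation Pearson correlation — plus a roster-reassignment scheme for
the sibling-cohabitation statistic (adult females reshuffled across harems
preserving per-harem counts). All are one-sided with 10,000 iterations by
default and a user seed (the session RNG state is saved and restored).
P-values use the add-one rule `p = (1 + #{null at least as extreme}) /
(1 + n_iter)`, so p is never 0 and ties count as extreme (conservative).
Monte-Carlo p converges to the exhaustive-enumeration p on instances small
enough to enumerate; the tests assert agreement within three binomial
standard errors. Under continuous-data nulls the p-values of the three
schemes are uniform; the roster statistic is a small count, so its p is
discrete and is checked for validity (null rejection rate at most alpha)
rather than KS-uniformity.

Subset rules for the demography-linked comparisons follow the monitoring
design: kinship effects are tested on dyads with no shared past membership
(`t_past = 0`), familiarity effects exclude close kin, and female-kinship
harem comparisons require zero between-harem female familiarity.

# The synthetic generator

`simulateHerd()` builds sessions from nested smooth mean-reverting walks:
a herd centroid travelling at 0.85 m/s with a slowly turning heading; harem
anchors wobbling around static home offsets; members wobbling around their
anchors; offspring around their mothers; bachelors around peripheral homes.
All wobbles are critically damped second-order processes, so offset paths
are differentiable and headings remain meaningful; the within-harem shared
anchor velocity is what makes movement similarity decay from family to
harem to herd.

The layout is a dense core — homes uniform in a disk, pair-repaired to a
minimum separation of 0.75 × the inter-harem scale, redrawn until the core
MST max edge is at most the scale — plus ~13% small peripheral "straggler"
harems attached at 1.15–1.55 × the scale and mutually at least 1.8 × the
scale apart. The stragglers set the critical network threshold while the
core stays connected at 90% of it, reproducing the qualitative regime in
which threshold robustness holds; their small size keeps the mass at far
straggler–straggler distances small, so the distance density is genuinely
two-peaked in the large majority of seeds (occasionally a far clump of
straggler-involved dyads survives peak detection as a minor third mode). Default scales (family 5 m, harem 15 m, herd
120 m), population sizes (31 harems, 238 identified individuals, 40
bachelors), session geometry (five 320-s sessions at 12.5 positions/s) and
travel speed are the study conditions; the cohesion scales are free
constants chosen once to produce a clearly bimodal distance density.

`simulatePopulation()` runs a yearly event cycle — births with within-harem
paternity, deaths, natal dispersal (females at 2–3 years to another harem,
males at 2–4 years to the bachelor pool), adult-female transfers, stallion
takeovers, and occasional harem foundations that split females off a donor
harem — and emits the pedigree, the membership interval records, and the
raw event log. The log is the ground truth: the tests replay it
independently (day scans, endpoint snapshots, tenure replays) and require
exact agreement with the demography functions computed from the interval
records. `herdDemography()` bridges the two generators by fabricating a
pedigree and membership history consistent with a herd layout, with planted
stallion sibling pairs, same-harem female siblings, and cross-harem
familiarity. `plantEffects()` injects alternative hypotheses (closer
sibling-stallion harems, future co-residency) with a manifest of the planted
truth for power analysis.

What the generator does **not** emulate: terrain and water points,
behaviourally realistic locomotion (gaits, leadership dynamics), tracking
dropouts and identification error, observation-day weather effects, or
contraception-driven demography. Passing the recovery properties therefore
shows that the pipeline is correct and well-calibrated on data with the
assumed statistical structure — not that real herds are this clean. In
particular, real inter-harem spacing need not have the exclusive-space
property that makes single-linkage classification exact here.

# Problem sizes used in the checks

The structure-recovery and robustness properties run 20 seeded default
herds (31 harems, 238 individuals, five 320-s sessions each); calibration
uses 3,000 replicate tests per scheme at 999 iterations; the demography
round trip uses a 20-year population (~1,000 individuals). These sizes give
each property enough resolution to fail visibly while keeping the default
test run to a few minutes.

# Known limitations

* Classification uses distances only; movement similarity is computed but
  not used as a clustering feature (it is available to users who want a
  two-feature classifier).
* The full-herd directional correlation (all ~28,000 dyads × 401 delays ×
  4,000 frames) is computationally heavy; `sessionPairMetrics(compute_c =
  FALSE)` gives the distance-only path, which is all the classification and
  network layers need.
* Endpoint transfer counting undercounts multi-step moves inside the
  window (see above).
* The lineage conflict rule is the simple descendant-selection rule stated
  above; losers of a conflict do not fall back to their second-best
  ancestor.
* Closeness of a two-node component is 1.0 by the reachable-set formula —
  highest possible — which makes rank-based robustness comparisons fragile
  if a network fragments into small non-singleton components.
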