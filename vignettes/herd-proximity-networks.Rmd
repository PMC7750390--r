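---
title: "Proximity interaction networks for housed dairy herds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity interaction networks for housed dairy herds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

herdprox analyses the social structure of a permanently housed dairy herd
from indoor positioning data. The pipeline has five stages — simulate (or
load), clean, detect, build networks, infer — and this vignette explains
the model behind each stage, the parameters that matter, and the design
choices made where more than one reasonable construction existed.

## The scientific setting

A herd of cows wears collar-mounted local-positioning sensors that emit a
planar fix per animal every 10 s (0.1 Hz). From these trajectories we ask:
do particular pairs of cows (dyads) spend sustained time near one another,
is that structure stable over days, and does it align with individual
attributes such as lameness, parity, or days in milk (DIM)? The unit of
observation is the *proximity interaction*: a dyad remaining within radius
`r` for duration `t`. Daily counts of these interactions per dyad form
symmetric weighted networks, one per day and per functional barn zone
(feeding passage, non-feeding cubicle area, and the full barn).

## Sustained-proximity detection

A candidate window is `window_points` consecutive samples whose timestamps
are exactly one sample interval apart; missing samples break contiguity
rather than being interpolated. Under the strict protocol every distance
in the window must lie within `r` (inclusive: ties at exactly `r` count,
a measure-zero event on real data); the lenient variant requires only a
fraction `f` of in-radius samples, and strict is identical to lenient with
`f = 1`. Defaults follow the field protocol: `r = 3` m, `t = 60` s, and
`window_points = round(t / sample_interval) = 6` samples at 0.1 Hz. Six
samples technically span 50 s of elapsed time; we follow the sample-count
reading of the protocol, which is the stated equivalence.

How overlapping qualifying windows are counted is genuinely open. Two
conventions are implemented:

* **tumbling** (default): scan left to right, count a qualifying window,
  then advance a full window past it. Daily counts are then proportional
  to sustained contact time, which is the natural reading of "number of
  interactions per day".
* **sliding**: count every qualifying window. This variant is used by the
  monotonicity invariants in the test suite (sliding counts are
  non-decreasing in `r` and non-increasing in `window_points`).

Neither convention is asserted to be the one used in any particular field
study; results in the package are tumbling unless stated.

Zone attribution filters positions into each zone's rectangle dilated by a
3 m buffer *before* pairing and detection, so an interaction is credited
to a zone exactly when both animals' samples in the window survive that
zone's buffered filter. Because of the buffers and of boundary-crossing
windows, per-zone counts need not sum to full-barn counts; with zero
buffer and sliding windows, zone counts are provably bounded by full-barn
counts, which the suite checks.

## Trajectory cleaning

Four stages run in a fixed order, each reporting the fraction of the
*original* records it removed:

1. **Region filter** (buffer 3 m): drops fixes further than the buffer
   outside the barn rectangle — erroneous far-out fixes and, when the
   generator emits them, parlor-located records during milking.
2. **Stuck-run removal** (`min_run = 12` samples, `eps_m = 0.05` m): a
   sensor that repeats essentially the same coordinate for two minutes or
   more is treated as stuck. The thresholds are package choices: genuine
   lying bouts keep sensor noise far above 5 cm, so they are untouched,
   while reset artifacts repeat coordinates exactly. A run is anchored at
   its first point (every member within `eps_m` of the anchor), found by a
   scan that the suite validates against a brute-force oracle.
3. **Moving-average smoothing** (window 15 samples = 150 s): an
   unweighted centred mean per coordinate. The half-window of 7 records at
   each end of a contiguous segment lacks a full window and is dropped;
   segments shorter than the window are dropped whole. Smoothing operates
   per contiguous same-day segment — any time gap larger than one sample
   interval (milking absences, removed stuck runs) breaks a segment — so
   absences never smear positions across gaps.
4. **Stationary-day removal** (extent 5 m over ≥ 90% of records): a
   cow-day is dropped whole when at least the span fraction of its records
   lie within half the extent threshold of the day's componentwise median
   point. The originating rule ("relatively stationary for most of a
   day") is qualitative; both thresholds are exposed and the defaults are
   package choices. A manual-inspection step used in field workflows is
   not reproducible and is deliberately not emulated.

No stage alters a retained record's animal id or timestamp; only
smoothing alters coordinates. Removal fractions are additive by
construction and the pipeline total equals `1 - retained/original`
exactly.

## Permutation inference

All tests share one p-value convention: with observed statistic `t_o` and
`q` permuted statistics `t_p`, `p = #(t_p >= t_o) / q`; when that count is
zero the biased estimator adds one to numerator and denominator
(`1/(q+1)`), since an exact zero is impossible with finite permutations.
Bonferroni correction (`min(1, p*m)`) is applied across each battery of
related comparisons. Default `q` is 10,000; the bundled demo
configurations use smaller `q` purely for turnaround, and `q` is recorded
in every report row.

**Social differentiation.** Under the uniform-association null every dyad
shares the day's total interactions equally, `E = total / (n(n-1)/2)`.
The statistic `S` is the mean squared deviation of observed from expected
dyadic counts. The printed ordered-pair form (double sum over `i != j`
divided by `n(n-1)`) equals the unordered dyad sum divided by the dyad
count — the implementation uses the unordered form and the suite checks
the identity numerically. The null distribution redistributes the day's
total over dyads as a multinomial draw, `q` times. Each dyad is also
flagged *differentiated* when its squared deviation exceeds the null's
95th percentile of per-dyad squared deviations (estimated as the mean
across draws of each draw's 95th percentile); the flag is additionally
split by direction, since a dyad interacting *above* expectation is the
"preferred partner" reading. How dyad-level differentiation should be
scored is not fixed by any published formula we follow; this exceedance
construction is an interpretation and is labelled as such.

A caveat established while building the generator: almost any movement
process with sustained bouts is overdispersed relative to the multinomial
null, so `S` rejects for nearly every realistic day — including herds
with no planted preferences. The type-I calibration of the `S` test is
therefore performed where it is well-posed, on matrices drawn from the
multinomial null itself; generator-level type-I calibration is performed
for the assortment and group-comparison tests, whose nulls (attribute
labels independent of behaviour) the no-preference generator does satisfy.

**Group comparisons.** Observed statistics come from the standard R
implementations (`kruskal.test`, `wilcox.test`'s W). The two-tailed
Wilcoxon feeds the absolute centred statistic `|W - n1*n2/2|` into the
one-sided permutation rule, which makes it two-tailed without changing
the p-value convention. The permutation schemes are node-level
randomizations chosen to be non-degenerate for each design:

* *inter-individual* (are some cows consistently more social?): each
  day's totals are permuted across cows independently, preserving the day
  structure while breaking cow identity. Relabelling whole per-cow
  vectors would leave the statistic literally unchanged (the groups are
  the cows), so it cannot serve as a null.
* *between-days*: each cow's totals are permuted across days, preserving
  cow identity while breaking day structure.
* *two-group* (lame vs non-lame on per-cow means of daily interactions,
  degree, or clustering): group labels are shuffled across cows.

Ranks use average-rank tie handling throughout; for label permutations
the pooled ranks are unchanged by the shuffle, so re-ranking per
permutation and rank reuse coincide.

**Matrix correlations.** The Mantel statistic is the Spearman rank
correlation of the two matrices' upper triangles; the null permutes one
matrix's node labels (rows and columns together). Temporal stability
averages daily matrices in consecutive blocks (default four days) and
compares consecutive block networks one-sidedly (positive correlation =
stability). Attribute assortment compares a day's interaction matrix with
an attribute absolute-difference matrix — parity and DIM as printed
absolute differences, lameness coded 1/0 so entries are 0 (same status)
or 1 (mixed) — two-sidedly, since planted preference for similar partners
makes this correlation *negative* and a one-sided (greater) test would
never see it. Cows whose lameness class is unresolved (status changed
twice, or any unscored session) are excluded from the lameness analyses.

**Lameness classification.** Mobility scores 2–3 mark a session lame (L),
0–1 non-lame (NL). All-NL and the dominant-NL patterns (NL-NL-L,
L-NL-NL) classify as non-lame; all-L and dominant-L (L-L-NL, NL-L-L) as
lame; double status changes (NL-L-NL, L-NL-L) and any "NS" session are
excluded. The two-group scheme merges dominant classes into their
respective groups, mirroring the main-analysis convention.

## The synthetic herd generator

No positioning dataset ships with the package; every downstream stage is
exercised against a generator with controllable, known ground truth.

**Affinity.** `plant_affinity()` builds symmetric dyadic preference
weights `A_ij = exp(spread * eps_ij - effect * d_ij)` with standard-normal
`eps` and standardised absolute attribute differences `d`. `spread = 0`
and `effect = 0` gives unit weights — *no* planted structure; `effect > 0`
couples affinity to attribute similarity with controllable strength.

**Movement.** Each cow alternates bouts — resting at a cubicle station,
feeding at the feed face, short loafing excursions — in a semi-Markov
schedule (geometric bout lengths; means 70 min rest, 40 min feed, 10 min
loaf), with AR(1) (Ornstein–Uhlenbeck-style) jitter around the active
station. A shared feeding-pressure template raises the chance of a feed
bout after each milking window (fresh feed delivery and push-ups). When
the affinity matrix carries structure, a classical-MDS embedding of
`-log A` places personal anchors so high-affinity dyads hold nearby
cubicle stations and adjacent feed-face slots, and cows follow their
affinity cluster's shared bout schedule with probability `sync` (default
0.6) — bout-start synchronization. When affinity is structureless, every
bout's station is drawn fresh from the available area, so no persistent
dyadic structure exists for downstream tests to find; station persistence
*is* the planted-preference mechanism, which keeps "no planted structure"
and "exchangeable dyads" the same thing.

Two realism constraints shape the defaults: station areas are packed to a
constant stocking density (about 0.1 cows/m², a crowded commercial barn),
so a 20-cow test herd is as crowded as a 92-cow barn rather than rattling
around an empty one; and the bout means give roughly 3–5 h of feeding per
day, matching typical dairy time budgets (and keeping genuine cow-days
clear of the stationary-day filter).

**Sampling and artifacts.** Days are uniform 10 s ticks with boundaries
at midnight; records during the three daily milking windows (80 min
centred on 05:00, 13:00, 21:00) are absent by default, or emitted at a
parlor location outside the barn on request (the real system recorded
parlor fixes that the region filter later removed). `inject_artifacts()`
then adds isotropic Gaussian noise with CEP50 = 1.90 m — the circular
error probability measured for this sensor class on a standing cow;
the per-axis sigma is `CEP50 / sqrt(2 ln 2)` — plus stuck runs (repeats
of a run's first coordinate) and isolated far-out-of-barn fixes, with
bookkeeping retained so the cleaning stages can be validated.

**Ground truth.** Contact intervals are logged wherever the planted
(noise-free) inter-cow distance is at or below `truth_radius`, broken at
milking gaps, and are exactly reproducible from the emitted noise-free
positions — the suite recomputes them independently. Setting
`truth_radius` below the protocol radius creates a distance margin, under
which every planted contact of length ≥ `t` is provably detectable on
noise-free data; the suite asserts that sensitivity equals 1 there, and
the acceptance script additionally reports the operating sensitivity
after noise injection and cleaning.

**What the generator does not emulate.** Biomechanics and gait, 3-D
posture, accelerometer channels, real barn furniture (cubicle rows,
passage widths), displacement/dominance interactions, and cows entering
or leaving the herd. Passing tests therefore demonstrate that the
*pipeline* recovers planted statistical structure under realistic noise —
not that any particular biological claim holds in real herds.

## Numerical choices and degenerate inputs

* Distance thresholds are inclusive; timestamp contiguity uses a 1e-9 s
  tolerance; unsorted or duplicate timestamps are rejected, never sorted
  silently.
* A zero-interaction day yields `S = 0, p = 1` with a warning; constant
  matrices make Spearman ranks undefined and Mantel tests error;
  degenerate (all-equal) attributes error in the assortment test.
* Local clustering is defined as 0 for nodes of degree < 2; binary
  measures threshold at one interaction, with no weight cut.
* "Filtering by mean degree" for network drawings is interpreted as
  retaining edges at or above the mean nonzero edge weight; it is a
  visualization aid, never used in inference, and the interpretation is
  flagged as such.
* Seeds: every stochastic stage derives its seed deterministically from
  the master seed; a rerun of `run_all()` with the same configuration is
  byte-identical, which the acceptance suite checks with file hashes.

## Problem sizes in the test and acceptance suites

The statistical suites run at sizes chosen to make their Monte-Carlo
error small while keeping a laptop-scale turnaround: detector-oracle
equivalence on 1000 random series (length ≤ 200); type-I calibration on
200 no-structure herds of 20 cows × 2 two-hour days at 0.1 Hz with
`q = 1000` (day length is irrelevant to permutation calibration, so
short days are used); power and parameter recovery on 100 herds with
`spread = 0.8, effect = 2.5` — a coupling calibrated once, by simulation,
to give a median planted assortment magnitude ≥ 0.3; and the determinism
check on a 30-cow × 3-full-day demo. The acceptance script runs a 25-cow
× 4-day herd with default artifact rates and `q = 1000`.

## Known limitations

The bout model is a stand-in: its parameters are plausible for housed
dairy cattle but are not estimates from any herd, and distributional
details of real within-day movement (heavy-tailed bout lengths, social
displacement at the feed face) are not modelled. The multinomial null for
`S` ignores daily activity budgets, so `S` p-values on realistic data
measure departure from uniform association, not from a realistic
movement null. Mantel tests inherit the usual caveat that node
permutation addresses exchangeability of identities, not autocorrelation
within matrices. The per-dyad differentiation flag is an interpretation,
as noted above.
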