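# herdprox

Proximity interaction networks for permanently housed dairy herds.

Indoor local-positioning systems can record the planar position of every
cow in a barn at 0.1 Hz for weeks. `herdprox` turns such trajectories into
social networks and inference about herd structure: who spends sustained
time near whom, whether that structure is stable across days, and whether
it aligns with individual attributes (lameness, parity, days in milk).
It is aimed at researchers in precision livestock farming and animal
social network analysis who need a tested, reproducible pipeline — and a
synthetic herd generator with known ground truth to validate it against,
since positioning datasets of this kind are rarely public.

## What it computes

A **proximity interaction** for a dyad (pair of cows) is a window of
`w = round(t / Δ)` consecutive samples (default `t = 60` s at `Δ = 10` s,
so `w = 6`) whose inter-cow distances all lie within radius `r` (default
3 m); a lenient variant requires only a fraction `f` of in-radius samples.
Daily counts per dyad form symmetric weighted networks per functional
barn zone (feeding, non-feeding, full barn). On these the package
computes:

* **Cleaning** — barn-region filter (3 m buffer), stuck-sensor run
  removal, 15-point moving-average smoothing, stationary-day removal,
  with per-stage removal accounting.
* **Network measures** — edge density, connected components, node degree,
  local clustering coefficient, mean-weight edge filtering for drawings.
* **Permutation inference** with the counting p-value
  `p = #(t_p ≥ t_o)/q` (biased estimator `1/(q+1)` when the count is 0)
  and Bonferroni correction:
  * social differentiation
    `S = Σ_dyads (O_ij − E_ij)² / (n(n−1)/2)` against a uniform
    multinomial null, with per-dyad differentiation flags;
  * node-label permutation Kruskal–Wallis (inter-individual and
    between-day variation in daily interactions) and two-tailed Wilcoxon
    (lame vs non-lame on per-cow means);
  * Mantel–Spearman matrix correlations for temporal stability
    (block-averaged consecutive networks) and attribute assortment
    (absolute-difference matrices);
  * AHDB-style lameness classification from three fortnightly mobility
    scores (2–3 = lame session; dominant-status rules; double switchers
    and unscored cows excluded).
* **Synthetic herds** — semi-Markov feeding/resting/loafing bouts with
  OU-style jitter around stations, affinity-embedded station placement
  and bout synchronization for planted dyadic preferences, controllable
  attribute assortment, milking-absence windows, sensor noise at
  CEP50 = 1.9 m, stuck-sensor and out-of-barn artifacts, and an exact
  ground-truth contact log.

## Worked example

```r
library(herdprox)

geom <- barn_geometry()                      # study-barn zones, 3 m buffers
cfg  <- sim_config(n_cows = 12, n_days = 2, seed = 42)
sim  <- simulate_herd(cfg, geom)             # noise-free tracks + ground truth
raw  <- inject_artifacts(sim$positions, cfg, geom)

cleaned <- clean_pipeline(raw, geom)
cleaned
#> Cleaned positions: 162062 of 172800 records retained (6.21% removed)
#>   region_filter            removed      676 (0.391%)
#>   stuck_removal            removed      209 (0.121%)
#>   smoothing                removed     9853 (5.702%)
#>   stationary_day_removal   removed        0 (0.000%)

M <- daily_interaction_matrix(cleaned$positions, geom, "full_barn",
                              proximity_protocol(), day_index = 1)
edge_density(M)
#> [1] 0.6969697
graph_components(M)$count
#> [1] 1

social_differentiation(M, q = 1000, seed = 42)
#> Social differentiation: S = 3.14e+04 (p = 0.000999, q = 1000)
#>   differentiated dyads: 96.97% (threshold 308.7)

adm <- attribute_difference_matrix(sim$attributes, "parity")
assortment_test(M, adm, q = 1000, seed = 42)
#> Mantel-Spearman permutation test: statistic = 0.1378, p = 0.257 (q = 1000)
```

Reading the output: about 70% of the 66 dyads interacted at least once on
day 1 and the network is a single connected component. `S` is far above
its uniform-association null (`p` at the permutation floor `1/(q+1)`), so
dyads do not associate uniformly — some pairs interact much more than
chance; here that is driven by planted affinity structure
(`affinity_spread = 0.6` by default). Parity was not coupled to affinity
(`assortment_effect = 0`), and correspondingly the assortment test finds
no relationship between interaction counts and parity differences.

`run_all(run_config(...), out_dir)` chains every stage with file-based
handoffs (positions, per-day/zone matrices, measures, a flat statistics
report, and a manifest with seeds and a config hash); a rerun with the
same configuration is byte-identical. A command-line front end with
`simulate / clean / detect / networks / stats / run` subcommands is
installed at `inst/scripts/herdprox`.

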