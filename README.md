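# coresat

Core and satellite subcommunity stability of microeukaryotic plankton
under a complete reservoir-mixing disturbance.

Deep monomictic reservoirs mix top to bottom once a year: the thermocline
collapses, oxygen and nutrients redistribute, and the plankton community
is hit by a whole-ecosystem disturbance. `coresat` is an analysis pipeline
for time series that span such an event at two depths. It asks the
questions a microbial ecologist asks of that design — which taxa are
*core* (present in ≥ 75 % of samples) versus *satellite* (< 50 %), which
subcommunity carries the community's stability, does the community
recover, and how do environment, community structure and nutrient cycling
connect — and answers them with tested, reproducible code:

* **Hydrology** — thermocline detection from temperature profiles
  (vertical gradient > 0.2 °C·m⁻¹) and run-length labelling of visits
  into before / mixing / after periods.
* **Community preparation** — low-count filtering, rarefaction without
  replacement, occupancy partitioning (core / intermediate / satellite),
  six abundance categories (AAT / CAT / MT / CRT / CRAT / ART), and
  absolute abundances (qPCR total 18S copies × relative abundance,
  copies·mL⁻¹).
* **Stability** — moving-window (w = 5) inverse coefficient of variation,
  1/CV = μ/σ, of group-summed absolute abundance; windows grouped by
  disturbance contact; subcommunity-vs-entire stability regressions.
* **Beta diversity** — Bray–Curtis, NMDS (stress-1), ANOSIM
  (R = (r̄_between − r̄_within)/(n(n−1)/4)), SIMPER decomposition,
  time-lag regression, and period-pair dissimilarity bins with
  Kruskal–Wallis letter displays.
* **Networks** — Spearman co-occurrence networks (|ρ| ≥ 0.8, BH-adjusted
  p < 0.01, 0.05 % node filter), per-sample induced subnetworks, and
  topological metrics including deterministic greedy modularity.
* **Nutrient function** — a multi-nutrient cycling (MNC) index (mean of
  Z-scored log(x+1) C/N/P variables) and PLS path modelling
  (Lohmöller, mode A, centroid scheme; GoF = √(communality·R²);
  loading-0.7 pruning; bootstrap path significance).
* **Synthetic data** — a generator that emulates the full study design
  (34 visits per depth, 14/11/9 periods, abundance crash with
  surface-only recovery, covarying environmental drivers) so the entire
  pipeline is testable without sequencing data.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints what it found and writes tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # synthetic inputs -> results/data/
Rscript analysis/02_partition_abundance.R
Rscript analysis/03_stability.R
Rscript analysis/04_beta_diversity.R
Rscript analysis/05_networks.R
Rscript analysis/06_nutrient_plspm.R     # full orchestrated bundle
```

Stage 3, for example, prints (seed 1):

```
surface core vs entire: r = 0.985 (p = 4.5e-23)
surface satellite vs entire: r = 0.139 (p = 0.46)
surface entire-community stability medians: group1 5.90 | group2 2.82 | group3 3.97
bottom core vs entire: r = 0.998 (p = 3.2e-34)
bottom satellite vs entire: r = 0.612 (p = 0.00032)
bottom entire-community stability medians: group1 5.54 | group2 3.31 | group3 0.91
```

Read: stability of the whole community is carried by the core
subcommunity (r ≈ 0.99 versus ≈ 0.1–0.6 for satellites) at both depths;
surface stability collapses in the windows touching the mixing event
(group 2) and rebounds afterwards (group 3), while bottom stability keeps
falling after the disturbance — the recovery-versus-persistence contrast
between depths.

The same run can be driven in R directly:

```r
library(coresat)
ds  <- generate_scenario(scenario_config(seed = 1))
res <- run_pipeline(ds, run_config(seed = 1), outdir = "results/pipeline")
res$surface$stability_relations
res$bottom$plspm$core$model   # path coefficients, R2, GoF
```

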