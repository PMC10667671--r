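---
title: "Methods: core and satellite subcommunity stability under reservoir mixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core and satellite subcommunity stability under reservoir mixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coresat` re-implements, as a tested pipeline, the analysis of how core and
satellite microeukaryotic subcommunities at two water depths respond to a
complete reservoir-mixing event: occupancy-based taxon partitioning,
absolute-abundance stability through moving windows, beta-diversity
recovery diagnostics, co-occurrence subnetwork topology, and a path model
linking environment, community and a multi-nutrient cycling index. This
vignette explains the models, the tunable parameters, the synthetic-data
generator, and the numerical choices, in the package's own terms.

## Study design and hydrology

The design the package assumes (and its generator emulates) is a deep
subtropical reservoir sampled roughly every 10 days for a year at two
depths, passing from thermal stratification through complete mixing to
re-stratification. A visit is *stratified* when some successive pair of
its temperature profile exceeds a vertical gradient of 0.2 °C·m⁻¹
(`thermocline_depth()`, gradient assigned to the deeper endpoint so a
single depth is reported; the criterion is strict `>`). `label_periods()`
run-length-encodes the visits into `before` (leading stratified run),
`mixing` (the single unstratified run) and `after`; two separate
unstratified spells raise an error rather than guessing. The default
design has 34 visits per depth: 14 before, 11 mixing, 9 after.

## Core/satellite partitioning and absolute abundance

Counts are filtered (taxa with fewer than 10 reads dataset-wide are
removed as likely sequencing errors) and rarefied without replacement
(multivariate hypergeometric, via `vegan::rrarefy`) to the minimum sample
sum. Occupancy is computed per depth layer, after rarefaction: taxa
occurring in ≥ 75 % of a depth's samples are *core*, in < 50 % are
*satellite*, and the gap [0.50, 0.75) is kept as *intermediate* — those
taxa stay in the entire community but belong to neither subcommunity, so
entire-community quantities remain well defined.

Each taxon also gets one of six abundance categories from its per-sample
relative abundances, with 1 % as the abundant threshold and 0.01 % as the
rare threshold: AAT (abundant in every sample), ART (rare in every
sample), MT (between the thresholds in every sample), CAT (sometimes
abundant, never rare), CRT (sometimes rare, never abundant) and CRAT
(spans rare to abundant). Defined this way from the four indicator events
(any/all abundant, any/all rare), the six classes are mutually exclusive
and exhaustive, which a property test asserts over random tables.

Absolute abundance is the qPCR-measured total 18S rRNA gene copy number of
a sample multiplied by each taxon's relative sequence abundance
(copies·mL⁻¹); group sums over the entire/core/satellite taxon sets are
the inputs to the stability analysis. Per-sample sums over all taxa equal
the qPCR total exactly, and the construction is invariant to rescaling a
sample's counts.

## Moving-window stability (1/CV)

`moving_windows(n, w = 5)` enumerates the n − w + 1 overlapping windows;
with 34 samples that is 30 windows, window 1 covering samples 1–5 and
window 11 being the first to touch a mixing sample. Stability of a window
is the inverse coefficient of variation μ/σ of the group-summed absolute
abundance, with σ the n−1 sample standard deviation (the convention of the
standard unbiased estimator; the choice only rescales all windows
equally). A constant window is reported as `Inf` and excluded pairwise
from downstream regressions. Windows are grouped by disturbance contact:
group 1 (before only; 10 windows), group 2 (≥ 1 mixing sample; windows
11–25), group 3 (after only; 5 windows). `stability_relation()` regresses
subcommunity stability on entire-community stability (OLS + Pearson r),
excluding infinite windows; at least three finite pairs are required.

## Beta diversity

Bray–Curtis dissimilarities are computed on relative abundances of the
rarefied tables (equal depths make proportions and counts equivalent up to
scale). NMDS uses Kruskal stress-1 via `vegan::metaMDS` on the supplied
distances with a fixed seed, centring and principal-axis rotation, so runs
are reproducible; two axes are retained because the path models consume
axis scores. ANOSIM is implemented from the rank definition with divisor
n(n−1)/4 (which makes R = 1 at complete separation) and mid-ranks for
ties; random-permutation p-values use the add-one convention so p = 0 is
never reported, and exhaustive enumeration of label permutations is
available for small n. SIMPER decomposes the mean between-group
dissimilarity into additive per-taxon contributions; the decomposition
identity (contributions sum to the mean dissimilarity, percentages to
100 %) holds to machine precision and is tested at 1e−12. Time-lag
analysis regresses pair dissimilarity on the pair's time difference in
months of 30.44 days (continuous lags; no month binning). Period-pair
analysis bins all C(34,2) = 561 sample pairs into B–B, B–M, B–A, M–M,
M–A, A–A (sizes 91/154/126/55/99/36 in the default design) and compares
bins with the Kruskal–Wallis machinery below.

Group comparisons throughout use the tie-corrected Kruskal–Wallis H with
Conover–Iman rank t post-hoc comparisons, Benjamini–Hochberg corrected,
and an insert-and-absorb compact letter display (groups sharing a letter
are not significantly different at α = 0.05). The Conover–Iman post-hoc
was chosen over pairwise Mann–Whitney because exact Mann–Whitney p-values
have a floor of 0.1 at n = 3 per group, which would make letter displays
uninformative exactly where such panels are typically drawn; it is also
the post-hoc of the tool this analysis style comes from.

## Co-occurrence networks

Network nodes are taxa present in at least one sample of every period and
with mean relative abundance ≥ 0.05 % (the mean, not per-sample, reading
of the filter). One whole network is built per depth per subcommunity
from all 34 samples: all-pairs Spearman correlations (rank-based, so the
rarefied counts are equivalent to proportions), two-sided p from the t
approximation (exact rank-permutation enumeration is available for n ≤ 8;
full enumeration beyond that is combinatorially infeasible), BH-corrected
across all pairs; an edge requires |ρ| ≥ 0.8 and adjusted p < 0.01.
Constant taxa have undefined correlations: they stay as isolated nodes
with a warning. Per-sample subnetworks are induced subgraphs on the taxa
with reads in that sample, so the period signal lives in node presence.

Topological metrics: node and edge counts; average path length over
connected pairs only (the common convention for disconnected graphs);
Freeman betweenness centralization Σ(b_max − b_i)/((N−1)²(N−2)/2) on raw
betweenness (1 for a star, 0 for a complete graph); density 2E/(N(N−1));
and modularity of the partition found by `greedy_modularity()`, a
deterministic Clauset–Newman–Moore agglomeration with lexicographic tie
breaking that returns the best cut seen along the merge sequence. The
greedy optimum is verified against exhaustive partition search on small
graphs; determinism was preferred over stochastic community detection so
repeated runs are identical. Metrics undefined on small graphs (
centralization for N < 3, density for N < 2, modularity without edges)
are reported absent rather than extrapolated.

## Multi-nutrient cycling index and path models

The MNC index log(x+1)-transforms each of the eight carbon/nitrogen/
phosphorus variables (TC, TOC, TN, NH₄⁺, NO₃⁻, NO₂⁻, TP, PO₄³⁻), Z-scores
each over samples, and averages the eight standardized values per sample;
a zero-variance nutrient is an error naming the variable. Before path
modelling, collinearity is reduced by a greedy pass in input order that
drops the later variable of any pair with squared Spearman correlation
above the threshold (0.5 for environmental variables, 0.6 for the few
network properties) — deterministic, matching the "arbitrarily remove one
of the pair" convention.

`fit_plspm()` implements component-based structural equation modelling
(PLS-PM) with Lohmöller's alternating algorithm: reflective (mode A)
measurement for every block, centroid inner weighting by default
(factorial and path schemes are available), convergence when the largest
outer-weight change falls below 1e−6, and OLS inner regressions of each
endogenous latent variable on its predecessors. Each latent variable's
sign is aligned to correlate positively with its first indicator, which
fixes the sign indeterminacy of composites (important for bootstrap
stability). GoF = √(mean communality × mean R²). Indicators with
|loading| < 0.7 are dropped and the model refitted until none remain;
emptying a block this way is an error. The centroid scheme and mode A
were chosen as the conventional defaults of the tool family this analysis
comes from; with single-indicator blocks the whole procedure collapses,
exactly, to OLS path analysis on standardized variables, which is tested
to 1e−10.

Path significance uses a case-resampling bootstrap with percentile
intervals and p by interval inversion (add-one convention); degenerate
resamples with a constant indicator are redrawn and counted. Parameter
recovery is tested under a composite-model data-generating process — all
between-block covariance flows through composites whose indicator
correlations equal the target loadings — because mode-A PLS is consistent
for composites. Under a common-factor process the population values of
the PLS estimates are attenuated (e.g. 0.445 and 0.265 for true structural
paths 0.5 and 0.3 with three indicators per block); that attenuation is a
property of the estimator itself, not a defect of this implementation,
and is why recovery is asserted against the composite model.

In the orchestrated pipeline the model has blocks WT, Phys, Nutr, Chl-a
(drivers), the two NMDS axis scores and the network properties
(community), and MNC. Drivers point at the community blocks and at MNC;
community blocks point at MNC; the Nutr → MNC path is structurally absent
because the nutrients define the index. If pruning empties a block the
pipeline refits without pruning and warns, preferring a complete result
bundle over a hard stop.

## The synthetic-data generator

`generate_scenario()` produces everything the pipeline consumes: counts,
qPCR totals, environment and temperature profiles, plus the latent truth
used by parameter-recovery tests. The generator's defaults are the study
conditions, chosen once:

* **Design**: 34 visits per depth at a 10-day cadence from 1 July 2015,
  periods 14/11/9; surface and bottom layers.
* **Taxon pool**: 60 core, 40 intermediate, 300 satellite taxa per depth.
  Core taxa have high log-normal mean abundances and occupancy ~1;
  satellite taxa have low means (log-mean −0.5, SD 1.5, so a tail of
  them passes the 0.05 % network filter) and per-taxon occupancy drawn
  from U(0.08, 0.45); intermediate occupancy U(0.55, 0.72).
* **Shared dynamics**: every taxon loads (SD 0.8) on two latent drivers —
  a seasonal temperature-like trajectory (cyclic at recovering depths, a
  persistent step otherwise) and the mixing pulse — giving taxa the
  correlated dynamics real plankton show and hence non-trivial
  co-occurrence structure. A further per-taxon mixing shift (SD 0.8)
  rearranges composition during the disturbance; at non-recovering depths
  an analogous persistent shift applies after it.
* **Totals**: latent total abundance 10⁶ copies·mL⁻¹ with log-normal
  sample noise (SD 0.25, log scale), multiplied by 0.2 during mixing
  (`crash_multiplier`). At recovering depths the multiplier returns to 1
  afterwards; at non-recovering depths the after period follows a
  declining random walk (drift −0.3 per step) whose step SD ramps
  linearly up to 2.0, so instability keeps growing instead of
  recovering — this is what produces "stays at disturbance-level
  stability" rather than a merely depressed but steady series, which
  would be just as stable as before (1/CV is scale-invariant).
* **Measurement**: counts are multinomial draws of 20 000 reads per
  sample from the latent relative abundances, separating compositional
  sampling from total-load measurement; qPCR totals are the latent totals
  times mean-1 log-normal noise with CV 0.1.
* **Environment**: surface temperature follows an annual sinusoid (so its
  before/after distributions agree by construction); bottom temperature
  steps down after mixing; bottom DO pulses from anoxia to ~7.85 mg·L⁻¹
  during mixing; bottom Chl-a, TN and TP decline after mixing; bottom
  NH₄⁺ falls and NO₃⁻ rises during mixing (the nitrification signature);
  the remaining variables carry mild period effects plus Gaussian noise.
* **Profiles**: stratified visits get a logistic temperature step across
  a thermocline that deepens through each stratified season; mixing
  visits are vertically uniform within 0.1 °C.

Sequencing depth is 20 000 reads rather than the ~10⁵ of a real run: at
the taxon-pool sizes above this keeps every distributional feature the
pipeline uses (occupancy classes, abundance categories, rank
correlations) while keeping the full suite fast.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: taxonomic structure and phylogeny; sequencing
error, chimeras and compositional artefacts beyond multinomial sampling;
autocorrelated environmental noise; and period contrasts in per-sample
subnetwork topology for the core subcommunity (core occupancy is ~1, so
core subnetworks barely change across samples; the topology-comparison
machinery is therefore validated on constructed patterns and exact
oracles instead of on generator truth).

## Numerical choices and degenerate inputs

Randomness always enters through explicit seeds; the pipeline fans a
single master seed out to stages via a deterministic hash, so whole runs
are byte-reproducible and independent stages have independent streams.
Permutation p-values use the add-one convention. Infinite stabilities are
excluded pairwise; all-zero samples are an error where a dissimilarity is
undefined, and are dropped with a warning where a subcommunity simply has
no reads in some samples. Thresholds sit exactly on their boundaries as
documented: occupancy core ≥ 0.75, satellite < 0.50; abundant ≥ 1 %, rare
< 0.01 %; network node filter ≥ 0.05 %; edge |ρ| ≥ 0.8 with adjusted
p < 0.01 strictly.

## Problem sizes used by the test suite

The suite regenerates everything programmatically: default 34-sample
scenarios for design arithmetic and directional signatures (12–50 seeds
for replicated directional checks), n = 5000 × 20 seeds for PLS-PM
recovery, 500 null datasets for the ANOSIM type-I calibration and 200
simulations × 299 bootstrap resamples for the bootstrap type-I
calibration, 100 random tables for the SIMPER identity, and exhaustive
enumeration oracles at n ≤ 9 observations (Kruskal–Wallis), n = 6 samples
(ANOSIM) and ≤ 6 nodes (modularity).

## Known limitations

* Mode B (formative) measurement, higher-order constructs and multi-group
  PLS-PM comparisons are out of scope.
* The ANOSIM/Mantel family shares ranks across all pairs, so its p-values
  inherit the usual non-independence caveats of distance-based tests.
* Greedy modularity is exact on the small graphs tested but is a
  heuristic in general; it was chosen for determinism, not optimality.
* SIMPER contributions are reported unstandardized (no per-taxon SD
  ratio), matching the decomposition identity the tests assert.
* Thermocline detection uses absolute successive-pair gradients; signed
  conventions would differ only for temperature inversions.
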