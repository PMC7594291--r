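---
title: "Modelling long-distance seed dispersal by red deer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-distance seed dispersal by red deer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deerseed)
```

## The model

`deerseed` treats the dispersal distance of an individual seed as the
displacement a deer accumulates while the seed sits in its gut:
`d = v · p`. Neither factor is modelled parametrically. The velocity term
is the animal's realized GPS trajectory; the passage-time term is an
empirical distribution assembled from feeding-trial results.

One simulated dispersal event proceeds as:

1. draw a deposition endpoint uniformly, with replacement, from the
   individual's GPS fixes (a random candidate defecation site — endpoints
   are deliberately *not* weighted toward resting or other
   defecation-likely behaviour, since no such weighting is identified);
2. draw a passage time `p` (hours) from the pooled passage-time sample;
3. set the ingestion time to the endpoint time minus `p` and read the
   ingestion position off the trajectory;
4. record the horizontal displacement `sqrt(Δe² + Δn²)` and the signed
   vertical displacement `z_end − z_start`.

Per (individual, month) cell, the per-seed LDD probability in each
orientation is the fraction of events strictly beyond the threshold:
1000 m horizontal, ±50 m vertical. These are *absolute* LDD definitions —
fixed distances with ecological meaning (beyond typical population extents;
a 50 m climb offsets roughly 0.3 °C of warming) — rather than
distribution-quantile definitions, which would track extremeness instead of
distance.

### Assumptions worth stating

- **Coordinates are planar metres** (UTM-style). No geodetic handling:
  inputs must be projected before they reach the package.
- **Straight-line displacement**, not path length: `d` is the chord between
  ingestion and deposition points.
- **Within-interval placement of passage times is uniform.** The retention
  model supplies only interval probabilities over 14 intervals with upper
  bounds 1, 3, 6, 9, 12, 15, 18, 21, 24, 30, 36, 42, 48, 54 h; the
  within-interval law is not identified, and uniform is the maximum-entropy
  completion. All (trial, species) cells are pooled with equal weight into
  one empirical `p` distribution (`cell_weights` can change this for
  sensitivity analyses); per-species passage distributions are deliberately
  not linked to the seed-load species, since a single pooled distribution
  serves all plants.
- **Ingestion positions are linearly interpolated** between the bracketing
  fixes (in easting, northing *and* elevation); `start_rule = "nearest"`
  snaps to the nearest fix instead, so the sensitivity to this choice is
  measurable. Elevation comes from the fixes themselves, not an external
  DEM.
- **Left-censoring**: an event whose ingestion time falls before the
  trajectory's first fix cannot be located. The (endpoint, p) pair is
  redrawn, up to `max_redraws` (default 100) times, then dropped; the
  dropped fraction is always reported in the run manifest. This slightly
  under-represents long passage times when trajectories are short, which
  is why the reported dropped fraction should be checked.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `horizontal_threshold` | 1000 | m | beyond most plant-population extents |
| `vertical_threshold` | 50 | m | ≈ 0.3 °C temperature offset |
| `n_endpoint_draws` | 100,000 | events/individual | Monte-Carlo error on cell probabilities ≪ between-cell variation |
| `n_passage_draws_per_cell` | 100,000 | draws/cell | with 6 × 6 cells: 3.6 M pooled values of p |
| `n_permutations` | 100,000 | — | stable 2.5/97.5 percentiles; a guard-rail warns below 1,000 |
| `min_individuals_per_species` | 5 | deer | species-level tests need replication across vectors |
| `contamination_tray_min` | 3 | trays | a species in ≥ 3 dung-free control trays is a greenhouse contaminant |
| `dry_mass_per_ml` | 0.13 | g/ml | measured dung dry-mass-to-volume ratio |
| `max_redraws` | 100 | — | bounds the left-censoring redraw loop |

The draw budget is per individual, with months stratified *post hoc* by
each event's endpoint month; this matches a design in which each animal's
whole study period is simulated at once. (A balanced per-cell budget can be
had by running `simulate_events` per month.)

### Seed load arithmetic

Q is seedlings per gram of dung dry mass:
`q = count / (volume_ml × 0.13 g/ml)`. A verbal recipe of the form
"divided by volume, multiplied by 0.13 g/ml" appears in parts of this
literature; read literally it yields seedlings·g/ml², which is not a
load per gram. We implement the dimensionally consistent reading and keep
the literal one behind `q_formula = "literal"` for auditing. Cell values
aggregate the up-to-three samples per individual × month by the **mean**
of per-sample q (samples lacking a species contribute 0); `"sum"` and
`"pooled"` (Σcounts/Σmass) are config alternatives, since the aggregator
is another choice the data description leaves open.

### Transforms for the linear models

LDD probabilities are logit-transformed and seed loads log-transformed
before regression, both then z-standardized ("scaled" is read as
z-scoring, the standard choice). Finite simulation budgets can produce
cells with probability exactly 0 or 1, where the logit diverges; these are
smoothed empirically as `(p·(n−1) + 0.5)/n` with `n` the cell's event
count. Zero loads are shifted by half the smallest positive load before
the log. Both rules are applied only where needed, so interior values are
untouched.

### ANOVA grains

The variance partitioning runs as *separate one-way fits per factor*, at
two grains: LDD probability at the individual × month cell grain, seed
load at the sample grain. This reproduces the degrees-of-freedom structure
of separate one-way analyses (e.g. F(20, 137) vs F(7, 150) on the same
158 cells). The better-specified additive two-factor fit is also computed
(`joint_partition`), with sequential sums of squares reported in both
orders since the design is generally unbalanced. No multiple-testing
correction is applied across these descriptive analyses. The load–LDD
regression is run at the individual grain (per-animal total load against
the event-weighted per-animal LDD probability).

## Species LDD potential and its null

For plant species `s` with loads `q_c` over sampled cells `c` and cell LDD
probabilities `ldd_c`, the LDD potential is the weighted mean
`Σ q_c · ldd_c / Σ q_c`. The null model permutes the species' load vector
uniformly at random across the sampled cells — *all* cells with dung data,
including zero-load cells, because the sampling design, not the species'
occupancy, defines the exchangeable set (`permute_positive_only = TRUE`
restricts it). The 95% interval is the plain 2.5/97.5 percentile pair of
the permutation distribution. Deviations use strict inequalities, so ties
with a degenerate interval count as non-deviations (conservative). The
across-species meta-test is the upper binomial tail
`P(X ≥ k), X ~ Bin(n_tests, 0.05)`.

Two caveats are documented rather than "fixed":

- **Cell-level permutation is exactly calibrated only for loads that are
  exchangeable across cells.** When a species' load concentrates on
  particular individuals (as real diets do) while LDD probability also
  clusters by individual, the permutation null is narrower than the
  sampling distribution of the observed potential and the per-test
  deviation rate exceeds 5% even without any load–mobility coupling. The
  acceptance checks therefore calibrate the null under exchangeable loads
  (flat month profiles, no individual load effect) and test the
  *directional* signature of mobility coupling separately.
- **The binomial meta-test treats species × orientation tests as
  independent**, which they are not (they share the LDD table and, across
  orientations, the loads). It is used as a descriptive summary exactly as
  in the field design.

## The synthetic population

The confidential telemetry data are replaced by a generator whose defaults
mirror the study conditions: 21 reproductively mature females, hourly
fixes, May–December, roughly three dung samples per individual per month
with mean volume 172.3 ml, and ≥ 62 plant species.

- **Movement** is a correlated random walk: gamma step lengths
  (shape 2) with individual-specific means spanning a 4-fold range
  (70–280 m/h on a log grid) — the single mobility axis — wrapped-normal
  turning noise (sd `π/(1 + turn_concentration)`), and a mild angular pull
  (`home_range_attraction = 0.1`) toward an individual home-range centre.
  One scalar mobility knob per animal keeps parameter recovery testable.
- **Terrain** is a smooth sum of sinusoids (amplitude 200 m, wavelength
  3 km, base 900 m), evaluated exactly at every fix, so vertical
  displacements have a closed-form oracle, unlike an interpolated DEM.
- **Seed loads** follow a log-linear mean function per sample:
  `λ = mass_g · base_rate_s · month_profile_{s,m} · n_months ·
  exp(σ_ind · z_{s,a} + γ · zmob_a)`, realized as Poisson counts.
  `z_{s,a}` is a species-specific individual effect — plant species differ
  in how their load distributes across deer — and `γ`
  (`mobility_coupling`) concentrates load on mobile individuals when
  positive, implementing the alternative hypothesis of the load–mobility
  analyses; `γ = 0` gives independence by construction. Base rates follow
  a steep log-series (2 down to 1e-4 seedlings/g at peak), so a few
  species dominate and a long rare tail is thinned by the five-individual
  filter. Contaminant species are planted in ≥ 3 control trays *and*
  sprinkled into samples, so the contamination filter has real work to do.

What the generator does **not** emulate: GPS fix error and fix failure
(all synthetic fixes pass the quality screen; the screen itself is tested
on constructed tables), the weekly 15-minute high-resolution days,
overdispersed (non-Poisson) seedling counts, habitat selection, and any
behavioural coupling between movement and defecation. Passing tests
therefore show the *machinery* is correct under known structure, not that
real data meet these assumptions.

## Numerical and reproducibility choices

- Strict inequality at thresholds (`d > 1000`, not `≥`): measure-zero for
  continuous kernels, fixed for reproducibility.
- Passage-model cells must sum to 1 within 1e-6 (renormalized) — larger
  deviations are data errors, not noise.
- Duplicate GPS timestamps collapse to the first occurrence (stable),
  with a logged count; animals with < 2 usable fixes are excluded with a
  warning rather than failing the run.
- Month labels are UTC calendar months of the *endpoint* (events) or the
  collection date (samples).
- One master seed (`rng_seed`) fans out to per-stage seeds by fixed
  offsets, so any stage can be rerun in isolation and still match the full
  pipeline; identical config + seed gives byte-identical outputs.
- Degenerate fits are handled explicitly: a saturated species × LDD
  interaction returns an infinite-F sentinel; a constant-load permutation
  null collapses to a zero-width interval and is flagged; a constant
  regression response returns slope 0 (a constant *predictor* is an
  error).

## Problem sizes used in the test suite

The shipped checks scale the study down to keep hundreds of replicates
cheap while preserving its structure: mini-populations of 10–21
individuals, 2–6 days per month, 800–20,000 endpoint draws, 500–2,000
permutations, with 100–500 seeded replicates for the calibration and
pattern checks (null coverage of the permutation interval, dominance of
individual over month variance under 4-fold mobility heterogeneity, and
the directional excess of potential-increasing deviations under positive
mobility coupling). Exact oracles — brute-force enumeration of
endpoint × passage-time pairs, exhaustive 4! permutation distributions,
closed-form constant-velocity kernels, and hand-computed sums of squares —
pin down the deterministic core at machine precision.

## Known limitations

- Endpoints are drawn uniformly over fixes, so irregular fix schedules
  (e.g. occasional high-frequency days) over-weight densely sampled
  periods; resample to a uniform schedule first if this matters.
- The permutation null's anti-conservativeness under clustered loads and
  the meta-test's independence assumption, discussed above.
- Retention beyond 54 h is truncated by the passage model's support;
  recorded dispersal distances are correspondingly truncated.
- The generator's movement model is stationary within the study period;
  it cannot produce genuine month effects on LDD probability, which is
  precisely what makes it a clean null for the individual-vs-month
  partitioning check.
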