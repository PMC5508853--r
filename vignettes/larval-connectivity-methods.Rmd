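---
title: "Methods: larval connectivity, reserve supply and fisheries dependency"
author: "larvalink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval connectivity, reserve supply and fisheries dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`larvalink` implements an end-to-end analysis of how well a system of
marine protected areas (MPAs) is connected by passive larval drift, and
whether the no-take reserves (MRs) among them supply larvae to the coastal
fishing zones of the countries that depend most on coastal fisheries. The
chain is:

1. **Transport.** Virtual larvae are released at MPA centroids and advected
   on gridded surface currents for the pelagic larval duration (PLD), with
   random-walk horizontal diffusion. Endpoints, not trajectories, are the
   output.
2. **Connectivity.** A connection probability `e_ij` is the fraction of
   larvae released at source *j* whose endpoint lies in the coastal portion
   (depth ≤ 100 m) of target *i*. Probabilities are only evaluated within a
   marine biogeographic realm.
3. **Networks.** MPAs are nodes, positive `e_ij` are directed edges
   (self-loops kept). Weakly connected components are "networks"; per
   network we compute self-loop-inclusive in/out degrees, normalized
   directed betweenness centrality (BC) and the max-scaled left Perron
   eigenvector centrality (EC).
4. **Larval supply.** Each fishing zone (the coastal part of an exclusive
   economic zone, EEZ, with reserves erased) receives a biomass-weighted
   larval density `LD_i = Σ_j e_ij B_j A_j / A_i`, where `B_j` is predicted
   fish biomass per unit area in reserve *j*, `A_j` its coastal area, and
   `A_i` the zone's coastal area. `LD` is min–max indexed to 0–100.
5. **Dependency mismatch.** Three country indicators — landed value/GDP
   (economic), fishers/active population (employment), catch per capita
   scaled by diet adequacy against a 36 g protein/day reference (food
   security) — are indexed 0–100, countries are split into dependency
   tertiles, and larval supply is compared across tertiles with a
   Kruskal–Wallis test followed by Conover–Iman pairwise comparisons under
   Benjamini–Hochberg adjustment.

Every stage is exercised on synthetic inputs with known ground truth, so
the whole pipeline runs and is testable at desk scale.

# The transport model

Advection uses the classical fourth-order Runge–Kutta scheme on bilinearly
interpolated velocities (linear in time between stored snapshots). The
reference step is `dt = 3600` s, short enough that a particle crosses at
most one grid cell per step at realistic speeds; `run_dispersal()` warns
when a configuration violates this.

Horizontal diffusion represents sub-grid-scale circulation. The
coefficient follows the dissipation-rate scaling

\[ K = \varepsilon^{1/3} \, l^{4/3}, \]

with turbulent dissipation rate `ε = 1e-9 m² s⁻³` by default and `l` the
grid cell length. Increments are Gaussian with zero mean and per-axis
variance `2 K Δt`. The literature describes the scheme only as a "random
walk"; we adopt the Gaussian form because it is the diffusion limit of any
bounded-step walk, and the tests pin the variance contract rather than the
increment shape (a uniform-step walk with matched variance would pass the
same suite at these step counts).

Boundary rules, which the desk-scale domain needs but a global domain does
not: an advection step that would beach a particle is truncated at the
coast (bisection to the last ocean point); a diffusion displacement onto
land is redrawn (up to 20 times, then dropped for that step); a particle
leaving the open boundary is frozen at its last valid position and flagged
`exited` — it counts as released and settles nowhere. Land nodes carry
zero velocity, so interpolation near the coast decays smoothly to zero and
a query surrounded by land returns (0, 0).

Releases default to the four season midpoints (2 February, 5 May,
6 August, 11 November) in each simulated year; 10,000 larvae per site per
event over 6 years is the reference design, which the scheduler's
arithmetic reproduces exactly (3,061 sites × 10,000 × 4 × 6 =
734,640,000).

**Coordinates are planar metres.** A spherical lon/lat mode was
considered and rejected: the tests rely on exact analytic oracles
(uniform displacement, rigid rotation, Brownian scaling), which are only
exact on a plane, and nothing in the downstream statistics depends on the
map projection.

# The synthetic study system

The generators define the study conditions; they are not tuning knobs.

* **Domain** (`make_domain`): a 1,800 × 300 km shelf. The coastline runs
  along y = 0; depth grows linearly offshore, putting the 100 m isobath
  150 km out. Six EEZ bands of 300 km alongshore are grouped into two
  contiguous realms. Band width matters: real EEZs are wide relative to a
  30-day drift (~140 km at the default current), so 300 km bands place the
  system in the retention-dominated regime; narrower bands would turn
  nearly all settlement into border crossings. Twenty MPAs (simple
  star-shaped polygons, 3–8 km radius, non-overlapping, each wholly inside
  one band) sit on the shelf between 10 and 60 km offshore. A quarter of
  them qualify as reserves, through a rotating mix of the qualifying
  mechanisms (fully no-take, partly no-take, IUCN Ia, IUCN Ib), so the
  classification rule is exercised on all its branches.
* **Currents** (`make_velocity_field`): four analytic families (uniform
  drift, solid-body rotation, double gyre, gyre plus noise). The demo uses
  a steady 5.4 cm/s drift at 22° — an alongshore current with a mild
  offshore component, the configuration under which shortening the PLD
  reduces larval supply to fishing zones. 5 cm/s is a typical mean
  coastal surface current; the offshore component (≈2 cm/s) exports part
  of each release without emptying the shelf.
* **Biomass survey** (`make_biomass_survey`): 121 reserves × 12
  standardized covariates; log10 biomass is linear in eight of them
  (slopes 0.35 … 0.08, four null covariates) plus Gaussian noise of
  sd 0.3, sized so the survey signal-to-noise sits near R² ≈ 0.8 — the
  regime reported for the real survey model. The ground-truth function is
  attached for recovery tests.
* **Country tables** (`make_dependency_tables`): a Gaussian copula on the
  normal scores of the supply ranking induces a target rank correlation
  (`mismatch_strength`) between supply and dependency; each indicator
  loads 0.95 on the shared latent, so the three indicators are correlated
  but distinct and the realized Spearman correlation is mildly attenuated
  (about 0.79 realized at a target of 0.9). Raw inputs (landed value,
  GDP, fisher counts as reported/extrapolated pairs averaging to the
  latent value, active population, catch, protein) are back-solved so the
  indicator module recomputes the intended values exactly. The default
  `mismatch_strength = -0.6` encodes the study's qualitative finding —
  supply concentrated where dependency is low — at moderate strength.

What the generators deliberately do **not** emulate: mesoscale eddies and
topographic steering, real coastline geometry, within-polygon release
spread (all larvae start at the centroid, which exaggerates self-retention
for large polygons), larval behaviour and mortality. Passing tests
therefore demonstrate the correctness of the numerics and statistics under
known conditions, not fidelity to any real coastline.

# Numerical and statistical choices

* **Tertile thresholds** on connection strength are the 1/3 and 2/3
  empirical quantiles (linear interpolation, type 7) of the *positive*
  entries, computed globally across realms; boundary-valued entries are
  kept. Zeros are excluded because the zero class is structurally distinct
  (unconnected pairs) rather than weakly connected.
* **Betweenness** treats edges as unweighted hops by default — the metric
  counts shortest paths, and the source description does not state a
  weight transform; a `-log(e)` weighted mode is available.
* **Eigenvector centrality** is computed per weakly connected component by
  power iteration on the transposed weight matrix (tolerance 1e-12, cap
  1000 iterations) with a dense `eigen()` fallback for periodic
  structures. Scaling is max-to-1 rather than min–max: min–max would force
  a zero score onto the least central node and destroy the ratio
  interpretation, while the ranking only needs values in [0, 1].
* **Degenerate min–max indexing** (all values equal) maps everything to 0
  with a warning rather than erroring, so unseeded-everywhere runs remain
  analysable.
* **Zero-supply or zero-coverage EEZs** fall outside the log domain of the
  coverage–supply regression and are excluded and counted; with fewer
  than three usable zones the regression refuses to fit.
* **Dependency grouping** uses tertiles of the indexed indicator — the
  grouping rule behind the published violin plots is unstated, and the
  tertile rule is flagged prominently here for that reason. Heavy ties
  fall back to ordinal-rank thirds with a warning.
* **Conover–Iman** pairwise statistics use the tie-corrected
  Kruskal–Wallis variance with df = N − k; BH adjustment is applied
  within each indicator's family of three pairwise tests. All-equal
  responses short-circuit to H = 0, p = 1.
* **Rank-sum protection comparisons** use mid-ranks, exact enumeration
  for small untied samples and the continuity-corrected normal
  approximation otherwise.
* **Boosted biomass model**: xgboost with learning rate 0.05, depth 3,
  bag fraction 0.7; the round count is chosen by 5-fold cross-validated
  deviance with 50-round patience (the CV-based stopping of the standard
  BRT protocol), covariates are ranked by gain and the top 8 are refit.
  Both the in-sample R² and a 5-fold cross-validated R² are reported,
  since published BRT accuracies rarely say which they are; on the
  calibrated synthetic survey the honest (CV) figure sits near 0.5–0.76
  while in-sample exceeds 0.9.

# Reproducibility and problem sizes

One master seed drives everything. Stage seeds are derived
deterministically (`derive_seed`), each release event gets its own
stream, and two runs from the same configuration are bit-identical — the
test suite checks artifact checksums. The desk-scale problem sizes were
chosen to keep a full pipeline run under about a minute: 20 MPAs × 200
larvae × 8 events (32,000 particles, 720 steps each), a 361 × 61 node
grid, 6 EEZs, and a 121-site survey; the country-scale mismatch power
study runs 200 replicates at 120 countries. The reference parameter set
(PLD 30 d, dt 3,600 s, ε = 1e-9, 10,000 larvae/event, 4 events × 6
years) is the package default and is asserted as such in the tests.

# Known limitations

* Connection probabilities pool all release events; inter-annual
  variability is not resolved (per-event matrices would need more larvae
  per event to be stable at desk scale).
* The unweighted-hop default for BC makes path counts insensitive to
  connection strength; use the weighted mode when strengths span orders
  of magnitude.
* With six EEZs the within-demo Kruskal–Wallis test is illustrative only
  (groups of two); the powered version of the mismatch analysis lives at
  the country scale (n = 120).
* The copula in `make_dependency_tables` targets the rank correlation
  with the *shared* dependency latent; per-indicator correlations are
  attenuated by the 0.95 loading, which tests must (and do) account for.
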