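# larvalink

Marine reserves are expected to seed surrounding fisheries with fish
larvae, yet whether the reserves a country *has* actually supply the
fishing zones that country *depends on* is a quantitative question about
ocean currents, reserve placement and socio-economics. `larvalink` is an R
package plus analysis workflow for exactly that question: it simulates
passive larval drift on gridded surface currents, estimates connection
probabilities among marine protected areas (MPAs) and from no-take marine
reserves (MRs) to coastal fishing zones, characterises the resulting
networks, computes a biomass-weighted larval-supply index per exclusive
economic zone (EEZ), and tests whether supply differs across levels of
national fisheries dependency.

It is written for spatial ecologists and fisheries scientists who want the
full chain — transport, connectivity, network metrics, supply index,
dependency statistics — runnable and testable at desk scale on synthetic
data with known ground truth.

## The model in brief

* **Transport:** fourth-order Runge–Kutta advection of passive larvae on
  bilinearly interpolated currents, with random-walk horizontal diffusion
  of coefficient `K = ε^(1/3) l^(4/3)` (ε the turbulent dissipation rate,
  l the grid cell length). Larvae drift for the pelagic larval duration
  (PLD, 30 days by default; 20 days as a behaviour proxy).
* **Connectivity:** `e_ij` = fraction of larvae released at source *j*
  settling in the coastal (≤ 100 m deep) portion of target *i*, evaluated
  within marine biogeographic realms only. An MPA is an MR if it is fully
  or partly no-take or in IUCN category Ia/Ib.
* **Networks:** weakly connected components of the directed MPA graph;
  self-loop-inclusive degrees, normalized betweenness (BC) and max-scaled
  left-eigenvector centrality (EC) per network.
* **Larval supply:** `LD_i = Σ_j e_ij · B_j · A_j / A_i` with `B_j`
  boosted-regression-tree-predicted fish biomass per unit area, `A_j`/`A_i`
  coastal surface areas; min–max indexed to 0–100.
* **Dependency mismatch:** economic (landed value/GDP), employment
  (fishers/active population) and food-security (catch per capita scaled by
  diet adequacy against 36 g protein/day) indicators, indexed 0–100;
  Kruskal–Wallis across dependency tertiles with Conover–Iman post hoc
  tests and Benjamini–Hochberg adjustment.

See `vignettes/larval-connectivity-methods.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running
it end to end on the built-in desk-scale study system (20 MPAs, 5 reserves,
6 EEZ bands on a 1,800 × 300 km shelf under a 5.4 cm/s drift):

```sh
Rscript analysis/01_generate_inputs.R
Rscript analysis/02_simulate_dispersal.R
Rscript analysis/03_connectivity_networks.R
Rscript analysis/04_larval_supply.R
Rscript analysis/05_dependency_mismatch.R
Rscript analysis/06_sensitivity.R
```

prints, among other lines:

```
Releasing 32000 larvae: 20 sites x 200/event x 8 events (PLD 30 d, dt 3600 s).
Dispersal done in 35 s; K = 85.5 m2/s; 3758 of 32000 particles exited the domain.
MPA-to-MPA: 7 positive connections among 20 MPAs (within realm).
13 networks; 13 MPAs not seeded by any other (65%); 9 fully isolated (45%).
Rank-sum MR vs MPA: BC W = 35 (P = 0.64); EC one-sided W = 38 (P = 0.53).
Within-EEZ retention across reserves: median 89%, mean 70%.
Biomass model: in-sample R2 = 0.97 (Pearson r = 0.99), CV R2 = 0.57; top 8 covariates kept: ...
Larval density: 2 of 6 EEZs unseeded (33%); index spans 0-100 by construction.
food dependency: Kruskal-Wallis H = 3.82, P = 0.15 (groups n = 2/2/2).
Power study (n = 120 countries, food security): reject 100% under strength -0.9, 6.0% under the null.
Isolated MPAs by threshold: 9 (all) <= 11 (medium+strong) <= 11 (strong).
```

Reading these numbers: most of the synthetic MPAs are unconnected (13 of 20
receive no larvae from any other MPA), most settlement is retained within
the home EEZ (median 89% of settled larvae), a third of the fishing zones
receive nothing from reserves, and centrality does not differ between
reserves and other MPAs. The within-demo Kruskal–Wallis (6 countries) is
illustrative; the powered mismatch analysis runs at 120 countries, where a
strong negative supply–dependency coupling is detected in 100% of
replicates and the null is rejected at the nominal ~5% rate. Tightening the
connection-strength threshold from all connections to the strongest tertile
raises the isolated-MPA count from 9 to 11, and shortening the PLD from 30
to 20 days seeds no additional fishing zones — the sensitivity directions
expected for drift-limited supply.

Each step also writes tables (endpoints, sparse connectivity triplets, node
metrics, larval-density and dependency indicators, sensitivity reports)
under `results/`.

From R, the same pipeline is one call:

```r
library(larvalink)
run <- run_pipeline(demo_config(seed = 1))
run$summary$retention_median   # 0.89125
run$summary$n_unseeded_eez     # 2
```

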