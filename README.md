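# lcnflow

Load-induced interstitial fluid flow through the osteocyte lacunocanalicular
network (LCN) of human osteons, modelled as a hydraulic circuit on a weighted
spatial graph.

Osteocytes live in lacunae connected by ~300 nm canaliculi, and the prevailing
hypothesis of bone mechanosensation is that these cells sense the wall shear
stress of interstitial fluid driven through this pore network when bone is
loaded. `lcnflow` provides the network-scale half of that story for
whole-osteon LCN graphs (tens of thousands of canaliculi): given a spatial
multigraph with canalicular arc lengths, it solves for node pressures,
per-canaliculus velocities and cell-process shear stresses, and derives the
osteon-level quantities that characterise the two osteon types (ordinary
osteons and "osteon-in-osteons", whose outer network reaches the Haversian
canal only through a few bridges).

## Model

Each canaliculus `j` is a Darcy conductor for the annulus between the
osteocyte process and the canalicular wall,

    C_jj = (k_p,eff / mu) * A / l_j,     A = (Ca.Rd^2 - CP.Rd^2) * pi

with effective canalicular permeability `k_p,eff = 1.53e-17 m^2`, bone-fluid
viscosity `mu = 1.06e-3 Pa s` and annular cross-section `A = 0.061 um^2`.
Kirchhoff's current law `t(A) q = -f` on the oriented incidence matrix plus
Darcy's law `q = C (-A p + b)` gives the weighted-Laplacian system
`L p = t(A) C b + f` with `L = t(A) C A`. All canal-surface nodes are merged
into a grounded reference supernode (the Haversian canal is a constant
low-pressure reservoir) and the reduced system is solved by sparse Cholesky
factorisation. Two boundary conditions are provided:

* **Fixed pressure (approach 1).** Cement-line nodes held at 13 kPa, canal at
  0; the resulting length-weighted mean velocity yields the intrinsic osteon
  permeability `k_osteon = v_bar * mu * dR / dp` (with `v_bar = sum(v_j l_j) /
  sum(l_j)`), which equals `k_p,eff` for straight radial canaliculi and falls
  below it for tortuous, poorly connected networks.
* **Strain sources (approach 2).** Homogeneous compression at volumetric
  strain rate `eps' = 0.015 1/s` (peak exercise; 0.0015 for walking) makes
  every node a fluid source proportional to its pore volume — half its
  incident canalicular volume plus 350 um^3 for lacunae — squeezing the fluid
  into the canal like water from a compressed sponge.

Shear stress on the cell process follows `tau = mu * K * v` with
`K = 465 1/um`. Downstream analyses include smoothed pressure-distance
profiles (tricube LOWESS, 10% span), 36-sector angular heterogeneity,
cumulative shear-exceedance distributions with confidence bands,
velocity/path-length relations and exact rank-sum group comparisons. Because
no imaging data accompany the model, a seeded generator produces synthetic
ordinary and osteon-in-osteon networks matched to the measured structural
statistics (canalicular length density ~0.081 um/um^3, mean node degree 3.6,
node density ~0.015 1/um^3, osteon radius ~104 um, 40 um slab).

## Worked example

```r
library(lcnflow)

net <- generate_osteon(generator_params("ordinary", seed = 1))
summary(net)
#> Osteon LCN network (ordinary)
#>   nodes: 16189 (49 lacunae, 494 haversian, 1394 cement)
#>   edges: 29140, total canalicular length 96901.8 um
#>   geometry: On.Rd 104 um, HCa.Rd 36 um, slab 40 um
#> ...
#>  canalicular_length_density            mean_node_degree
#>                  0.08100000                  3.59997529

sol <- solve_strain_sources(net)   # approach 2, exercise strain rate
summary(sol)
#> LCN flow solution (strain_sources)
#>   strain rate 0.015 1/s, V_OLCN 2.304e+04 um^3
#>   flux into Haversian canal: 345.7 um^3/s
#>   mean |velocity| (length-weighted): 4.832 um/s
#>   shear stress: median 0.781 Pa, max 64.3 Pa

intrinsic_permeability(net, solve_fixed_pressure(net))
#> Intrinsic osteon permeability
#>   mean velocity (length-weighted): 0.588 um/s
#>   wall thickness: 68 um at 1.3e+04 Pa
#>   k_osteon: 3.26e-18 m^2
```

The flux into the canal equals the strain rate times the mobilised pore
volume exactly (mass conservation); the median shear stress of ~0.8 Pa sits
inside the 0.4–2 Pa band where in-vitro studies report osteogenic responses
of osteocyte-like cells. A full cohort comparison (8 ordinary vs 9
osteon-in-osteon networks, both approaches, rank-sum tests) is one call:

```r
report <- run_pipeline(run_config(seed = 1))
print(report)
```

A command-line wrapper with `generate`, `solve`, `analyze` and `run-all`
subcommands is installed under `inst/scripts/lcnflow`.

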