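---
title: "Hydraulic network modelling of osteonal lacunocanalicular fluid flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic network modelling of osteonal lacunocanalicular fluid flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnflow)
```

## The model

Compact bone is perfused by an interstitial fluid that occupies the
lacunocanalicular network (LCN): ellipsoidal lacunae housing osteocyte cell
bodies, connected by sub-micron canaliculi housing their processes. When bone
is loaded, the pore space is compressed and fluid moves; the wall shear
stress this flow exerts on the osteocyte processes is the leading candidate
stimulus for bone mechanosensation. `lcnflow` models one osteon's LCN as a
hydraulic circuit.

The network is a spatial multigraph: nodes (lacunae, canalicular branch
points, endpoints) carry 3D positions in µm; edges (canaliculi) carry arc
lengths $l_j \ge$ chord length. Each canaliculus conducts Darcy flow through
the annulus between the cell process and the canalicular wall,

$$C_{jj} = \frac{k_{p,\mathrm{eff}}}{\mu}\,\frac{A}{l_j},\qquad
  A = (Ca.Rd^2 - CP.Rd^2)\,\pi ,$$

and mass balance at every node (Kirchhoff's current law) combined with
Darcy's law yields the weighted-Laplacian system $L\,p = A^{\!\top} C\, b + f$
with $L = A^{\!\top} C A$, where $A$ is the oriented edge–node incidence
matrix, $f$ holds nodal flow sources and $b$ edge pressure sources. Pressures
are defined up to a constant, so all canal-surface nodes are merged into one
reference supernode held at zero — physically, the Haversian canal is a
well-mixed low-pressure reservoir — and the system is solved on the reduced
Laplacian with that row and column removed. The supernode exists only at
solve time; it is never serialized.

Edge orientation is the stored endpoint order; conductivities are stored
positive and flows are computed as $q_j = C_{jj}(p_{\mathrm{tail}} -
p_{\mathrm{head}})$, so fluid always runs from high to low pressure and
flipping an edge's stored orientation merely negates its signed flow (a
property the test suite checks explicitly). Velocities are $v_j = q_j / A$
and the shear stress on the process membrane is $\tau = \mu K |v|$.

### Physical parameters

| parameter | default | units | role |
|---|---|---|---|
| $\mu$ | 1.06e-3 | Pa s | bone-fluid viscosity |
| $Ca.Rd$ | 157.5 | nm | canalicular radius |
| $CP.Rd$ | 73 | nm | cell-process radius |
| $A$ | derived, 0.0612 | µm² | annular flow cross-section |
| $k_{p,\mathrm{eff}}$ | 1.53e-17 | m² | effective canalicular permeability (Brinkman value for the fiber-filled pericellular annulus) |
| $K$ | 465 | µm⁻¹ | shear constant, $\tau = \mu K v$ |
| $\dot\epsilon$ | 0.015 | s⁻¹ | volumetric strain rate (peak exercise; walking is tenfold lower) |
| $V^{\mathrm{lacuna}}$ | 350 | µm³ | lacunar pore volume |

$A$ is recomputed from the radii; an explicit override is accepted only
within 2% of the derived value. Internally everything is computed in
µm–Pa–s, in which velocities come out directly in µm/s; permeabilities are
reported in m². The conversions are centralized and covered by unit tests in
both directions.

## The two boundary conditions

**Approach 1 — intrinsic permeability.** A fixed trans-osteonal pressure
difference: cement-line nodes are held at $\Delta p = 13$ kPa, the canal at
0, interior nodes satisfy source-free mass balance. We implement this as a
Dirichlet problem rather than as literal edge pressure sources $b = A\,
p_{\mathrm{fix}}$ with $f = 0$: the literal form, applied at dead-end cement
terminals where no flux may enter, admits the trivial uniform solution and no
through-flow, which contradicts the intended continuous pressure drop across
the osteon wall. The Dirichlet reading pins the boundary values and lets the
boundary supply whatever flux the network draws. Interior pressures then obey
the discrete maximum principle, $0 \le p \le \Delta p$, which the acceptance
suite asserts exactly at the boundary values. The intrinsic permeability is
$k_{\mathrm{osteon}} = \bar v\,\mu\,\Delta R/\Delta p$ with $\bar v$ the
*length-weighted mean of absolute velocities* $\sum |v_j| l_j / \sum l_j$.
Absolute values matter: signed averaging would cancel antiparallel canaliculi
and break the exact spoke-osteon limit $k_{\mathrm{osteon}} = k_{p,\mathrm{eff}}$.
$\Delta R$ is taken as $On.Rd - HCa.Rd$ from the metadata (for concentric
circular geometry; both are overridable for irregular osteons).

**Approach 2 — deformation-driven flow.** Homogeneous compression at
volumetric strain rate $\dot\epsilon$ makes every node a source
$f_i = \dot\epsilon\,(\tfrac{\deg_i}{2} A + V_i^{\mathrm{lacuna}})$, where
$\deg_i$ is the *weighted* node degree (summed incident arc length): each
canaliculus contributes half its annular volume to each endpoint, and lacunae
add their pore volume (a per-node `lacuna_volume` column can override the
constant). The canal reference absorbs the total: because the reference row
is removed, global balance holds by construction, and the solved flux into
the supernode equals $\dot\epsilon\,V^{\mathrm{OLCN}}$ with
$V^{\mathrm{OLCN}}$ defined as the summed pore volume of the *solved* nodes —
the reference's own half-volumes are never injected, which is exactly the
convention under which the chain fixture has the closed form
$v_k = \dot\epsilon\, l\,(k - \tfrac12)$ (segment $k$ counted from the sealed
end). Components with no path to the canal are excluded from the unknowns and
reported with undefined (`NA`) pressure rather than grounded — grounding them
would fabricate flow paths; they still count toward the geometric densities,
which are geometric rather than topological quantities.

A "leaking cement line" variant connects a seeded random fraction of
cement-line nodes to an external zero-pressure reservoir through a virtual
canaliculus of standard conductivity (one mean edge length). The two boundary
fluxes always sum to $\dot\epsilon\,V^{\mathrm{OLCN}}$, and the mean pressure
decreases monotonically in the leak fraction.

## Numerics

The reduced Laplacian is symmetric positive definite on the canal-connected
component; we factor it with sparse Cholesky (fill-reducing permutation) and
apply two steps of iterative refinement, which pushes per-node Kirchhoff
residuals to the representation floor. That floor is worth stating: flows are
reconstructed as $C(p_i - p_j)$, and since each stored pressure carries
relative rounding error, nodes whose incident flows nearly cancel retain
residuals of order $\varepsilon \sum_j C_j \max|p|$ — a few times $10^{-14}$
µm³/s on full osteons — which no solver can remove. The test suite asserts
the per-node balance against the local flow scale plus exactly this floor,
while global conservation (canal influx vs. total source injection) holds to
~1e-15 relative. A reverse Cuthill–McKee reordering of the unknowns is
available (`reorder = "rcm"`); it exists for bandwidth reduction only and is
asserted to leave the solution unchanged.

LOWESS pressure profiles use a tricube-weighted, degree-1 local regression
over the nearest 10% of points, evaluated on a uniform grid of normalized
distance (0 = canal surface, 1 = cement line, i.e. $(r - HCa.Rd)/(On.Rd -
HCa.Rd)$ for the concentric geometry). We implement the smoother directly
rather than through `stats::loess` because grid prediction with heavily tied
abscissae — nodes at discrete radii, as in the spoke oracle — degenerates
there; our window auto-widens until the weighted x-spread identifies the
local slope, and degree-1 locality makes the smoother exact on linear data
(asserted to 1e-6). Angular heterogeneity follows the 36-sector convention
(10° half-open sectors; a node exactly on a boundary belongs to the sector it
opens) and reports the population standard deviation of the sector means over
their mean. Exceedance distributions default to per-canaliculus counting
("fraction of canaliculi above $\tau$"), with length weighting available; the
confidence band is the t-based 99% interval of the mean across osteons.
Group comparisons use the two-tailed Wilcoxon rank-sum test, exact for small
samples without ties (cross-checked against full permutation enumeration).

## The synthetic generator

No LCN imaging data ship with the package, so cohorts are synthesized by a
seeded generator that emulates the first-order structural statistics of
osteonal LCNs: node number density ~0.015 µm⁻³, mean node degree 3.6,
canalicular length density 0.081 (ordinary) / 0.072 (osteon-in-osteon)
µm µm⁻³, osteon radius 104 µm, Haversian radius 36 / 22 µm, 40 µm slab.
The algorithm: (1) sample nodes uniformly in the annular slab at the target
node density; (2) collect near-neighbour candidate pairs on a spatial grid
and rank them by an effective distance that discounts radially aligned
directions (`radial_bias`, default 0.5, reflecting the predominant radial
orientation of canaliculi); (3) keep a minimum-spanning backbone under true
chord distance plus the best-ranked extras up to the edge budget implied by
the degree target; (4) attach terminal nodes on the canal surface (tagged
`haversian`) and on the cement line (dead ends, tagged `cement`) for nodes
within one spacing of each surface; (5) assign arc length = chord ×
tortuosity. The tortuosity factor defaults to automatic calibration: it is
set so the achieved arc-length density meets the target (bounded,
seed-deterministic re-draws adjust the node count if the needed factor falls
outside [1, 1.6]). At the defaults this lands within a percent of the target
length density with mean degree 3.60 and mean shortest path to the canal
around 59 µm.

The osteon-in-osteon variant carves a low-density annulus (default centred at
normalized radius 0.4, width 6 µm) and removes all gap nodes and gap-crossing
canaliculi outside a few 10°-wide angular corridors (`n_bridges`, default 3,
at seeded positions); stranded fragments are re-attached on their own side of
the gap. This reproduces the defining property of the type: the outer osteon
reaches the canal only through a few bridges, roughly doubling the mean
shortest path at matched densities.

What the generator does *not* emulate: spline curvature of individual
canaliculi, diameter variation, z-anisotropy, the tree-like radial thickening
of real osteons near the canal, or measured lacuna number densities (the
lacuna fraction defaults to ~0.3% of nodes, an order-of-magnitude assumption
the source statistics do not constrain; it is configurable). Consequently,
passing cohort tests demonstrate that the solver and analyses respond
correctly to the topological contrast between the types — they do not
reproduce specimen-level magnitudes, which depend on real network
microstructure. On our synthetic ordinary osteons the intrinsic permeability
comes out near $3\times10^{-18}$ m², lower than the $\sim1.1\times10^{-17}$
m² reported for imaged ordinary osteons (whose networks are more efficiently
radial than our near-neighbour graphs); the qualitative orderings — lower
fixed-pressure velocity and higher strain-driven velocity in
osteon-in-osteons, strain-driven angular heterogeneity exceeding
fixed-pressure heterogeneity — are robust across seeds. One source-value
note: the published ratio of osteon-in-osteon permeability to
$k_{p,\mathrm{eff}}$ appears twice as "72%", which is inconsistent with the
accompanying values ($4.1/15.3 \approx 27\%$); the package always reports
ratios computed from the values.

## Decisions on under-specified points

* Mean shortest path averages over **all** nodes reachable from the canal
  (lacunae are a sub-percent fraction, so restricting to lacunae is noisier);
  configurable via `path_nodes`.
* Velocity means are length-weighted everywhere for consistency with the
  $\bar v$ definition; count weighting is available.
* The osteon axis is $z$; all angular and radial computations are in the
  xy-plane; slabs span $[0, t]$ in $z$.
* Multigraphs are allowed (parallel canaliculi between one node pair);
  self-loops are rejected, as they can carry no pressure difference.
* Half-osteon velocity splits assign an edge by the normalized distance of
  its midpoint (< 0.5 is the canal half).

## Problem sizes

Default full-scale osteons have ~16,000 nodes and ~29,000 canaliculi; one
generation takes a few seconds and one solve well under a second. The test
suite runs full-scale networks where the property concerns them (the 13 kPa
bound check, the 8-vs-9 cohort comparison) and reduced radii (60–80 µm)
where only the property, not the scale, matters. The oracle-equivalence suite
solves 100 random graphs of at most 12 nodes against an independently coded
dense elimination.

## Limitations

Both boundary conditions are steady-state snapshots: no poroelastic
transients, no saturation cap on pressure (the architecture leaves room for a
pressure-limiting post-pass), no biomechanical loading detail beyond a
homogeneous strain rate, and no claim about how per-cell shear translates
into osteocyte signalling — the 0.4–2 Pa osteogenic band used in plots is an
annotation from in-vitro literature, not a computed quantity.
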