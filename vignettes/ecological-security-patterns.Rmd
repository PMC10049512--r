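---
title: "Ecological security patterns from habitat quality, least-cost corridors and circuit theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological security patterns from habitat quality, least-cost corridors and circuit theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecocircuit)
```

`ecocircuit` chains six analyses that together delineate a landscape
ecological security pattern: where the habitat worth protecting is, how
species are expected to move between its cores, where that movement is
squeezed or blocked, and how those findings translate into a four-class
protection zoning. Every stage operates on a plain single-band raster
(`eco_grid`) and all stages share one movement-cost kernel, so the
least-cost and circuit layers are mutually consistent. This vignette
explains the models, the defaults, and the judgement calls.

## The raster data model

All layers are north-up matrices with a cell size in metres and an
upper-left origin; distances are centre-to-centre Euclidean. Cellwise
operations between layers demand exact alignment (shape, cell size,
origin) and fail loudly otherwise — a deliberate choice, since silent
resampling is the classic source of corrupt overlay analyses. File I/O
uses the ESRI ASCII Grid format: a plain-text header (`ncols`, `nrows`,
`xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) over whitespace-
separated values, readable by every GIS. Buffering is done in raster
space with an exact Euclidean distance transform (the two-pass
lower-envelope algorithm), not vector buffering: the pipeline is
raster-native throughout and the zoning buffers (0.5–2 km) are coarse
relative to any sensible cell size.

## Habitat quality and ecological sources

Habitat degradation at cell $x$ with land-cover class $j$ accumulates
over threat layers $r$:

$$D(x) \;=\; \sum_r \frac{w_r}{\sum_r w_r}\; i_r(x)\; S_{jr},$$

where $i_r$ decays with the distance $d$ to the nearest threat cell —
linearly, $\max(0,\,1-d/d_{max})$, or exponentially,
$e^{-2.99\,d/d_{max}}$, both reaching zero at the maximum impact
distance $d_{max}$. Quality then follows the half-saturation form

$$Q \;=\; H_j\!\left[1-\frac{D^z}{D^z+k^z}\right],$$

so an undisturbed cell scores its class suitability $H_j$ and a cell
with $D=k$ scores half of it. Defaults: $k=0.5$, $z=2.5$ (the customary
habitat-quality model constants; the sensitivity of results to them is
mild because classification is by rank), exponential decay for
point-like threats (settlements at weight 1 / 5 km, mining at 0.8 /
3 km), linear decay for roads (0.6 / 2 km). Forest and water are full
habitat ($H=1$), wetland 0.9, shrubland 0.8, grassland 0.7; cultivated
land is semi-habitat at $H=0.3$; artificial surfaces and bare land are
(near) non-habitat. All of these are plain data-frame columns a user can
replace wholesale.

Quality is cut into five ordered levels by Fisher–Jenks natural breaks —
the exact dynamic-programming optimum, not a heuristic, with the break
search running on a deterministic thinning of the sorted values (cap
2000) for large rasters. Ecological sources are the 8-connected patches
of the top level whose area **strictly** exceeds 2 km²; 8-connectivity
maximizes the merging of adjacent habitat, and the strict inequality
follows the "greater than" reading of the area rule.

## Pattern metrics and the working grain

`grain_sweep()` coarsens the land cover by majority rule (ties to the
smallest class code) and recomputes six landscape-level indices — NP,
DIVISION, LSI, SHDI, CONTAG, SPLIT — under their standard FRAGSTATS
definitions, since the printed formulations of these indices in the
source literature are frequently garbled typographically. DIVISION and
SPLIT are algebraically locked ($\mathrm{DIVISION} = 1 - 1/\mathrm{SPLIT}$),
which the tests assert on random maps. `select_grain()` returns the
grain at the elbow (largest positive second difference) of the NP curve:
patch counts fall steeply while coarsening merges nearby fragments and
flatten once the landscape's backbone structure is reached. The choice
is advisory — buffers and thresholds take their grain from configuration,
not from the sweep.

## Resistance surfaces

Movement resistance is a weighted sum over five factors: land cover
(weight 0.4) and slope, surface undulation (focal max−min of the DEM,
window half-width 1 cell), and distance to grade-I and grade-II roads
(0.15 each), with separate per-bin coefficients for small (<300 g) and
large (>300 g) mammals. Bins are closed-left/open-right, matching their
printed notation; slope uses Horn's 3×3 method. The integrated surface
is the **cellwise maximum** of the two group surfaces, so it is
conservative for both guilds; all path accumulation runs on it. Useful
arithmetic facts, all recomputed by the acceptance script: the analytic
extrema are small ∈ [1.15, 353.75] and large ∈ [1.00, 355.50], and the
smallest achievable integrated value over all factor-bin combinations is
1.40.

## Corridors

Cost-weighted distance (CWD) from each source patch is a Dijkstra run on
the lattice with edge cost $\;c\cdot g\cdot (r_i+r_j)/2$ ($c$ = cell
size, $g=1$ for rook moves, $\sqrt2$ for diagonal; default
8-connectivity). Source pairs to link are those whose cost-allocation
(CWD-Voronoi) regions share a lattice edge. Per pair, the least-cost
distance is $\mathrm{LCD}=\min(\mathrm{CWD}_A+\mathrm{CWD}_B)$, the
corridor is the swath where $\mathrm{CWD}_A+\mathrm{CWD}_B-\mathrm{LCD}$
stays below a cutoff (default $5\times$ cell size $\times$ mean
resistance, which scales with the landscape), and one optimal path is
extracted as a deterministic Dijkstra shortest path between the two
source supernodes. Tie-breaking among equal-cost paths is delegated to
the deterministic traversal order of the solver rather than an explicit
row/column backtrack rule; either convention is arbitrary, and the
solver's is simpler to keep exactly reproducible.

Corridors split into **key** and **potential** by membership in the
minimum spanning tree of the source graph under LCD weights (Kruskal,
ties by lower LCD then pair id). The MST is the reproducible reading of
a "network backbone vs redundant alternatives" distinction; the
classifier is a pluggable function if another convention is wanted.

## Circuit currents and pinch points

The same lattice, with conductances $1/\mathrm{cost}$, becomes a
resistor network; each source patch collapses to a supernode (parallel
conductances summing — total boundary conductance is preserved, as the
tests check). For every adjacent pair, unit current is injected and the
reduced graph-Laplacian system solved sparsely; per-cell current is half
the sum of absolute incident edge currents, and Kirchhoff residuals at
non-terminal nodes are checked below $10^{-8}$ on every fixture solve.
The lattice defaults to 4-connectivity to keep the planar current
interpretation clean (diagonal edges carry $\sqrt2$-scaled cost where
enabled). Pinch points are the 8-connected regions inside the corridor
mask whose cumulative current reaches the 95th in-mask percentile —
the percentile is configuration, since any current threshold makes the
pinch count threshold-dependent — with source cells excluded because
their current reflects the injection, not a landscape constriction.

## Barriers

A circular moving window (diameter 500 m; the source description of
whether 500 m is radius or diameter is self-contradictory, so the
diameter is the single knob) slides on a stride lattice over a band
around each corridor (the corridor mask dilated by one window diameter;
full-grid scanning is a flag). Each window hypothetically restores its
cells to the landscape's minimum resistance — implemented as
$\min(r, r_{restored})$ so restoration can never raise a cell's
resistance, which makes $\Delta\mathrm{LCD}= \mathrm{LCD}_0-\mathrm{LCD}_1 \ge 0$
a structural guarantee — and the link's LCD is recomputed **exactly**
(a fresh Dijkstra with modified edge weights), affordable at desk scale
and free of the approximation error of summed-CWD shortcuts. The
improvement score $IS=\Delta\mathrm{LCD}/D$ is a cost-per-metre
improvement density; the top 10% of windows by IS (ties at the cut-off
included) union into the barrier regions.

## Zoning

The default table-driven rules: the Primary Protected Zone takes the
sources plus 1 km around pinch regions and 0.5 km around key corridors;
the Eco-Regulation Zone takes 1 km around barrier regions plus cells
with $IS>0.10$, restricted to cultivated/artificial cover; the Secondary
Protected Zone takes 0.5 km around potential corridors plus 2 km around
sources, restricted to habitat cover; everything else is Living
Production. Precedence PPZ > ERZ > SPZ > LPZ resolves overlaps (the rule
table's row order; no other resolution is stated anywhere). An
alternative rule-set zones SPZ/ERZ directly from IS bands
($0.05<IS\le0.15$ and $0<IS\le0.05$) because the narrative re-derivation
of the zones conflicts with the rule table; both ship, selectable via
`default_zoning_rules(variant=)`, with the table rules as default. Area
accounting multiplies cell counts by the cell area, so district rows,
zone columns and the grand total reconcile exactly by construction.

## The synthetic landscape generator

`generate_landscape()` emulates the statistical structure the analysis
needs, not any particular basin: blobby multi-class land cover from
rank-uniformized Gaussian-smoothed noise cut at class-mix quantiles;
water and forest cores stamped as discs, placed one-per-block on a
stratified partition (with an interior margin that makes cores disjoint
by construction) and sized 15% above the requested minimum area so
source extraction always has material; a smooth DEM scaled to the relief
amplitude; roads as rasterized random walks in separate masks (roads are
distance factors and threats, not cover classes); threats derived as
settlement = artificial cover, mining = bare land, road = road cells.
One master seed spawns per-layer substreams, so adding a layer never
perturbs earlier ones, and identical specs are bit-identical. Core
areas are *netted out* of the water/forest noise quantile bands, so
realized class fractions track the requested mix to well within a
percentage point.

What the generator does **not** emulate: hydrological realism (rivers do
not flow downhill), road network topology, autocorrelated threat
placement, or any calibration to a real region's class mix. Passing
tests on synthetic stacks therefore demonstrates algorithmic
correctness and end-to-end coherence, not predictive validity on real
GIS data.

`worked_toy()` is the fixed 60×100 fixture used across the tests: two
4.86 km² cores (water west, forest east) separated by artificial-surface
walls with a single grassland neck, a grade-I road crossing the neck and
a grade-II road along the southern edge. Its 90 m cell size is a
deliberate didactic grain — at 30 m, two >2 km² sources cannot fit a
60×100 grid — and it makes the expected answers knowable by
construction: the corridor and the pinch regions must lie in the neck,
and the top barrier window must overlap the road.

```{r toy, eval = FALSE}
m <- run_pipeline(default_pipeline_config(seed = 1))
c(sources = m$n_sources, key = m$n_key_corridors,
  pinch = m$n_pinch_regions, barriers = m$n_barrier_regions)
#>  sources      key    pinch barriers
#>        2        1        6        1
```

## Numerical choices and problem sizes

* Dijkstra and MST run through igraph; the Laplacian solves use sparse
  Cholesky/LU from Matrix with a grounded node, and residuals are
  verified rather than assumed.
* Allocation ties break to the lower source id; coarsening ties to the
  smaller class code; Jenks is exact DP; every stochastic step draws
  from an explicit seed. Reruns are bit-identical.
* Degenerate inputs fail early with typed messages: fewer distinct
  values than Jenks classes, empty source sets (the pipeline exits with
  status `"no_sources"` rather than crashing), infeasible core requests,
  non-positive resistances.
* The shipped analyses run at sizes a laptop handles in seconds to a few
  minutes: the toy (60×100 at 90 m) end-to-end in seconds, the study
  landscape at 180×180 cells of 90 m (16.2 km extent) with a 4-cell
  barrier stride. The 90 m grain is also a modelling choice: threat
  impact distances of 2–5 km need a landscape extent well beyond them,
  otherwise degradation blankets the map and no top-quality patch
  clears the 2 km² source threshold.

## Known limitations

Only terrestrial, lattice-based movement is modelled; corridor width is
a cutoff, not an optimized quantity; the circuit solver is a plain
sparse factorization (fine to ~10⁵ cells, no multigrid); pinch and
barrier *counts* are threshold-dependent by nature and should be read
together with their thresholds, which the manifest records. GeoTIFF
I/O is not provided — the ASCII grid keeps the package dependency-free
and its outputs diffable; any GIS can convert.
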