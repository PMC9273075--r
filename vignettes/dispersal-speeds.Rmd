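---
title: "Modelling terrain-dependent dispersal speeds from radiocarbon dates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling terrain-dependent dispersal speeds from radiocarbon dates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cropwave` estimates how fast a dispersal front — here, the southwest Asian
Neolithic crop package of wheat, barley and companion crops moving east
towards South Asia — advanced through different kinds of terrain, using
radiocarbon dates as the observations.

The front is modelled as in classic wave-of-advance work, with one twist:
instead of a single constant speed, each terrain class (biome) `k` gets a
relative friction cost `c_k`. A cell of class `k` is crossed at local speed

    v_k = v0 / c_k        (v0 = base speed, 1 km/yr by default)

so cost 1 is neutral, cost 0.5 doubles the local speed and cost 2 halves
it. Given per-class costs, the *accumulated cost distance* `D(x)` of every
cell from an origin site is the shortest weighted path on the grid graph,
and the simulated arrival date is linear in it:

    t(x) = t0 - D(x) / v0      (years cal BP; later arrivals = smaller BP)

The observations are the medians of the calibrated radiocarbon dates of
sites attributed to the dispersal. A cost vector is scored by the RMSE (in
years) between simulated arrivals and those medians, and a genetic
algorithm searches cost space for the minimum. The fitted costs convert
directly into per-biome front speeds — the quantity of interest.

Key assumptions worth keeping in mind:

* a single origin and a single, monotone front: no backflow, no multiple
  centres (the origin site is a configuration choice; the two natural
  candidates in the study corridor are Mureybet and, as the documented
  alternative, Dhra);
* friction is constant in time and piecewise-constant in space (one cost
  per biome class);
* the observed median calibrated date of a site's earliest attestation is
  an unbiased, independent reading of the front's arrival there.

## Cost-distance accumulation

Distances are computed by Dijkstra's algorithm on a 16-direction stencil:
the 8 queen neighbours plus the 8 knight's-move offsets, with step lengths
1, √2 and √5 cells. The knight's moves make the reachable set much closer
to circular under uniform cost than an 8-neighbour stencil (which
overestimates distances off the 8 principal directions by up to ~8%).

The edge weight between adjacent cells `a`, `b` is

    w(a, b) = euclid(a, b) * (f(a) + f(b)) / 2

with `f(c)` the friction of the cell's class and `euclid` the step length
in km. Averaging the two endpoint frictions is the standard midpoint rule
for crossing a class boundary; for knight's moves the same two-endpoint
mean is used rather than averaging over the intermediate cells the chess
move "jumps" — a simpler, fully documented rule whose difference is
second-order when friction is constant within whole biomes. The
implementation (`accumulate_cost()`) is an indexed-heap Dijkstra in C++;
an independent reference (`reference_cost_distance()`) builds the explicit
edge list and defers to `igraph::distances()`, and the test suite holds the
two to 1e-9 relative agreement on randomized grids.

Numerical/degenerate-input choices:

* **Cost floor** `ε = 0.01`: non-positive friction has no shortest-path
  meaning (it would be infinite local speed), so costs are clamped to ε
  wherever the optimiser or user could produce smaller values, and
  `accumulate_cost()` refuses costs below the floor outright.
* **Nodata** cells are impassable; cells cut off by nodata get `D = Inf`
  and sites on them are excluded from the fitness (and counted), never
  imputed.
* **Site sampling** is nearest-cell: `D` is a path quantity and
  interpolating it across a class boundary is ill-defined.
* Rasters must be **projected with square cells in km** (the base speed is
  km/yr). The package reads ESRI ASCII grids; project your biome layer
  upstream (any GIS will write this format). For the self-contained
  synthetic fixtures and demos an equirectangular helper
  (`project_lonlat()`, standard parallel 30°N by default) maps lon/lat to
  km; over many degrees of latitude its cells distort, which is one reason
  real analyses should bring their own projection.

## Radiocarbon calibration

`calibrate()` uses the standard Gaussian-combination likelihood: on a
1-calendar-year grid over the curve's support, the posterior weight at age
`t` is the normal density of the measured age at mean `mu(t)` and standard
deviation `sqrt(error^2 + sigma_curve(t)^2)`, normalised to 1. One year of
grid resolution is far below dating noise (errors are tens to hundreds of
years), and the median — defined as the smallest grid age whose cumulative
probability reaches 0.5, a deterministic tie-break on plateaus — is the
only summary the fitness uses. Curve files are read in IntCal CSV layout
(`#` comments; cal BP, ¹⁴C age, error columns; descending rows resorted).

Per-site aggregation defaults to `earliest_per_site`: the arrival of the
package at a place is its earliest attestation, i.e. the included date
with the largest median. `all_dates` (one observation per determination)
is retained as an option because either convention is defensible; on
single-date sites they coincide.

The anchor date `t0` at the origin defaults to the origin site's own
earliest median (`t0 = "origin"`), keeping the model self-contained; a
fixed numeric `t0` can be configured instead, which is what the synthetic
experiments use since the generator knows the truth.

## The genetic algorithm

`run_ga()` implements the published search settings as defaults
(`ga_config()`): 500 individuals initialised gene-wise from N(1, 1) and
clamped to ε; each generation every individual is scored; the best 250 are
eligible parents; the best 50 pass unchanged (elitism, which makes the
best-RMSE trace provably non-increasing); the remaining 450 children are
produced by uniform crossover of a parent pair drawn uniformly without
replacement per pairing; with probability 20% a child has one uniformly
chosen gene perturbed by a standard-normal draw (then clamped); 20
generations.

Where the procedure's verbal description left room, the package picks the
simplest compliant scheme and sticks to it: crossover is uniform (each
gene from either parent with probability ½); the 20% mutation rate is per
child, mutating exactly one gene; parent pairs are drawn uniformly, so
selection pressure is purely truncation-based; fitness ties break by
stable order; a single integer seed makes the entire run bit-reproducible.
Clamping at ε after initialisation and mutation is a deliberate divergence
from a literal N(1, 1) draw, which produces meaningless negative frictions
about 16% of the time.

A practical note on resolution: single-gene standard-normal mutations are
coarse relative to the cost precision (~0.01) needed to drive the RMSE to
zero on noiseless data, so the search reliably finds the right *speeds*
(the tests demand 10% on noiseless and 25% on noisy data) while the final
RMSE floor after 20 generations is typically some tens of years rather
than zero. This matches the intended use — ranking and estimating
per-biome speeds — not exact interpolation of the dates.

## What the synthetic generator emulates

`synth_spec()` + `make_banded_raster()` + `simulate_sites()` build a
west-to-east corridor of K vertical biome bands with known true speeds,
place sites uniformly at random on the grid, and date them by the same
linear front model plus optional Gaussian date noise. The defaults — a
100 × 200 grid of 20-km cells (a ~4000-km corridor, matching the real
west–east extent from the Fertile Crescent to peninsular India), four
bands at true speeds {0.4, 0.8, 1.5, 2.0} km/yr spanning the range from
mountain-barrier crossings to rapid cultural diffusion, origin on the
western edge dated 10000 cal BP, base speed 1 km/yr, 60 sites — are the
package's standing parameter-recovery conditions, and the date-noise
setting of 100 years reflects typical combined dating/assignment
uncertainty.

Two design details matter for what the tests prove:

* In oracle mode (the default) the generator computes its distances with
  the independent igraph reference, not with the production C++ path, so
  recovering the truth end-to-end genuinely cross-checks the cost engine.
* `synth_c14_table()` pushes the simulated calendar dates backwards
  through an invertible toy calibration curve (`toy_cal_curve()`,
  monotone by construction), so fixtures exercise the full
  calibrate → median → fit path, not just the fit.

What the generator does **not** emulate: realistic biome geometry
(vertical bands only), clustered or preservation-biased site discovery,
calibration-curve plateaus' effect on real medians (the toy curve is
nearly linear), multiple origins, or time-varying environments. Passing
recovery tests therefore demonstrates that the estimator is consistent and
the machinery correct under the model's own assumptions — not that the
real-data speed estimates are unbiased in the presence of these
real-world complications.

## Problem sizes and runtime

The standing experiment sizes were chosen to keep a full parameter-recovery
study (5 seeds × 10,000 fitness evaluations, each a Dijkstra run over
20,000 cells) in the minutes range on a single core; unit tests use a
smaller 20 × 60 corridor with three bands. The end-to-end demo fixture
(`write_fixture()`) runs the full pipeline, including the GA at the
published settings, in well under five minutes.

## Known limitations

* One cost per biome ignores within-biome heterogeneity (rivers, coasts,
  altitude gradients); the class raster is the resolution of inference.
* The equirectangular helper projection distorts far from its standard
  parallel; bring a proper projection for real data.
* Medians discard calibration uncertainty; the fitness treats a
  tightly-dated and a loosely-dated site alike.
* The GA returns a point estimate; rerunning across seeds (cheap) is the
  pragmatic way to gauge search variability, but it is not a posterior.
* GeoTIFF I/O is not built in; convert to ESRI ASCII grids upstream.
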