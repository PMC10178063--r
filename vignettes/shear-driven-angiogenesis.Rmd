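---
title: "Shear-driven angiogenesis in reduced-order vessel networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-driven angiogenesis in reduced-order vessel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselflow)
```

## The scientific problem

In rheumatoid arthritis (RA) the inflamed synovium becomes hypervascular:
new vessels sprout from the existing network (angiogenesis), driven
chemically by vascular endothelial growth factor (VEGF) and mechanically
by the haemodynamic environment. Because wall shear stress (WSS) both
responds to and reshapes the flow field, it is widely used as a mechanical
surrogate for VEGF activity. `vesselflow` implements a desk-scale model of
this feedback loop for planar networks of straight cylindrical vessels
with the characteristic ladder-like RA branching pattern: solve the flow,
read off the WSS at vessel junctions, locate wall portions whose WSS falls
in the *junction overlap region*, sprout a new vessel there, and repeat.

## The flow model and its assumptions

Blood is treated as an incompressible Newtonian fluid
(density $\rho = 1060\ \mathrm{kg/m^3}$, dynamic viscosity
$\mu = 0.0035\ \mathrm{Pa\,s}$) in steady, laminar flow through rigid
circular cylinders with no-slip walls. Under exactly these assumptions
the three-dimensional Navier–Stokes problem in each segment reduces to
Hagen–Poiseuille flow, so the network collapses to a resistor graph:

* segment resistance $R = 8\mu L / (\pi r^4)$,
* nodal mass balance $\sum_k Q_k = 0$ at every node (the network form of
  continuity, $\nabla\cdot U = 0$),
* wall shear stress $\tau = 4\mu |Q| / (\pi r^3)$,
* mean velocity $\bar v = Q / (\pi r^2)$.

Velocity inlets prescribe a volumetric inflow $Q = v\,\pi r^2$
(mean-velocity reading of the plug inlet); pressure outlets pin gauge
pressures (0 Pa unless overridden). The sparse symmetric system in the
unknown nodal pressures is solved by direct factorisation (`Matrix`), so
there is no iterative tolerance to tune; the nodal mass residual is
*reported* in the solution object rather than assumed. Junction pressure
losses are neglected: at the operating point ($v = 0.09$ m/s,
$r = 1$ mm) the segment Reynolds number is $\approx 55$, and no loss
model is available for these geometries. Density only enters through the
Reynolds diagnostic.

This reduced-order model is exact for the stated assumptions, which is
what makes the analytic verification meaningful: solving the single
straight pipe ($r = 0.001$ m, $v = 0.09$ m/s) returns
$\tau = 1.26$ Pa, identical to the closed-form value, to machine
precision:

```{r verify}
verify_against_analytic(single_pipe_network())
```

What the model deliberately does **not** capture: pulsatility,
non-Newtonian rheology, wall distensibility, entrance and junction
effects, three-dimensional WSS contours along a vessel, and all VEGF /
hypoxia biochemistry. Consequently the spatially graded per-wall contour
ranges of a volumetric CFD solution are *not* reproducible here — each
segment carries a single WSS value — and no mesh-independence study
applies (there is no volumetric mesh).

## Binning, junction intervals, and the overlap statistic

Reported WSS ranges live on contour bins of width 0.42 Pa (every printed
endpoint in the reference tables is a multiple of 0.42; the bin width is
a `binning_scheme()` parameter, not a constant). Conventions, each forced
by a printed table row:

* **Outward snapping.** A raw range widens to the nearest enclosing bin
  edges; endpoints already on an edge stay put.
* **Edge ties go to the bin below.** A degenerate reading of exactly
  1.26 Pa belongs to $[0.84, 1.26]$, consistent with 1.26 appearing as an
  upper endpoint throughout the tables.
* **Touching is not overlapping.** The overlap
  $[\max_i \ell_i, \min_i h_i]$ must have strictly positive width; the
  variant whose junction intervals share only the point 1.260 Pa is
  reported "No overlap".
* **Stagnant-branch exclusion.** When characterising a junction, incident
  segments below the stagnation floor (default one bin width, 0.42 Pa)
  are discarded as non-flowing whenever at least one branch flows; the
  printed junction ranges do not extend down to the $5.5\times10^{-6}$ Pa
  of adjoining stagnant walls. The floor is a parameter.
* **Raw ranges are preserved** alongside snapped ones (as attributes), so
  reports can print values like 0.0000055 Pa verbatim.

The *junction overlap region* of a model is the intersection of the
snapped WSS intervals over its junction regions. One printed wall range
(0.840–2.950 Pa) is not a multiple of 0.42 — likely a typo for 2.940 —
and is stored as printed, not silently corrected.

```{r overlap}
junction_overlap_region(printed_region_samples("2A"))
junction_overlap_region(printed_region_samples("2C"))
```

### Junctions with a single flowing branch

One rule here is a deliberate package design choice. For a *solved*
network, `junction_overlap_region()` drops junctions with fewer than two
supra-floor branches (`min_active_branches = 2`). Rationale: a junction
whose other branches have stagnated is hydraulically a point along a
single vessel — there is no confluence, and a one-segment "range" is a
degenerate point whose snapped bin reflects only where that value happens
to fall. Including such junctions makes the two-iteration growth
narrative structurally impossible in the reduced-order model: mass
conservation bounds the flow split on the sprouted trunk such that the
sprout and the downstream junction's lone flowing branch can never both
clear the 0.84 Pa bin edge, so the overlap would always collapse through
a touching-endpoint intersection. With the rule, the default run
reproduces the documented 3-wall → 4-wall → 5-wall sequence. Set
`min_active_branches = 0` to recover the literal all-junctions
intersection. Table-driven overlaps (external sample files, printed
rows) always use every junction region.

## The growth engine

Each iteration: solve → overlap → candidate walls → select → sprout.
A wall qualifies when its snapped WSS interval meets the overlap with
positive width and its peak WSS exceeds the stagnation floor. Knobs in
`growth_policy()`, with defaults and why:

| parameter | default | reason |
|---|---|---|
| `sprout_length` | 0.05 m | stated construction length of new vessels |
| `sprout_radius` | 0.001 m | all vessels share the 1 mm radius |
| `max_iterations` | 2 | the reference procedure was "repeated twice" |
| `attach_fraction` | 0.5 | mid-wall attachment matches the figures |
| `terminal_bc` | outlet, 0 Pa | new sprouts discharge to the venous side |
| `site_selection` | `newest_wall` | see below |

Where the source material is silent, the engine makes explicit,
deterministic choices:

* **Site selection.** No rule is stated for choosing among several
  qualifying walls (wall 3 was chosen, then wall 4). `newest_wall`
  prefers the most recently created wall and breaks ties among coeval
  walls by descending numeric label, which reproduces that sequence; two
  alternative policies (`no_existing_junction`,
  `closest_to_overlap_centre`) are provided. This is a package
  convention, not a claim about the original study.
* **Attachment fallback.** `attach_fraction = 0.5` of a wall whose
  midpoint is an existing junction (the starter model's top wall) is
  unusable — attaching *at* a node would violate the
  two-segments-per-iteration bookkeeping — so the engine falls back to
  the midpoint of the first qualifying constituent segment, in
  arc-length order.
* **Side selection.** The sprout leaves perpendicular to its parent, on
  the side pointing away from the network centroid (prevents
  self-intersection). In our planar layout this sends the second sprout
  left, where the original figures show the final vessel of one variant
  developing to the right; the regression surface therefore compares
  wall/junction counts and parent identity, never coordinates.

```{r growth}
tr <- run_growth(build_fixture("1C")$network)
tr
compare_topology(tr, list("1D", "1E"))
```

## Fixtures and the synthetic generator

The ten fixture geometries are deterministic code. Horizontal trunk
lengths are not printed and are fixed at 0.1 m (the verified
single-vessel length), with the two trunks 0.05 m apart (the sprout
length); inlet/outlet placements for variants described only in figures
(1A, 1B, 1F, 1G, 2C) and the entire 6-wall/6-junction geometry of the
second model family are best readings, flagged in each fixture's
`notes`, and overridable through the network file format — boundary
conditions are data, not code.

`generate_ladder_network()` emulates the same morphology with `n`
rungs at seed-deterministic positions (uniform in the middle 70 % of the
trunk, keeping rungs off the terminals), parallel-flow boundary
conditions by default. `generate_region_samples()` draws WSS samples
uniformly from known true intervals plus optional truncated-Gaussian
noise (default 0 — the flow model it stands in for is deterministic; the
noise knob is synthetic-only). A green test on these generators
establishes that the solver, binning and overlap machinery behave as
specified on networks *of this class*; it says nothing about image-derived
geometries, 3-D contour structure, or measurement noise in real CFD
exports.

## Numerical choices

* Direct sparse factorisation; residual reported (tests require
  $\le 10^{-12}\times$ total inflow).
* Bin-edge comparisons use a relative tolerance of $10^{-9}$; overlap
  width must exceed $10^{-12}$ Pa to count as positive.
* Segment lengths must equal endpoint distances to $10^{-9}$ relative.
* Zero-inlet-speed networks are solvable (everything is zero); strict
  speed positivity is enforced only by the optional physiological
  validation, which also checks the 0.1–10 mm diameter window.
* Degenerate inputs fail loudly and early: missing pressure reference or
  a disconnected component without an outlet are solver errors naming
  the offending component; malformed files report the missing field or
  offending row.

## Known limitations

Single-value WSS per segment (no axial contour structure); planar
geometries only; no anastomosis, regression, or radius adaptation during
growth; no chemical coupling (VEGF, hypoxia); steady flow only. These
mirror the stated limitations of the modelling approach the package
implements, plus the simplifications introduced by the reduced-order
substitution itself.
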