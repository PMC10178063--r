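# vesselflow

Reduced-order hemodynamics and shear-driven angiogenesis for planar
networks of cylindrical blood vessels.

## Who this is for, and what it does

In rheumatoid arthritis the synovium becomes hypervascular: new vessels
sprout from a ladder-like network, and wall shear stress (WSS) is widely
used as a mechanical surrogate for the VEGF signalling that drives the
sprouting. `vesselflow` is for researchers who want a fast, fully
deterministic desk-scale model of that loop — no volumetric CFD required.

The core model: steady, laminar, Newtonian flow in rigid circular
cylinders is *exactly* Hagen–Poiseuille flow, so a vessel network is a
resistor graph,

* segment resistance `R = 8 μ L / (π r⁴)` (Pa·s/m³),
* nodal mass balance `Σ Q = 0` at every node,
* wall shear stress `τ = 4 μ |Q| / (π r³)` (Pa),

with velocity inlets prescribing `Q = v π r²` and pressure outlets fixing
gauge pressures. On top of the solver sit the analysis statistics: WSS
ranges snapped to 0.42 Pa contour bins, per-junction intervals (stagnant
branches excluded), and the **junction overlap region** — the
intersection of all junction intervals — which marks the shear window in
which new vessels sprout. An iterative growth engine solves, finds wall
portions inside the overlap, sprouts a perpendicular 0.05 m vessel, and
repeats. Synthetic generators (ladder networks, labelled WSS samples with
known ground truth) make every stage testable offline.

## Worked example

```r
library(vesselflow)

# analytic verification: a straight 1 mm vessel at 0.09 m/s
verify_against_analytic(single_pipe_network())
#> $tau_solver
#> [1] 1.26
#> $tau_analytic
#> [1] 1.26
#> $relative_error
#> [1] 0
```

1.26 Pa is the wall shear stress of the verification pipe — the solver
and the closed-form Hagen–Poiseuille value agree to machine precision,
and the value sits inside the 0.6–4 Pa arterial window.

```r
# the three-vessel starter model: two trunks + a near-stagnant connector
sol <- solve_network(build_fixture("1C")$network)
report_model_table(sol)
#>     location region_kind wss_raw_low wss_raw_high   wss_range junction_overlap velocity_range
#> 1 junction_1    junction        1.26         1.26 0.840-1.260      0.840-1.260     0.055-0.11
#> 2 junction_2    junction        1.26         1.26 0.840-1.260      0.840-1.260     0.055-0.11
#> 3     wall_1        wall        1.26         1.26 0.840-1.260                      0.055-0.11
#> 4     wall_2        wall        0.00         0.00 0.000-0.420                         0-0.055
#> 5     wall_3        wall        1.26         1.26 0.840-1.260                      0.055-0.11
```

Both trunks carry 1.26 Pa; the vertical connector (wall 2) is stagnant
and excluded from the junction intervals, so the junction overlap region
is **0.840–1.260 Pa**: sprouting is allowed only where wall shear falls
in that window.

```r
# two iterations of shear-driven growth
tr <- run_growth(build_fixture("1C")$network)
tr
#> <growth_trace> 2 sprouting event(s); stopped: max_iterations
#>   it 1: wall_3 -> wall_4 at f=0.250 (overlap 0.840-1.260)
#>   it 2: wall_4 -> wall_5 at f=0.500 (overlap 0.840-1.260)

compare_topology(tr, list("1D", "1E"))
#>   iteration walls walls_expected junctions junctions_expected parent_wall match
#> 1         1     4              4         3                  3      wall_3  TRUE
#> 2         2     5              5         4                  4      wall_4  TRUE
```

The network grows 3 → 4 → 5 walls (2 → 3 → 4 junctions), the second
sprout parented on the first sprout's wall — the documented growth
sequence, reproduced deterministically.

There is also a command-line interface (`vesselflow_main()`, installed as
`exec/vesselflow`): `fixture`, `solve`, `analyze`, `grow`, `verify`.

```sh
Rscript -e 'vesselflow::vesselflow_main(commandArgs(TRUE))' verify
# tau_solver_pa   1.26
# tau_analytic_pa 1.26
# relative_error  0.000e+00
```

## Documentation

`vignettes/shear-driven-angiogenesis.Rmd` describes the model and its
assumptions, the binning and overlap conventions (and the printed table
rows that force them), the growth-policy knobs, what the synthetic
generators do and do not emulate, numerical choices, and known
limitations.
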