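Package: vesselflow
Title: Reduced-Order Hemodynamics and Shear-Driven Angiogenesis in
    Vessel Networks
Version: 0.1.0
Authors@R:
    person("vesselflow", "maintainers", role = c("aut", "cre"),
           email = "maintainers@vesselflow.invalid")
Description: Steady, laminar, Newtonian blood flow in rigid cylindrical
    vessel networks solved as a Poiseuille resistance network with nodal
    mass balance, yielding per-segment flow rate, mean velocity and wall
    shear stress.  Includes wall-shear-stress contour binning and the
    junction-overlap statistic used to locate candidate sprouting sites,
    an iterative vessel-sprouting (angiogenesis) engine, deterministic
    fixture geometries for ladder-like rheumatoid-arthritis vessel
    networks, synthetic network and sample generators with known ground
    truth, and command-line entry points for solving, analysing and
    growing networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
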