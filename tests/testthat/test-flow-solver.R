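fluid <- fluid_properties()

test_that("segment resistance follows the Poiseuille law", {
  # 8 * 0.0035 * 0.1 / (pi * 0.001^4), frozen from a hand evaluation
  expect_equal(segment_resistance(0.001, 0.1, fluid), 891267681.3,
               tolerance = 1e-6)
  r0 <- segment_resistance(0.001, 0.1, fluid)
  expect_equal(segment_resistance(0.001, 0.2, fluid), 2 * r0)
  expect_equal(segment_resistance(0.0005, 0.1, fluid), 16 * r0)
  expect_error(segment_resistance(-0.001, 0.1, fluid), "radius")
  expect_error(segment_resistance(0.001, 0, fluid), "length")
})

test_that("the straight pipe reproduces the analytic wall shear", {
  sol <- solve_network(single_pipe_network(), fluid)
  expect_equal(sol$segments$wall_shear, 1.26, tolerance = 1e-12)
  expect_equal(sol$segments$mean_velocity, 0.09, tolerance = 1e-12)
  expect_lte(sol$residual, 1e-12 * sol$total_inflow)
  # pressure drop = Q * R
  q <- 0.09 * pi * 0.001^2
  expect_equal(sol$nodes$pressure[sol$nodes$id == "in"],
               q * segment_resistance(0.001, 0.1, fluid), tolerance = 1e-12)

  zero <- solve_network(single_pipe_network(inlet_speed = 0), fluid,
                        validate = FALSE)
  expect_true(all(zero$segments$flow_rate == 0))
  expect_true(all(zero$segments$wall_shear == 0))
})

test_that("wall_shear_from_flow and reynolds_number match hand values", {
  q <- 0.09 * pi * 0.001^2
  expect_equal(wall_shear_from_flow(q, 0.001), 1.26, tolerance = 1e-12)
  expect_identical(wall_shear_from_flow(0, 0.001), 0)
  expect_equal(wall_shear_from_flow(2 * q, 0.001),
               2 * wall_shear_from_flow(q, 0.001))
  expect_equal(wall_shear_from_flow(-q, 0.001),
               wall_shear_from_flow(q, 0.001))
  expect_error(wall_shear_from_flow(q, 0), "radius")
  # rho * v * 2r / mu, frozen from hand evaluations
  expect_equal(reynolds_number(0.09, 0.001, fluid), 54.5142857,
               tolerance = 1e-6)
  expect_equal(reynolds_number(0.19, 0.001, fluid), 115.0857143,
               tolerance = 1e-6)
  expect_identical(reynolds_number(0, 0.001, fluid), 0)
})

test_that("a symmetric Y-junction splits the inlet flow in half", {
  sol <- solve_network(y_network(), fluid)
  q_in <- 0.09 * pi * 0.001^2
  qs <- sol$segments$flow_rate
  names(qs) <- sol$segments$id
  expect_equal(unname(qs["trunk"]), q_in, tolerance = 1e-12)
  expect_equal(unname(qs["d1"]), q_in / 2, tolerance = 1e-10)
  expect_equal(unname(qs["d2"]), q_in / 2, tolerance = 1e-10)
})

test_that("series and parallel resistances reproduce the closed forms", {
  q <- 0.09 * pi * 0.001^2
  ser <- solve_network(series_network(), fluid)
  r_tot <- segment_resistance(0.001, 0.04, fluid) +
    segment_resistance(0.0008, 0.07, fluid)
  expect_equal(ser$nodes$pressure[ser$nodes$id == "in"], q * r_tot,
               tolerance = 1e-10)

  dia <- diamond_network()
  sol <- solve_network(dia, fluid)
  len <- sum(dia$segments$length[dia$segments$id %in% c("u1", "u2")])
  r1 <- segment_resistance(0.001, len, fluid)
  r2 <- segment_resistance(0.0008, len, fluid)
  r_par <- 1 / (1 / r1 + 1 / r2)
  dp <- sol$nodes$pressure[sol$nodes$id == "a"] -
    sol$nodes$pressure[sol$nodes$id == "c"]
  expect_equal(dp, q * r_par, tolerance = 1e-10)
})

test_that("mass is conserved and the solution scales linearly", {
  nets <- list(build_fixture("1C")$network, build_fixture("2A")$network,
               diamond_network(), y_network())
  for (net in nets) {
    sol <- solve_network(net, fluid)
    expect_lte(sol$residual, 1e-12 * sol$total_inflow)
    # Stokes-regime linearity: scaling all inlet speeds scales everything
    k <- 2.5
    net2 <- net
    inl <- net2$nodes$bc_kind == "velocity_inlet"
    net2$nodes$bc_value[inl] <- k * net2$nodes$bc_value[inl]
    sol2 <- solve_network(net2, fluid)
    expect_equal(sol2$segments$flow_rate, k * sol$segments$flow_rate,
                 tolerance = 1e-10)
    expect_equal(sol2$segments$wall_shear, k * sol$segments$wall_shear,
                 tolerance = 1e-10)
    expect_equal(sol2$nodes$pressure, k * sol$nodes$pressure,
                 tolerance = 1e-10)
  }
})

test_that("the sparse solution matches the dense brute-force oracle", {
  nets <- c(list(single_pipe_network(), series_network(), y_network(),
                 diamond_network()),
            h_bc_variants())
  for (net in nets) {
    sol <- solve_network(net, fluid)
    ora <- oracle_solve(net, fluid)
    expect_equal(stats::setNames(sol$nodes$pressure, sol$nodes$id),
                 ora$pressure, tolerance = 1e-10)
    expect_equal(stats::setNames(sol$segments$wall_shear, sol$segments$id),
                 ora$shear, tolerance = 1e-10)
  }
})

test_that("the solution is independent of node and segment ordering", {
  net <- build_fixture("1E")$network
  perm <- net
  set.seed(42)
  perm$nodes <- perm$nodes[sample(nrow(perm$nodes)), ]
  perm$segments <- perm$segments[sample(nrow(perm$segments)), ]
  rownames(perm$nodes) <- NULL
  rownames(perm$segments) <- NULL
  a <- solve_network(net, fluid)
  b <- solve_network(perm, fluid)
  ib <- match(a$segments$id, b$segments$id)
  expect_equal(a$segments$wall_shear, b$segments$wall_shear[ib],
               tolerance = 1e-12)
  expect_equal(a$nodes$pressure,
               b$nodes$pressure[match(a$nodes$id, b$nodes$id)],
               tolerance = 1e-12)
})

test_that("missing pressure references are reported as solver errors", {
  net <- build_fixture("1C")$network
  noref <- net
  noref$nodes$bc_kind[noref$nodes$bc_kind == "pressure_outlet"] <-
    "closed_end"
  noref$nodes$bc_value[noref$nodes$bc_kind == "closed_end"] <- NA_real_
  expect_error(solve_network(noref, fluid), "validation")
  expect_error(solve_network(noref, fluid, validate = FALSE),
               "no pressure_outlet")

  # disconnected component without an outlet
  lad <- generate_ladder_network(0)
  expect_error(solve_network(lad, fluid), "validation")
})

test_that("verify_against_analytic is exact for straight pipes", {
  cases <- list(list(v = 0.09, r = 0.001), list(v = 0.19, r = 0.001),
                list(v = 0.09, r = 0.0005))
  for (cs in cases) {
    net <- single_pipe_network(radius = cs$r, inlet_speed = cs$v)
    res <- verify_against_analytic(net, fluid)
    expect_lte(res$relative_error, 1e-12)
  }
  expect_error(verify_against_analytic(build_fixture("1C")$network, fluid),
               "single straight pipe")
})

test_that("solution tables serialize with segments and nodes", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  sol <- solve_network(single_pipe_network(), fluid)
  write_solution_table(sol, tmp)
  lines <- readLines(tmp)
  expect_true(any(lines == "[segments]"))
  expect_true(any(lines == "[nodes]"))
  expect_true(any(grepl("1.26", lines, fixed = TRUE)))
})
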