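#' Fluid properties
#'
#' Blood is modelled as an incompressible Newtonian fluid.  Density does
#' not enter the steady Poiseuille network equations; it is retained for
#' Reynolds-number diagnostics.
#'
#' @param density Fluid density in kg/m^3 (default 1060, whole blood).
#' @param viscosity Dynamic viscosity in Pa.s (default 0.0035, whole blood).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, viscosity = 0.0035) {
  stopifnot(is.numeric(density), density > 0,
            is.numeric(viscosity), viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Hydraulic resistance of a cylindrical segment
#'
#' Fully developed laminar (Hagen-Poiseuille) flow in a rigid circular
#' pipe gives `R = 8 * mu * L / (pi * r^4)` in Pa.s/m^3: proportional to
#' length and to the inverse fourth power of the radius.
#'
#' @param radius Segment radius in m.
#' @param length Segment length in m.
#' @param fluid A [fluid_properties()].
#' @return Resistance in Pa.s/m^3.
#' @export
#' @examples
#' segment_resistance(0.001, 0.1)  # ~8.9127e8
segment_resistance <- function(radius, length, fluid = fluid_properties()) {
  if (!is.numeric(radius) || any(radius <= 0))
    stop("radius must be > 0")
  if (!is.numeric(length) || any(length <= 0))
    stop("length must be > 0")
  8 * fluid$viscosity * length / (pi * radius^4)
}

#' Wall shear stress from volumetric flow
#'
#' For Poiseuille flow, `tau = 4 * mu * |Q| / (pi * r^3)` (Pa).  The
#' magnitude of the signed flow is used: reported shear is non-negative.
#'
#' @param flow_rate Volumetric flow in m^3/s (signed).
#' @param radius Vessel radius in m.
#' @param viscosity Dynamic viscosity in Pa.s.
#' @return Shear stress in Pa.
#' @export
#' @examples
#' wall_shear_from_flow(0.09 * pi * 0.001^2, 0.001)  # 1.26 Pa
wall_shear_from_flow <- function(flow_rate, radius, viscosity = 0.0035) {
  if (!is.numeric(radius) || any(radius <= 0)) stop("radius must be > 0")
  if (!is.numeric(viscosity) || any(viscosity <= 0))
    stop("viscosity must be > 0")
  4 * viscosity * abs(flow_rate) / (pi * radius^3)
}

#' Segment Reynolds number
#'
#' `Re = rho * |v| * 2r / mu`; a diagnostic supporting the laminar
#' assumption (Re stays well below transition for physiological inputs).
#'
#' @param velocity Mean velocity in m/s.
#' @param radius Vessel radius in m.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(velocity, radius, fluid = fluid_properties()) {
  fluid$density * abs(velocity) * 2 * radius / fluid$viscosity
}

#' Solve steady flow in a vessel network
#'
#' Reduced-order model of steady, laminar, Newtonian flow in rigid
#' cylinders: each segment is a Poiseuille resistance, mass is conserved at
#' every node (the network form of the continuity equation), velocity
#' inlets prescribe a volumetric inflow `Q = v * pi * r^2`, and pressure
#' outlets fix gauge pressures.  The resulting sparse symmetric linear
#' system in the unknown nodal pressures is solved by direct sparse
#' factorisation; the nodal mass residual is reported, not assumed.
#'
#' @param network A valid `vessel_network` with at least one pressure
#'   outlet in every connected component.
#' @param fluid A [fluid_properties()].
#' @param validate Run [validate_network()] first (structural rules only).
#' @return An object of class `flow_solution`: `$nodes` (id, pressure in Pa
#'   gauge), `$segments` (flow_rate m^3/s signed node_a -> node_b,
#'   mean_velocity m/s, wall_shear Pa, reynolds), `$residual` (max absolute
#'   nodal imbalance, m^3/s), `$total_inflow`, and the solved `$network`.
#' @export
#' @examples
#' sol <- solve_network(single_pipe_network())
#' sol$segments$wall_shear  # 1.26 Pa
solve_network <- function(network, fluid = fluid_properties(),
                          validate = TRUE) {
  stopifnot(inherits(network, "vessel_network"))
  if (validate) {
    rep <- validate_network(network)
    if (nrow(rep) > 0)
      stop("network fails validation: ", rep$rule[1], " (", rep$subject[1],
           "): ", rep$message[1])
  }
  nd <- network$nodes
  sg <- network$segments
  n <- nrow(nd)

  comp <- node_components(network)
  out_idx <- which(nd$bc_kind == "pressure_outlet")
  if (length(out_idx) == 0L)
    stop("singular system: no pressure_outlet to provide a gauge reference")
  for (k in seq_len(max(comp))) {
    members <- names(comp)[comp == k]
    if (!any(nd$id[out_idx] %in% members))
      stop("singular system: component containing node '", members[1],
           "' has no pressure_outlet")
  }

  g <- 1 / segment_resistance(sg$radius, sg$length, fluid)
  ia <- match(sg$node_a, nd$id)
  ib <- match(sg$node_b, nd$id)

  is_fixed <- nd$bc_kind == "pressure_outlet"
  p <- numeric(n)
  p[is_fixed] <- nd$bc_value[is_fixed]

  src <- numeric(n)
  inl <- which(nd$bc_kind == "velocity_inlet")
  for (i in inl) {
    si <- which(ia == i | ib == i)
    # validated: exactly one incident segment
    src[i] <- nd$bc_value[i] * pi * sg$radius[si[1]]^2
  }

  unknown <- which(!is_fixed)
  if (length(unknown)) {
    umap <- integer(n)
    umap[unknown] <- seq_along(unknown)
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    rhs <- src[unknown]
    for (s in seq_len(nrow(sg))) {
      a <- ia[s]; b <- ib[s]
      if (!is_fixed[a]) {
        trip_i <- c(trip_i, umap[a]); trip_j <- c(trip_j, umap[a])
        trip_x <- c(trip_x, g[s])
        if (is_fixed[b]) rhs[umap[a]] <- rhs[umap[a]] + g[s] * p[b]
        else {
          trip_i <- c(trip_i, umap[a]); trip_j <- c(trip_j, umap[b])
          trip_x <- c(trip_x, -g[s])
        }
      }
      if (!is_fixed[b]) {
        trip_i <- c(trip_i, umap[b]); trip_j <- c(trip_j, umap[b])
        trip_x <- c(trip_x, g[s])
        if (is_fixed[a]) rhs[umap[b]] <- rhs[umap[b]] + g[s] * p[a]
        else {
          trip_i <- c(trip_i, umap[b]); trip_j <- c(trip_j, umap[a])
          trip_x <- c(trip_x, -g[s])
        }
      }
    }
    # aggregate duplicate triplets before assembly
    key <- paste(trip_i, trip_j)
    agg <- rowsum(trip_x, key)
    ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    A <- Matrix::sparseMatrix(i = as.integer(ij[, 1]),
                              j = as.integer(ij[, 2]),
                              x = as.numeric(agg),
                              dims = c(length(unknown), length(unknown)))
    sol <- tryCatch(Matrix::solve(A, rhs),
                    error = function(e)
                      stop("singular system: ", conditionMessage(e),
                           call. = FALSE))
    p[unknown] <- as.numeric(sol)
  }

  q <- g * (p[ia] - p[ib])
  area <- pi * sg$radius^2
  vbar <- q / area
  tau <- wall_shear_from_flow(q, sg$radius, fluid$viscosity)
  re <- reynolds_number(vbar, sg$radius, fluid)

  # nodal imbalance at every non-outlet node (signed flows vs sources)
  imb <- numeric(n)
  for (s in seq_len(nrow(sg))) {
    imb[ia[s]] <- imb[ia[s]] + q[s]
    imb[ib[s]] <- imb[ib[s]] - q[s]
  }
  imb <- imb - src
  residual <- if (any(!is_fixed)) max(abs(imb[!is_fixed])) else 0

  structure(list(nodes = data.frame(id = nd$id, pressure = p,
                                    stringsAsFactors = FALSE),
                 segments = data.frame(id = sg$id,
                                       wall_label = sg$wall_label,
                                       node_a = sg$node_a,
                                       node_b = sg$node_b,
                                       radius = sg$radius,
                                       length = sg$length,
                                       flow_rate = q,
                                       mean_velocity = vbar,
                                       wall_shear = tau,
                                       reynolds = re,
                                       stringsAsFactors = FALSE),
                 residual = residual,
                 total_inflow = sum(abs(src)),
                 network = network,
                 fluid = fluid),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> ", nrow(x$segments), " segments, residual ",
      format(x$residual, digits = 3), " m^3/s\n", sep = "")
  cat("  wall shear range: ",
      format(min(x$segments$wall_shear), digits = 4), " - ",
      format(max(x$segments$wall_shear), digits = 4), " Pa\n", sep = "")
  invisible(x)
}

#' A single straight vessel with one inlet and one outlet
#'
#' The quantitative verification geometry: a straight rigid pipe of the
#' stated radius carrying the prescribed mean inlet velocity, discharging
#' to a zero-gauge outlet.
#'
#' @param radius Pipe radius in m.
#' @param length Pipe length in m.
#' @param inlet_speed Mean inlet velocity in m/s.
#' @param outlet_pressure Outlet gauge pressure in Pa.
#' @return A `vessel_network` with one segment.
#' @export
single_pipe_network <- function(radius = 0.001, length = 0.1,
                                inlet_speed = 0.09, outlet_pressure = 0) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")
  nodes <- data.frame(id = c("in", "out"), x = c(0, length), y = c(0, 0),
                      bc_kind = c("velocity_inlet", "pressure_outlet"),
                      bc_value = c(inlet_speed, outlet_pressure),
                      stringsAsFactors = FALSE)
  segs <- data.frame(id = "p1", node_a = "in", node_b = "out",
                     radius = radius, wall_label = "wall_1",
                     stringsAsFactors = FALSE)
  vessel_network(nodes, segs, notes = "single straight verification pipe")
}

#' Verify the solver against the analytic Hagen-Poiseuille result
#'
#' Solves a single straight pipe and compares the solver's wall shear
#' stress with `tau = 4 mu Q / (pi r^3)` evaluated on the prescribed inlet
#' flow `Q = v pi r^2`.
#'
#' @param network A `vessel_network` consisting of a single segment with
#'   one velocity inlet and one pressure outlet.
#' @param fluid A [fluid_properties()].
#' @return List with `tau_solver`, `tau_analytic` (both Pa) and
#'   `relative_error`.
#' @export
verify_against_analytic <- function(network, fluid = fluid_properties()) {
  stopifnot(inherits(network, "vessel_network"))
  if (nrow(network$segments) != 1L)
    stop("verification network must be a single straight pipe")
  nd <- network$nodes
  if (sum(nd$bc_kind == "velocity_inlet") != 1L ||
      sum(nd$bc_kind == "pressure_outlet") != 1L)
    stop("verification network needs exactly one inlet and one outlet")
  sol <- solve_network(network, fluid)
  r <- network$segments$radius[1]
  v <- nd$bc_value[nd$bc_kind == "velocity_inlet"]
  q <- v * pi * r^2
  tau_an <- 4 * fluid$viscosity * q / (pi * r^3)
  tau_sv <- sol$segments$wall_shear[1]
  rel <- if (tau_an == 0) abs(tau_sv) else abs(tau_sv - tau_an) / abs(tau_an)
  list(tau_solver = tau_sv, tau_analytic = tau_an, relative_error = rel)
}

#' Write a solved network as a delimited table
#'
#' One row per segment (id, wall label, flow rate, mean velocity, wall
#' shear, Reynolds number) followed by one row per node (id, pressure),
#' tab-separated with SI units in the header comment.
#'
#' @param solution A `flow_solution`.
#' @param path Output file, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_solution_table <- function(solution, path = "") {
  stopifnot(inherits(solution, "flow_solution"))
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(paste0("# vesselflow solution; units: flow_rate m^3/s, ",
                    "mean_velocity m/s, wall_shear Pa, pressure Pa gauge"),
             con)
  seg <- solution$segments[, c("id", "wall_label", "flow_rate",
                               "mean_velocity", "wall_shear", "reynolds")]
  writeLines("[segments]", con)
  utils::write.table(seg, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("[nodes]", con)
  utils::write.table(solution$nodes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("# residual_m3s\t%.6e", solution$residual), con)
  invisible(path)
}
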