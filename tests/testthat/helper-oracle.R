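# Independent dense brute-force solver for the nodal pressure equations.
# Deliberately written against base R only (dense matrix, base::solve) so
# it shares no code path with the package's sparse solver.
oracle_solve <- function(network, fluid = fluid_properties()) {
  nd <- network$nodes
  sg <- network$segments
  n <- nrow(nd)
  cond <- pi * sg$radius^4 / (8 * fluid$viscosity * sg$length)
  ia <- match(sg$node_a, nd$id)
  ib <- match(sg$node_b, nd$id)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    if (nd$bc_kind[i] == "pressure_outlet") {
      A[i, i] <- 1
      b[i] <- nd$bc_value[i]
      next
    }
    inc <- which(ia == i | ib == i)
    for (s in inc) {
      j <- if (ia[s] == i) ib[s] else ia[s]
      A[i, i] <- A[i, i] + cond[s]
      A[i, j] <- A[i, j] - cond[s]
    }
    if (nd$bc_kind[i] == "velocity_inlet")
      b[i] <- nd$bc_value[i] * pi * sg$radius[inc[1]]^2
  }
  p <- base::solve(A, b)
  q <- cond * (p[ia] - p[ib])
  tau <- 4 * fluid$viscosity * abs(q) / (pi * sg$radius^3)
  list(pressure = stats::setNames(as.numeric(p), nd$id),
       flow = stats::setNames(q, sg$id),
       shear = stats::setNames(tau, sg$id))
}
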