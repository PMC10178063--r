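# Small networks built in code for the tests.

set_bc <- function(network, node_id, bc_kind, bc_value = NA_real_) {
  i <- match(node_id, network$nodes$id)
  network$nodes$bc_kind[i] <- bc_kind
  network$nodes$bc_value[i] <- bc_value
  network
}

# symmetric Y: one inlet feeding two identical daughter branches
y_network <- function(radius = 0.001, inlet_speed = 0.09) {
  nodes <- data.frame(
    id = c("in", "j", "o1", "o2"),
    x = c(0, 0.05, 0.1, 0.1),
    y = c(0, 0, 0.03, -0.03),
    bc_kind = c("velocity_inlet", "junction", "pressure_outlet",
                "pressure_outlet"),
    bc_value = c(inlet_speed, NA, 0, 0), stringsAsFactors = FALSE)
  segs <- data.frame(id = c("trunk", "d1", "d2"),
                     node_a = c("in", "j", "j"),
                     node_b = c("j", "o1", "o2"),
                     radius = radius,
                     wall_label = c("wall_1", "wall_2", "wall_3"),
                     stringsAsFactors = FALSE)
  vessel_network(nodes, segs, c(junction_1 = "j"))
}

# two segments in series with distinct radii/lengths
series_network <- function(r1 = 0.001, r2 = 0.0008, l1 = 0.04, l2 = 0.07,
                           inlet_speed = 0.09) {
  nodes <- data.frame(id = c("in", "m", "out"),
                      x = c(0, l1, l1 + l2), y = 0,
                      bc_kind = c("velocity_inlet", "junction",
                                  "pressure_outlet"),
                      bc_value = c(inlet_speed, NA, 0),
                      stringsAsFactors = FALSE)
  segs <- data.frame(id = c("s1", "s2"), node_a = c("in", "m"),
                     node_b = c("m", "out"), radius = c(r1, r2),
                     wall_label = c("wall_1", "wall_2"),
                     stringsAsFactors = FALSE)
  vessel_network(nodes, segs, c(junction_1 = "m"))
}

# diamond: stub in, two parallel branches with distinct radii, stub out
diamond_network <- function(rb1 = 0.001, rb2 = 0.0008, inlet_speed = 0.09) {
  nodes <- data.frame(
    id = c("in", "a", "b1", "b2", "c", "out"),
    x = c(0, 0.02, 0.05, 0.05, 0.08, 0.1),
    y = c(0, 0, 0.02, -0.02, 0, 0),
    bc_kind = c("velocity_inlet", "junction", "junction", "junction",
                "junction", "pressure_outlet"),
    bc_value = c(inlet_speed, NA, NA, NA, NA, 0), stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("si", "u1", "u2", "v1", "v2", "so"),
    node_a = c("in", "a", "b1", "a", "b2", "c"),
    node_b = c("a", "b1", "c", "b2", "c", "out"),
    radius = c(0.001, rb1, rb1, rb2, rb2, 0.001),
    wall_label = c("wall_1", "wall_2", "wall_2", "wall_3", "wall_3",
                   "wall_4"),
    stringsAsFactors = FALSE)
  vessel_network(nodes, segs, c(junction_1 = "a", junction_2 = "c"))
}

# chain whose two labelled junctions sit in disjoint shear bins:
# thick segments carry 1.26 Pa, thin ones ~3.67 Pa
disjoint_junction_network <- function(inlet_speed = 0.09) {
  nodes <- data.frame(
    id = c("in", "j1", "x", "j2", "out"),
    x = c(0, 0.05, 0.1, 0.15, 0.2), y = 0,
    bc_kind = c("velocity_inlet", "junction", "junction", "junction",
                "pressure_outlet"),
    bc_value = c(inlet_speed, NA, NA, NA, 0), stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("t1", "t2", "n1", "n2"),
    node_a = c("in", "j1", "x", "j2"),
    node_b = c("j1", "x", "j2", "out"),
    radius = c(0.001, 0.001, 0.0007, 0.0007),
    wall_label = c("wall_1", "wall_1", "wall_2", "wall_2"),
    stringsAsFactors = FALSE)
  vessel_network(nodes, segs, c(junction_1 = "j1", junction_2 = "j2"))
}

# all valid inlet/outlet assignments of the four H-network terminals
h_bc_variants <- function(inlet_speed = 0.09) {
  base <- build_fixture("1C")$network
  term <- c("bl", "br", "tl", "tr")
  out <- list()
  for (mask in 1:14) {
    net <- base
    for (k in seq_along(term)) {
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) > 0L)
        net <- set_bc(net, term[k], "velocity_inlet", inlet_speed)
      else
        net <- set_bc(net, term[k], "pressure_outlet", 0)
    }
    out[[length(out) + 1L]] <- net
  }
  out
}

si <- function(low, high) shear_interval(low, high, snapped = TRUE)
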