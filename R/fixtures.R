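# Deterministic fixture geometries for the ladder-like vessel-network
# models.  All radii 0.001 m; horizontal trunks 0.1 m; sprouts 0.05 m.
# Inlet/outlet placements that are shown only in figures are encoded as a
# best reading and flagged in the `notes` field.

h_core_network <- function(inlet_speed = 0.09) {
  nodes <- data.frame(
    id = c("bl", "j1", "br", "tl", "j2", "tr"),
    x = c(0, 0.05, 0.1, 0, 0.05, 0.1),
    y = c(0, 0, 0, 0.05, 0.05, 0.05),
    bc_kind = c("velocity_inlet", "junction", "pressure_outlet",
                "velocity_inlet", "junction", "pressure_outlet"),
    bc_value = c(inlet_speed, NA, 0, inlet_speed, NA, 0),
    stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("w1a", "w1b", "w2", "w3a", "w3b"),
    node_a = c("bl", "j1", "j1", "tl", "j2"),
    node_b = c("j1", "br", "j2", "j2", "tr"),
    radius = 0.001,
    wall_label = c("wall_1", "wall_1", "wall_2", "wall_3", "wall_3"),
    stringsAsFactors = FALSE)
  vessel_network(nodes, segs,
                 junction_labels = c(junction_1 = "j1", junction_2 = "j2"))
}

set_node_bc <- function(network, node_id, bc_kind, bc_value = NA_real_) {
  i <- match(node_id, network$nodes$id)
  if (is.na(i)) stop("unknown node id '", node_id, "'")
  network$nodes$bc_kind[i] <- bc_kind
  network$nodes$bc_value[i] <- bc_value
  network
}

# tip node id of the single sprout segment carrying `wall_label`
wall_tip_node <- function(network, wall_label) {
  path <- wall_path(network, wall_label)
  deg <- node_degree(network)
  ends <- c(path$start_node, path$end_node)
  ends[deg[ends] == 1L][1]
}

ladder_2_network <- function(inlet_speed = 0.09) {
  # two 0.1 m trunks, three rungs at x = 0.025 / 0.05 / 0.075, wall 6
  # sprouting upward from the middle top junction
  xs <- c(0.025, 0.05, 0.075)
  nodes <- data.frame(
    id = c("bl", "b1", "b2", "b3", "br", "tl", "t1", "t2", "t3", "tr", "s6"),
    x = c(0, xs, 0.1, 0, xs, 0.1, 0.05),
    y = c(rep(0, 5), rep(0.05, 5), 0.10),
    bc_kind = c("velocity_inlet", "junction", "junction", "junction",
                "pressure_outlet",
                "velocity_inlet", "junction", "junction", "junction",
                "pressure_outlet", "pressure_outlet"),
    bc_value = c(inlet_speed, NA, NA, NA, 0, inlet_speed, NA, NA, NA, 0, 0),
    stringsAsFactors = FALSE)
  segs <- data.frame(
    id = c("b_1", "b_2", "b_3", "b_4",
           "t_1", "t_2", "t_3", "t_4",
           "r_1", "r_2", "r_3", "s_6"),
    node_a = c("bl", "b1", "b2", "b3",
               "tl", "t1", "t2", "t3",
               "b1", "b2", "b3", "t2"),
    node_b = c("b1", "b2", "b3", "br",
               "t1", "t2", "t3", "tr",
               "t1", "t2", "t3", "s6"),
    radius = 0.001,
    wall_label = c(rep("wall_1", 4), rep("wall_3", 4),
                   "wall_4", "wall_2", "wall_5", "wall_6"),
    stringsAsFactors = FALSE)
  vessel_network(nodes, segs,
                 junction_labels = c(junction_1 = "b1", junction_2 = "b2",
                                     junction_3 = "b3", junction_4 = "t1",
                                     junction_5 = "t2", junction_6 = "t3"))
}

#' Build a named model fixture
#'
#' Deterministic construction of the ten reference geometries.  Models
#' 1A-1C are the three-vessel "H" (two horizontal trunks joined at their
#' midpoints by a vertical connector) under different inlet/outlet
#' arrangements; 1D and 1E add one and two sprouts; 1F and 1G flip the
#' newest sprout terminal to a velocity inlet; 2A-2C are the full
#' six-wall, six-junction ladder with a sprouting sixth vessel (2B angles
#' it, 2C flips its terminal to an inlet).
#'
#' @param model_id One of `"1A"`, `"1B"`, `"1C"`, `"1D"`, `"1E"`, `"1F"`,
#'   `"1G"`, `"2A"`, `"2B"`, `"2C"`.
#' @param inlet_speed Inlet mean velocity in m/s (default 0.09).
#' @return A list of class `model_fixture` with elements `model_id`,
#'   `network` and `notes`.
#' @export
#' @examples
#' fx <- build_fixture("1C")
#' wall_labels(fx$network)
build_fixture <- function(model_id, inlet_speed = 0.09) {
  ids <- c("1A", "1B", "1C", "1D", "1E", "1F", "1G", "2A", "2B", "2C")
  if (!is.character(model_id) || length(model_id) != 1L ||
      !model_id %in% ids)
    stop("fixture not found: unknown model_id '", model_id,
         "' (supported: ", paste(ids, collapse = ", "), ")")
  pol <- growth_policy()
  grow1 <- function(net) {
    # first sprout: midpoint of wall 3's left constituent segment, upward
    sprout(net, "wall_3", fraction = 0.25, policy = pol)
  }
  grow2 <- function(net) sprout(net, "wall_4", fraction = 0.5, policy = pol)
  note_fig <- "inlet/outlet placement is a best reading of figure-only information"

  net <- switch(model_id,
    "1A" = {
      n <- h_core_network(inlet_speed)
      n <- set_node_bc(n, "tl", "pressure_outlet", 0)
      n <- set_node_bc(n, "tr", "velocity_inlet", inlet_speed)
      n$notes <- paste("Model 1A: antiparallel trunk flow;", note_fig)
      n
    },
    "1B" = {
      n <- h_core_network(inlet_speed)
      n <- set_node_bc(n, "br", "closed_end")
      n$notes <- paste("Model 1B: both left ends inlets, single top-right",
                       "outlet, bottom-right closed;", note_fig,
                       "; second-inlet speed equal to 0.09 m/s is assumed,",
                       "not stated")
      n
    },
    "1C" = {
      n <- h_core_network(inlet_speed)
      n$notes <- paste("Model 1C: inlets at both left ends, outlets at both",
                       "right ends (near-stagnant vertical connector)")
      n
    },
    "1D" = {
      n <- grow1(h_core_network(inlet_speed))
      n$notes <- "Model 1D: 1C plus one upward sprout on wall 3"
      n
    },
    "1E" = {
      n <- grow2(grow1(h_core_network(inlet_speed)))
      n$notes <- "Model 1E: 1D plus one sprout on wall 4"
      n
    },
    "1F" = {
      n <- grow1(h_core_network(inlet_speed))
      n <- set_node_bc(n, wall_tip_node(n, "wall_4"), "velocity_inlet",
                       inlet_speed)
      n$notes <- paste("Model 1F: 1D with the sprout terminal flipped to a",
                       "velocity inlet;", note_fig)
      n
    },
    "1G" = {
      n <- grow2(grow1(h_core_network(inlet_speed)))
      n <- set_node_bc(n, wall_tip_node(n, "wall_5"), "velocity_inlet",
                       inlet_speed)
      n$notes <- paste("Model 1G: 1E with the newest sprout terminal",
                       "flipped to a velocity inlet;", note_fig)
      n
    },
    "2A" = {
      n <- ladder_2_network(inlet_speed)
      n$notes <- "Model 2A: full six-wall ladder network (best reading)"
      n
    },
    "2B" = {
      n <- ladder_2_network(inlet_speed)
      # angle wall 6: same 0.05 m length, tip displaced by a 3-4-5 triangle
      i <- match("s6", n$nodes$id)
      n$nodes$x[i] <- 0.05 + 0.03
      n$nodes$y[i] <- 0.05 + 0.04
      n$notes <- "Model 2B: 2A with wall 6 placed at an angle"
      n
    },
    "2C" = {
      n <- ladder_2_network(inlet_speed)
      n <- set_node_bc(n, "s6", "velocity_inlet", inlet_speed)
      n$notes <- paste("Model 2C: 2A with the wall-6 terminal changed from",
                       "outlet to inlet;", note_fig)
      n
    })
  structure(list(model_id = model_id, network = net, notes = net$notes),
            class = "model_fixture")
}

#' @export
print.model_fixture <- function(x, ...) {
  cat("<model_fixture> Model ", x$model_id, "\n", sep = "")
  print(x$network)
  invisible(x)
}

#' Published wall-shear-stress and velocity ranges
#'
#' The per-wall and per-junction contour ranges printed for the ten model
#' variants, stored verbatim (including the near-stagnant floor 5.5e-6 Pa
#' and the off-grid endpoint 2.950 Pa, kept as printed).  These rows are
#' inputs for the overlap analysis and regression tests.
#'
#' @return data.frame with columns `model`, `location`, `region_kind`
#'   (`wall`/`junction`), `wss_low_pa`, `wss_high_pa`, `velocity_low_ms`,
#'   `velocity_high_ms`.
#' @export
printed_wss_table <- function() {
  path <- system.file("extdata", "printed_wss_intervals.csv",
                      package = "vesselflow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published junction intervals as a region sample table
#'
#' Re-expresses the printed junction ranges of one model as a
#' [region sample table][read_region_samples()] whose samples are the
#' interval endpoints, ready for [junction_overlap_region()].
#'
#' @param model Model identifier, e.g. `"2A"`.
#' @param kinds Region kinds to include (default junctions only).
#' @return A `region_sample_table` data.frame.
#' @export
printed_region_samples <- function(model, kinds = "junction") {
  tab <- printed_wss_table()
  tab <- tab[tab$model == model & tab$region_kind %in% kinds, ]
  if (nrow(tab) == 0L) stop("no printed rows for model '", model, "'")
  out <- data.frame(
    region_label = rep(tab$location, each = 2L),
    region_kind = rep(tab$region_kind, each = 2L),
    wss_pa = as.numeric(t(cbind(tab$wss_low_pa, tab$wss_high_pa))),
    stringsAsFactors = FALSE)
  class(out) <- c("region_sample_table", "data.frame")
  out
}
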