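# Synthetic generators with known ground truth.  Every generator is a pure
# function of its arguments (seed included): RNG state is saved and
# restored around each call, so repeated calls are bitwise identical and
# never disturb the caller's random stream.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a ladder-like synthetic vessel network
#'
#' Two parallel horizontal trunks joined by `n_sprouts` perpendicular
#' rungs at seed-deterministic positions: the straight, branching pattern
#' characteristic of rheumatoid-arthritis vasculature, in the same planar
#' layout as the model fixtures.  Default boundary conditions are
#' parallel-flow: velocity inlets at both left ends, pressure outlets at
#' both right ends, which leaves the rungs near-stagnant.
#'
#' With `n_sprouts = 1` the topology matches the three-wall, two-junction
#' starter model.  `n_sprouts = 0` intentionally yields two disconnected
#' trunks, which fails [validate_network()] (the generator does not crash).
#'
#' @param n_sprouts Number of rungs (>= 0).
#' @param radius Vessel radius in m.
#' @param trunk_length Trunk length in m.
#' @param sprout_length Rung length (trunk separation) in m.
#' @param inlet_speed Inlet mean velocity in m/s, in (0, 1].
#' @param seed Integer seed controlling rung positions.
#' @return A `vessel_network`.
#' @export
generate_ladder_network <- function(n_sprouts, radius = 0.001,
                                    trunk_length = 0.1,
                                    sprout_length = 0.05,
                                    inlet_speed = 0.09, seed = 1L) {
  stopifnot(n_sprouts >= 0, radius > 0, trunk_length > 0, sprout_length > 0,
            inlet_speed > 0, inlet_speed <= 1)
  n <- as.integer(n_sprouts)
  xs <- if (n > 0)
    sort(with_seed(seed, stats::runif(n, 0.15, 0.85))) * trunk_length
  else numeric(0)

  trunk <- function(side, y) {
    bc <- data.frame(id = paste0(side, c("l", "r")),
                     x = c(0, trunk_length), y = y,
                     bc_kind = c("velocity_inlet", "pressure_outlet"),
                     bc_value = c(inlet_speed, 0), stringsAsFactors = FALSE)
    mids <- if (n > 0)
      data.frame(id = paste0(side, "m", seq_len(n)), x = xs, y = y,
                 bc_kind = "junction", bc_value = NA_real_,
                 stringsAsFactors = FALSE)
    else NULL
    rbind(bc[1, ], mids, bc[2, ])
  }
  bot <- trunk("b", 0)
  top <- trunk("t", sprout_length)

  chain <- function(nodes, wall, prefix) {
    k <- nrow(nodes)
    data.frame(id = paste0(prefix, seq_len(k - 1L)),
               node_a = nodes$id[-k], node_b = nodes$id[-1L],
               radius = radius, wall_label = wall, stringsAsFactors = FALSE)
  }
  segs <- rbind(chain(bot, "wall_1", "bs"),
                chain(top, paste0("wall_", n + 2L), "ts"))
  if (n > 0) {
    rungs <- data.frame(id = paste0("rg", seq_len(n)),
                        node_a = paste0("bm", seq_len(n)),
                        node_b = paste0("tm", seq_len(n)),
                        radius = radius,
                        wall_label = paste0("wall_", seq_len(n) + 1L),
                        stringsAsFactors = FALSE)
    segs <- rbind(segs, rungs)
  }
  jl <- if (n > 0)
    stats::setNames(c(rbind(paste0("bm", seq_len(n)),
                            paste0("tm", seq_len(n)))),
                    paste0("junction_", seq_len(2L * n)))
  else character(0)
  vessel_network(rbind(bot, top), segs, jl,
                 notes = sprintf("synthetic ladder (n_sprouts=%d, seed=%d)",
                                 n, as.integer(seed)))
}

#' Generate labelled wall-shear samples with known ground truth
#'
#' For each region, samples are drawn uniformly from its true interval,
#' perturbed by Gaussian noise of standard deviation `noise_sd`, and
#' truncated at zero.  The true intervals are returned alongside, so tests
#' can compare the recovered snapped interval with the snapped truth.  The
#' noise model is synthetic-only: the deterministic flow model it stands
#' in for has none.
#'
#' @param regions data.frame with columns `region_label`, `region_kind`,
#'   `low`, `high` (true interval in Pa).
#' @param n_samples Samples per region (>= 1).
#' @param noise_sd Gaussian noise standard deviation in Pa (>= 0).
#' @param seed Integer seed.
#' @return List with `samples` (a `region_sample_table`) and `truth`.
#' @export
generate_region_samples <- function(regions, n_samples = 100, noise_sd = 0,
                                    seed = 1L) {
  need <- c("region_label", "region_kind", "low", "high")
  if (!all(need %in% names(regions)))
    stop("regions needs columns ", paste(need, collapse = ", "))
  stopifnot(n_samples >= 1, noise_sd >= 0,
            all(regions$low >= 0), all(regions$high >= regions$low))
  samples <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      s <- stats::runif(n_samples, regions$low[i], regions$high[i]) +
        stats::rnorm(n_samples, 0, noise_sd)
      data.frame(region_label = regions$region_label[i],
                 region_kind = regions$region_kind[i],
                 wss_pa = pmax(s, 0), stringsAsFactors = FALSE)
    }))
  })
  class(samples) <- c("region_sample_table", "data.frame")
  list(samples = samples, truth = regions)
}

#' Randomly reassign inlets and outlets at the terminals
#'
#' Emulates the rearrangement experiments: every terminal (degree-1) node
#' becomes either a velocity inlet or a pressure outlet, uniformly at
#' random but with at least one of each, deterministically under `seed`.
#'
#' @param network A `vessel_network` with at least two terminal nodes.
#' @param seed Integer seed.
#' @param inlet_speed Speed assigned to inlets, m/s.
#' @param outlet_pressure Gauge pressure assigned to outlets, Pa.
#' @return A `vessel_network` with reassigned terminal boundary conditions.
#' @export
generate_random_bc_assignment <- function(network, seed = 1L,
                                          inlet_speed = 0.09,
                                          outlet_pressure = 0) {
  term <- sort(terminal_nodes(network))
  if (length(term) < 2L)
    stop("network needs at least two terminal nodes")
  is_inlet <- with_seed(seed, {
    repeat {
      draw <- stats::runif(length(term)) < 0.5
      if (any(draw) && !all(draw)) break
    }
    draw
  })
  for (k in seq_along(term)) {
    network <- if (is_inlet[k])
      set_node_bc(network, term[k], "velocity_inlet", inlet_speed)
    else
      set_node_bc(network, term[k], "pressure_outlet", outlet_pressure)
  }
  network
}
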