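#' Growth policy for the sprouting engine
#'
#' Tunable parameters of the iterative angiogenesis procedure.  Defaults
#' encode the reference construction: sprouts are 0.05 m cylinders of
#' radius 0.001 m, grown perpendicular to the parent wall on the side away
#' from the network centroid, terminated by a 0 Pa gauge pressure outlet,
#' for at most two iterations.
#'
#' `site_selection` ranks qualifying walls: `"newest_wall"` prefers the
#' most recently created wall (ties among coeval walls broken by
#' descending numeric label); `"no_existing_junction"` prefers walls
#' carrying the fewest labelled junctions; `"closest_to_overlap_centre"`
#' prefers the wall whose shear interval midpoint is nearest the overlap
#' midpoint.
#'
#' @param sprout_length New-vessel length in m.
#' @param sprout_radius New-vessel radius in m.
#' @param max_iterations Maximum number of sprouting events (>= 0).
#' @param site_selection Site ranking rule (see Details).
#' @param attach_fraction Preferred attachment point as a fraction of the
#'   parent wall's arc length; when it coincides with an existing node the
#'   engine falls back to the midpoint of the first qualifying segment.
#' @param terminal_bc,terminal_value Boundary condition of the sprout tip.
#' @param min_active_branches Passed to [junction_overlap_region()].
#' @return An object of class `growth_policy`.
#' @export
growth_policy <- function(sprout_length = 0.05, sprout_radius = 0.001,
                          max_iterations = 2L,
                          site_selection = c("newest_wall",
                                             "no_existing_junction",
                                             "closest_to_overlap_centre"),
                          attach_fraction = 0.5,
                          terminal_bc = "pressure_outlet",
                          terminal_value = 0,
                          min_active_branches = 2L) {
  stopifnot(sprout_length > 0, sprout_radius > 0, max_iterations >= 0,
            attach_fraction > 0, attach_fraction < 1)
  site_selection <- match.arg(site_selection)
  structure(list(sprout_length = sprout_length,
                 sprout_radius = sprout_radius,
                 max_iterations = as.integer(max_iterations),
                 site_selection = site_selection,
                 attach_fraction = attach_fraction,
                 terminal_bc = terminal_bc,
                 terminal_value = terminal_value,
                 min_active_branches = as.integer(min_active_branches)),
            class = "growth_policy")
}

# labelled junction nodes lying on a wall's path (interior or ends)
wall_junction_count <- function(network, wall_label) {
  p <- wall_path(network, wall_label)
  on_wall <- unique(c(p$segments$node_a, p$segments$node_b))
  sum(network$junction_labels %in% on_wall)
}

#' Walls qualifying for angiogenesis under an overlap region
#'
#' A wall qualifies when its snapped shear interval intersects the overlap
#' with positive width and its peak shear exceeds the stagnation floor.
#' The returned walls are ordered by the policy's site-selection ranking;
#' per wall, the qualifying sub-interval and the ids of the constituent
#' segments whose own contour bin meets the overlap are reported.
#'
#' @param solution A `flow_solution`.
#' @param overlap An `overlap_result` (or `shear_interval`).
#' @param scheme A [binning_scheme()].
#' @param policy A [growth_policy()].
#' @return data.frame with columns `wall_label`, `qual_low`, `qual_high`,
#'   `max_shear`, `segments` (comma-joined ids), ordered best-first; zero
#'   rows when nothing qualifies.  With an empty overlap, a zero-row frame
#'   with attribute `halted = TRUE` (a growth-halted signal, not an error).
#' @export
find_candidate_walls <- function(solution, overlap,
                                 scheme = binning_scheme(),
                                 policy = growth_policy()) {
  stopifnot(inherits(solution, "flow_solution"))
  iv <- if (inherits(overlap, "overlap_result")) overlap$interval else overlap
  none <- data.frame(wall_label = character(), qual_low = numeric(),
                     qual_high = numeric(), max_shear = numeric(),
                     segments = character(), stringsAsFactors = FALSE)
  if (is_empty_interval(iv)) {
    attr(none, "halted") <- TRUE
    return(none)
  }
  net <- solution$network
  seg <- solution$segments
  rows <- list()
  for (w in wall_labels(net)) {
    wi <- wall_interval(solution, w, scheme)
    qi <- interval_intersection(wi, iv)
    if (is.null(qi)) next
    tau <- seg$wall_shear[!is.na(seg$wall_label) & seg$wall_label == w]
    if (max(tau) <= scheme$stagnation_floor) next
    ids <- seg$id[!is.na(seg$wall_label) & seg$wall_label == w]
    qseg <- ids[vapply(seq_along(ids), function(k) {
      b <- snap_to_bins(tau[k], tau[k], scheme)
      tau[k] > scheme$stagnation_floor &&
        !is.null(interval_intersection(b, iv))
    }, logical(1))]
    if (length(qseg) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      wall_label = w, qual_low = qi$low, qual_high = qi$high,
      max_shear = max(tau), segments = paste(qseg, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(none)
  out <- do.call(rbind, rows)
  num <- wall_number(out$wall_label)
  num[is.na(num)] <- -Inf
  ord <- switch(policy$site_selection,
    newest_wall = order(-num),
    no_existing_junction = {
      jc <- vapply(out$wall_label, wall_junction_count, integer(1),
                   network = net)
      order(jc, -num)
    },
    closest_to_overlap_centre = {
      mid_ov <- (iv$low + iv$high) / 2
      d <- abs((out$qual_low + out$qual_high) / 2 - mid_ov)
      order(d, -num)
    })
  out[ord, , drop = FALSE]
}

parse_segment_hits <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]

#' Sprout a new vessel from a wall
#'
#' Splits the parent wall at `fraction` of its arc length (strictly inside
#' a constituent segment), then attaches a new perpendicular segment of
#' the policy's length and radius on the side pointing away from the
#' network centroid.  The new interior node becomes the next labelled
#' junction; the tip carries the policy's terminal boundary condition.
#'
#' @param network A `vessel_network`.
#' @param wall_label Parent wall.
#' @param fraction Attachment point along the wall's arc length, in (0, 1).
#' @param policy A [growth_policy()].
#' @return A new `vessel_network` with one added wall.
#' @export
sprout <- function(network, wall_label, fraction, policy = growth_policy()) {
  stopifnot(inherits(network, "vessel_network"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1)")
  path <- wall_path(network, wall_label)
  target <- fraction * path$total_length
  tol <- 1e-9 * path$total_length
  hit <- which(target > path$start_length + tol &
                 target < path$start_length + path$segments$length - tol)
  if (length(hit) == 0L)
    stop("attachment point coincides with an existing node on wall '",
         wall_label, "'")
  hit <- hit[1]
  pseg <- path$segments[hit, ]
  local_f <- (target - path$start_length[hit]) / pseg$length
  if (!path$forward[hit]) local_f <- 1 - local_f

  attach_id <- fresh_node_id(network)
  net2 <- split_segment_at(network, pseg$id, local_f, attach_id)

  # perpendicular direction, side away from the centroid
  nd <- net2$nodes
  a <- nd[match(pseg$node_a, nd$id), ]
  b <- nd[match(pseg$node_b, nd$id), ]
  u <- c(b$x - a$x, b$y - a$y)
  u <- u / sqrt(sum(u^2))
  perp <- c(-u[2], u[1])
  at <- nd[match(attach_id, nd$id), ]
  cen <- network_centroid(network)
  tip1 <- c(at$x, at$y) + policy$sprout_length * perp
  tip2 <- c(at$x, at$y) - policy$sprout_length * perp
  d1 <- sum((tip1 - cen)^2)
  d2 <- sum((tip2 - cen)^2)
  tip <- if (d1 > d2 + 1e-18) tip1
         else if (d2 > d1 + 1e-18) tip2
         else if (perp[2] > 0 || (perp[2] == 0 && perp[1] > 0)) tip1
         else tip2

  # placement checks: tip must not coincide with an existing node and the
  # sprout must not run along an existing segment out of the attach node
  if (any(abs(nd$x - tip[1]) < 1e-12 & abs(nd$y - tip[2]) < 1e-12))
    stop("sprout placement error: tip coincides with an existing node")
  dir_new <- (tip - c(at$x, at$y)) / policy$sprout_length
  inc <- which(net2$segments$node_a == attach_id |
                 net2$segments$node_b == attach_id)
  for (s in inc) {
    other <- if (net2$segments$node_a[s] == attach_id)
      net2$segments$node_b[s] else net2$segments$node_a[s]
    o <- nd[match(other, nd$id), ]
    v <- c(o$x - at$x, o$y - at$y)
    v <- v / sqrt(sum(v^2))
    if (abs(dir_new[1] * v[2] - dir_new[2] * v[1]) < 1e-9 &&
        sum(dir_new * v) > 0)
      stop("sprout placement error: sprout would coincide with segment '",
           net2$segments$id[s], "'")
  }

  wnum <- wall_number(wall_labels(network))
  new_wall <- paste0("wall_", max(wnum, na.rm = TRUE) + 1L)
  jnum <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1",
                                          names(network$junction_labels))))
  new_junction <- paste0("junction_",
                         if (length(jnum)) max(jnum, na.rm = TRUE) + 1L
                         else 1L)
  tip_id <- fresh_node_id(net2, "tip")
  bc_val <- if (policy$terminal_bc %in% c("velocity_inlet",
                                          "pressure_outlet"))
    policy$terminal_value else NA_real_
  nodes <- rbind(net2$nodes,
                 data.frame(id = tip_id, x = tip[1], y = tip[2],
                            bc_kind = policy$terminal_bc, bc_value = bc_val,
                            stringsAsFactors = FALSE))
  segs <- rbind(net2$segments,
                data.frame(id = fresh_segment_id(net2, "spr"),
                           node_a = attach_id, node_b = tip_id,
                           radius = policy$sprout_radius,
                           length = policy$sprout_length,
                           wall_label = new_wall, stringsAsFactors = FALSE))
  jl <- c(net2$junction_labels, stats::setNames(attach_id, new_junction))
  vessel_network(nodes, segs, jl, network$notes)
}

#' Run the iterative shear-driven growth procedure
#'
#' Repeats solve -> junction overlap -> candidate walls -> select ->
#' sprout until `max_iterations` is reached, the overlap is empty, or no
#' wall qualifies.  The engine is fully deterministic.
#'
#' @param initial A valid `vessel_network`.
#' @param fluid A [fluid_properties()].
#' @param policy A [growth_policy()].
#' @param scheme A [binning_scheme()].
#' @return List of class `growth_trace`: `initial`, `events` (one record
#'   per sprout), `solutions`, `overlaps`, `networks` (state after each
#'   iteration), `final`, `stopped` (one of `"max_iterations"`,
#'   `"no overlap"`, `"no candidates"`, or `"error: ..."`).
#' @export
run_growth <- function(initial, fluid = fluid_properties(),
                       policy = growth_policy(),
                       scheme = binning_scheme()) {
  stopifnot(inherits(initial, "vessel_network"))
  net <- initial
  events <- list()
  solutions <- list()
  overlaps <- list()
  networks <- list()
  stopped <- "max_iterations"
  it <- 0L
  while (it < policy$max_iterations) {
    it <- it + 1L
    sol <- tryCatch(solve_network(net, fluid), error = function(e) e)
    if (inherits(sol, "error")) {
      stopped <- paste0("error: ", conditionMessage(sol))
      break
    }
    ov <- junction_overlap_region(sol, scheme, policy$min_active_branches)
    solutions[[it]] <- sol
    overlaps[[it]] <- ov
    if (is_empty_interval(ov$interval)) {
      stopped <- "no overlap"
      break
    }
    cand <- find_candidate_walls(sol, ov, scheme, policy)
    if (nrow(cand) == 0L) {
      stopped <- "no candidates"
      break
    }
    pick <- cand[1, ]
    path <- wall_path(net, pick$wall_label)
    frac <- policy$attach_fraction
    target <- frac * path$total_length
    tol <- 1e-9 * path$total_length
    hit <- which(target > path$start_length + tol &
                   target < path$start_length + path$segments$length - tol)
    qseg <- parse_segment_hits(pick$segments)
    ok <- length(hit) > 0 && path$segments$id[hit[1]] %in% qseg
    if (!ok) {
      # fall back to the midpoint of the first qualifying segment,
      # "first" in arc-length order along the wall
      k <- which(path$segments$id %in% qseg)[1]
      target <- path$start_length[k] + 0.5 * path$segments$length[k]
      frac <- target / path$total_length
    }
    net_new <- tryCatch(sprout(net, pick$wall_label, frac, policy),
                        error = function(e) e)
    if (inherits(net_new, "error")) {
      stopped <- paste0("error: ", conditionMessage(net_new))
      break
    }
    new_wall <- setdiff(wall_labels(net_new), wall_labels(net))
    new_junction <- setdiff(names(net_new$junction_labels),
                            names(net$junction_labels))
    events[[length(events) + 1L]] <- list(
      iteration = it, parent_wall = pick$wall_label,
      attach_fraction = frac, new_wall = new_wall,
      new_junction = new_junction,
      overlap_used = ov$interval)
    net <- net_new
    networks[[it]] <- net
  }
  structure(list(initial = initial, events = events, solutions = solutions,
                 overlaps = overlaps, networks = networks, final = net,
                 stopped = stopped),
            class = "growth_trace")
}

#' @export
print.growth_trace <- function(x, ...) {
  cat("<growth_trace> ", length(x$events), " sprouting event(s); stopped: ",
      x$stopped, "\n", sep = "")
  for (e in x$events)
    cat(sprintf("  it %d: %s -> %s at f=%.3f (overlap %s)\n", e$iteration,
                e$parent_wall, e$new_wall, e$attach_fraction,
                format_interval(e$overlap_used)))
  invisible(x)
}

#' Compare a growth trace with a fixture sequence
#'
#' Regression surface for the growth narrative: per iteration, compares
#' wall and labelled-junction counts of the evolving network with the
#' corresponding fixture, and reports the parent wall of each sprout.
#' Coordinates are deliberately not compared.
#'
#' @param trace A `growth_trace`.
#' @param fixtures List of `vessel_network`s (or model id strings) of the
#'   expected states after each iteration.
#' @return data.frame with columns `iteration`, `walls`, `walls_expected`,
#'   `junctions`, `junctions_expected`, `parent_wall`, `match`.
#' @export
compare_topology <- function(trace, fixtures) {
  stopifnot(inherits(trace, "growth_trace"))
  fixtures <- lapply(fixtures, function(f) {
    if (is.character(f)) build_fixture(f)$network
    else if (inherits(f, "model_fixture")) f$network
    else f
  })
  n <- min(length(trace$networks), length(fixtures))
  if (length(trace$networks) != length(fixtures))
    warning("trace has ", length(trace$networks),
            " iterations but ", length(fixtures), " fixtures supplied")
  if (n == 0L)
    return(data.frame(iteration = integer(), walls = integer(),
                      walls_expected = integer(), junctions = integer(),
                      junctions_expected = integer(),
                      parent_wall = character(), match = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(n), function(i) {
    got <- trace$networks[[i]]
    exp <- fixtures[[i]]
    w1 <- length(wall_labels(got)); w2 <- length(wall_labels(exp))
    j1 <- length(got$junction_labels); j2 <- length(exp$junction_labels)
    data.frame(iteration = i, walls = w1, walls_expected = w2,
               junctions = j1, junctions_expected = j2,
               parent_wall = trace$events[[i]]$parent_wall,
               match = w1 == w2 && j1 == j2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a growth trace as structured text
#'
#' One log record per iteration (overlap, selection, event) plus one
#' network file per intermediate state (`<prefix>_it<k>.json`) and the
#' final network (`<prefix>_final.json`).
#'
#' @param trace A `growth_trace`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_growth_trace <- function(trace, prefix) {
  log_path <- paste0(prefix, "_trace.txt")
  con <- file(log_path, "w")
  lines <- c(sprintf("events\t%d", length(trace$events)),
             sprintf("stopped\t%s", trace$stopped))
  for (e in trace$events)
    lines <- c(lines, sprintf(
      "it\t%d\tparent\t%s\tnew\t%s\tfraction\t%.6f\toverlap\t%s",
      e$iteration, e$parent_wall, e$new_wall, e$attach_fraction,
      format_interval(e$overlap_used)))
  writeLines(lines, con)
  close(con)
  files <- log_path
  for (i in seq_along(trace$networks)) {
    p <- sprintf("%s_it%d.json", prefix, i)
    save_network(trace$networks[[i]], p)
    files <- c(files, p)
  }
  p <- paste0(prefix, "_final.json")
  save_network(trace$final, p)
  invisible(c(files, p))
}
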