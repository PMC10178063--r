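#' Cylindrical vessel network
#'
#' The geometry the whole pipeline operates on: a planar graph of nodes and
#' cylindrical segments.  Nodes carry a boundary-condition tag
#' (`junction`, `interior`, `velocity_inlet`, `pressure_outlet`,
#' `closed_end`); velocity inlets store the prescribed mean speed in m/s,
#' pressure outlets a gauge pressure in Pa.  Collinear segments may be
#' grouped into one named wall via `wall_label`; `junction_labels` maps
#' human junction names (`"junction_1"`, ...) to node ids.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `bc_kind`,
#'   `bc_value` (positions in metres; `bc_value` `NA` where not required).
#' @param segments data.frame with columns `id`, `node_a`, `node_b`,
#'   `radius`, `wall_label`, and optionally `length` (metres).  A missing
#'   `length` is computed from the endpoint positions.
#' @param junction_labels Named character vector mapping junction names to
#'   node ids.
#' @param notes Free-text provenance string.
#' @return An object of class `vessel_network`.
#' @seealso [validate_network()], [build_fixture()], [solve_network()]
#' @export
vessel_network <- function(nodes, segments, junction_labels = character(),
                           notes = "") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need_n <- c("id", "x", "y", "bc_kind")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("nodes missing column(s): ", paste(miss, collapse = ", "))
  if (!"bc_value" %in% names(nodes)) nodes$bc_value <- NA_real_
  need_s <- c("id", "node_a", "node_b", "radius")
  miss <- setdiff(need_s, names(segments))
  if (length(miss)) stop("segments missing column(s): ", paste(miss, collapse = ", "))
  if (!"wall_label" %in% names(segments)) segments$wall_label <- NA_character_
  if (!"length" %in% names(segments)) {
    ia <- match(segments$node_a, nodes$id)
    ib <- match(segments$node_b, nodes$id)
    if (anyNA(ia) || anyNA(ib))
      stop("segment endpoints reference unknown node ids")
    segments$length <- sqrt((nodes$x[ia] - nodes$x[ib])^2 +
                              (nodes$y[ia] - nodes$y[ib])^2)
  }
  nodes$id <- as.character(nodes$id)
  nodes$bc_kind <- as.character(nodes$bc_kind)
  nodes$bc_value <- as.numeric(nodes$bc_value)
  segments$id <- as.character(segments$id)
  segments$node_a <- as.character(segments$node_a)
  segments$node_b <- as.character(segments$node_b)
  segments$wall_label <- as.character(segments$wall_label)
  rownames(nodes) <- NULL
  rownames(segments) <- NULL
  jl <- junction_labels
  if (length(jl)) {
    jl <- stats::setNames(as.character(jl), names(jl))
  } else {
    jl <- stats::setNames(character(0), character(0))
  }
  structure(list(nodes = nodes,
                 segments = segments[, c("id", "node_a", "node_b", "radius",
                                         "length", "wall_label")],
                 junction_labels = jl,
                 notes = as.character(notes)[1]),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network> ", nrow(x$nodes), " nodes, ", nrow(x$segments),
      " segments, ", length(unique(stats::na.omit(x$segments$wall_label))),
      " walls, ", length(x$junction_labels), " labelled junctions\n", sep = "")
  inl <- sum(x$nodes$bc_kind == "velocity_inlet")
  out <- sum(x$nodes$bc_kind == "pressure_outlet")
  cat("  inlets: ", inl, "  outlets: ", out, "\n", sep = "")
  if (nzchar(x$notes)) cat("  notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

node_degree <- function(network) {
  ids <- network$nodes$id
  tab <- table(factor(c(network$segments$node_a, network$segments$node_b),
                      levels = ids))
  stats::setNames(as.integer(tab), ids)
}

terminal_nodes <- function(network) {
  deg <- node_degree(network)
  names(deg)[deg == 1L]
}

network_centroid <- function(network) {
  c(x = mean(network$nodes$x), y = mean(network$nodes$y))
}

#' Wall labels present in a network
#' @param network A `vessel_network`.
#' @return Character vector of distinct wall labels, sorted by their
#'   numeric suffix where present.
#' @export
wall_labels <- function(network) {
  w <- unique(stats::na.omit(network$segments$wall_label))
  w[order(wall_number(w), w)]
}

# numeric suffix of "wall_7" style labels (NA when absent)
wall_number <- function(labels) {
  suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", labels)))
}

# connected components by breadth-first walk; returns integer component id
# per node (named)
node_components <- function(network) {
  ids <- network$nodes$id
  adj <- split(c(network$segments$node_b, network$segments$node_a),
               factor(c(network$segments$node_a, network$segments$node_b),
                      levels = ids))
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (start in ids) {
    if (!is.na(comp[[start]])) next
    k <- k + 1L
    queue <- start
    comp[[start]] <- k
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (is.na(comp[[u]])) {
          comp[[u]] <- k
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

#' Validate a vessel network
#'
#' Checks the structural invariants of the data model and (optionally) the
#' physiological ranges.  Violations are returned as data, not raised as
#' conditions: the empty report means the network is valid.
#'
#' @param network A `vessel_network`.
#' @param physiological If `TRUE`, additionally require vessel diameters in
#'   0.1-10 mm and strictly positive inlet speeds.
#' @return data.frame with columns `rule`, `subject`, `message`; zero rows
#'   when all invariants hold.
#' @export
validate_network <- function(network, physiological = FALSE) {
  v <- list()
  bad <- function(rule, subject, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, subject = subject,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  nd <- network$nodes
  sg <- network$segments

  if (anyDuplicated(nd$id))
    bad("unique_node_id", nd$id[duplicated(nd$id)][1],
        "duplicate node id")
  if (anyDuplicated(sg$id))
    bad("unique_segment_id", sg$id[duplicated(sg$id)][1],
        "duplicate segment id")

  kinds <- c("junction", "interior", "velocity_inlet", "pressure_outlet",
             "closed_end")
  for (i in seq_len(nrow(nd))) {
    if (!nd$bc_kind[i] %in% kinds)
      bad("bc_kind", nd$id[i], paste0("unknown bc_kind '", nd$bc_kind[i], "'"))
  }

  ia <- match(sg$node_a, nd$id)
  ib <- match(sg$node_b, nd$id)
  for (i in seq_len(nrow(sg))) {
    if (is.na(ia[i]) || is.na(ib[i])) {
      bad("segment_endpoints", sg$id[i], "endpoint references unknown node")
      next
    }
    if (sg$radius[i] <= 0)
      bad("radius_positive", sg$id[i], "radius must be > 0")
    if (sg$length[i] <= 0)
      bad("length_positive", sg$id[i], "zero or negative length")
    d <- sqrt((nd$x[ia[i]] - nd$x[ib[i]])^2 + (nd$y[ia[i]] - nd$y[ib[i]])^2)
    if (sg$length[i] > 0 &&
        abs(sg$length[i] - d) > 1e-9 * max(sg$length[i], d))
      bad("length_euclidean", sg$id[i],
          "length does not equal endpoint distance")
    if (physiological) {
      dia <- 2 * sg$radius[i]
      if (dia < 1e-4 - 1e-12 || dia > 1e-2 + 1e-12)
        bad("diameter_physiological", sg$id[i],
            "diameter outside 0.1-10 mm")
    }
  }

  key <- paste(pmin(sg$node_a, sg$node_b), pmax(sg$node_a, sg$node_b))
  if (anyDuplicated(key))
    bad("duplicate_edge", sg$id[duplicated(key)][1],
        "duplicate undirected edge between the same node pair")

  deg <- node_degree(network)
  for (i in seq_len(nrow(nd))) {
    kind <- nd$bc_kind[i]
    val <- nd$bc_value[i]
    if (kind %in% c("velocity_inlet", "pressure_outlet")) {
      if (!is.na(deg[nd$id[i]]) && deg[[nd$id[i]]] != 1L)
        bad("terminal_degree", nd$id[i],
            paste0(kind, " must have exactly one incident segment"))
      if (is.na(val))
        bad("bc_value_present", nd$id[i],
            paste0(kind, " requires a bc_value"))
      if (kind == "velocity_inlet" && !is.na(val) && val < 0)
        bad("inlet_speed", nd$id[i], "inlet speed must be non-negative")
      if (physiological && kind == "velocity_inlet" && !is.na(val) && val <= 0)
        bad("inlet_speed_positive", nd$id[i], "inlet speed must be > 0")
    } else if (!is.na(val)) {
      bad("bc_value_absent", nd$id[i],
          paste0(kind, " must not carry a bc_value"))
    }
  }

  if (!any(nd$bc_kind == "velocity_inlet"))
    bad("has_inlet", "<network>", "no velocity_inlet")
  if (!any(nd$bc_kind == "pressure_outlet"))
    bad("has_outlet", "<network>", "no pressure_outlet")

  if (nrow(nd) > 0) {
    comp <- node_components(network)
    if (max(comp) > 1L)
      bad("connected", "<network>",
          paste0("graph has ", max(comp), " disconnected components"))
  }

  for (j in seq_along(network$junction_labels)) {
    if (!network$junction_labels[[j]] %in% nd$id)
      bad("junction_label", names(network$junction_labels)[j],
          "junction label references unknown node id")
  }

  if (length(v)) do.call(rbind, v)
  else data.frame(rule = character(), subject = character(),
                  message = character(), stringsAsFactors = FALSE)
}

fresh_node_id <- function(network, prefix = "nd") {
  k <- 1L
  repeat {
    id <- paste0(prefix, k)
    if (!id %in% network$nodes$id) return(id)
    k <- k + 1L
  }
}

fresh_segment_id <- function(network, prefix = "sg") {
  k <- 1L
  repeat {
    id <- paste0(prefix, k)
    if (!id %in% network$segments$id) return(id)
    k <- k + 1L
  }
}

#' Split a segment at an interior fraction
#'
#' Replaces the segment by two collinear children sharing a new junction
#' node.  Total length is conserved; both children inherit the parent's
#' radius and wall label.
#'
#' @param network A `vessel_network`.
#' @param segment_id Segment to split.
#' @param fraction Split point, strictly inside (0, 1), measured from
#'   `node_a`.
#' @param new_node_id Optional id for the created node.
#' @return A new `vessel_network`.
#' @export
split_segment_at <- function(network, segment_id, fraction,
                             new_node_id = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1)")
  i <- match(segment_id, network$segments$id)
  if (is.na(i)) stop("unknown segment id '", segment_id, "'")
  seg <- network$segments[i, ]
  a <- network$nodes[match(seg$node_a, network$nodes$id), ]
  b <- network$nodes[match(seg$node_b, network$nodes$id), ]
  if (is.null(new_node_id)) new_node_id <- fresh_node_id(network)
  if (new_node_id %in% network$nodes$id)
    stop("node id '", new_node_id, "' already exists")
  mid <- data.frame(id = new_node_id,
                    x = a$x + fraction * (b$x - a$x),
                    y = a$y + fraction * (b$y - a$y),
                    bc_kind = "junction", bc_value = NA_real_,
                    stringsAsFactors = FALSE)
  child <- function(suffix, na, nb, len) {
    data.frame(id = paste0(seg$id, suffix), node_a = na, node_b = nb,
               radius = seg$radius, length = len,
               wall_label = seg$wall_label, stringsAsFactors = FALSE)
  }
  kids <- rbind(child("a", seg$node_a, new_node_id, fraction * seg$length),
                child("b", new_node_id, seg$node_b,
                      (1 - fraction) * seg$length))
  if (any(kids$id %in% network$segments$id[-i]))
    kids$id <- paste0(kids$id, "x")
  segments <- rbind(network$segments[-i, ], kids)
  vessel_network(rbind(network$nodes, mid), segments,
                 network$junction_labels, network$notes)
}

# Ordered walk along the segments sharing a wall label.  Returns a list with
# the ordered segment data.frame, a `forward` flag per segment (traversed
# node_a -> node_b?) and cumulative start lengths.
wall_path <- function(network, wall_label) {
  segs <- network$segments[!is.na(network$segments$wall_label) &
                             network$segments$wall_label == wall_label, ]
  if (nrow(segs) == 0L) stop("unknown wall_label '", wall_label, "'")
  occ <- table(c(segs$node_a, segs$node_b))
  ends <- names(occ)[occ == 1L]
  if (length(ends) != 2L)
    stop("wall '", wall_label, "' is not a simple open chain")
  pos <- network$nodes[match(ends, network$nodes$id), ]
  start <- ends[order(pos$x, pos$y)][1]
  used <- rep(FALSE, nrow(segs))
  order_idx <- integer(0)
  forward <- logical(0)
  cur <- start
  while (!all(used)) {
    nxt <- which(!used & (segs$node_a == cur | segs$node_b == cur))
    if (length(nxt) == 0L) stop("wall '", wall_label, "' is disconnected")
    nxt <- nxt[1]
    used[nxt] <- TRUE
    order_idx <- c(order_idx, nxt)
    fw <- segs$node_a[nxt] == cur
    forward <- c(forward, fw)
    cur <- if (fw) segs$node_b[nxt] else segs$node_a[nxt]
  }
  segs <- segs[order_idx, ]
  starts <- cumsum(c(0, segs$length))[seq_len(nrow(segs))]
  list(segments = segs, forward = forward, start_length = starts,
       total_length = sum(segs$length), start_node = start, end_node = cur)
}

#' Save / load a vessel network as structured text (JSON)
#'
#' The on-disk schema is versioned (`"format": "vesselflow-network/1"`) and
#' uses explicit SI units: metres for positions, radii and lengths, m/s for
#' inlet speeds, Pa gauge for outlet pressures.  `load_network(save_network(n))`
#' reproduces `n` field for field.
#'
#' @param network A `vessel_network`.
#' @param path File path.
#' @return `save_network` returns `path` invisibly; `load_network` returns a
#'   `vessel_network`.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "vessel_network"))
  obj <- list(format = "vesselflow-network/1",
              units = list(position = "m", radius = "m", length = "m",
                           velocity_inlet = "m/s",
                           pressure_outlet = "Pa gauge"),
              notes = network$notes,
              nodes = network$nodes,
              segments = network$segments,
              junction_labels = as.list(network$junction_labels))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e)
                    stop("cannot parse network file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(obj$format) || !identical(obj$format, "vesselflow-network/1"))
    stop("network file '", path, "': missing or unsupported 'format' field")
  for (fld in c("nodes", "segments")) {
    if (is.null(obj[[fld]]))
      stop("network file '", path, "': missing '", fld, "' field")
  }
  need_n <- c("id", "x", "y", "bc_kind")
  for (col in need_n) {
    if (!col %in% names(obj$nodes))
      stop("network file '", path, "': nodes missing field '", col, "'")
  }
  for (col in c("id", "node_a", "node_b", "radius", "length")) {
    if (!col %in% names(obj$segments))
      stop("network file '", path, "': segments missing field '", col, "'")
  }
  jl <- unlist(obj$junction_labels)
  if (is.null(jl)) jl <- character(0)
  notes <- if (is.null(obj$notes)) "" else obj$notes
  vessel_network(obj$nodes, obj$segments, jl, notes)
}

#' Export network geometry as a legacy-VTK polyline file
#'
#' Writes an ASCII VTK `POLYDATA` file (one polyline per segment, z = 0)
#' for quick visualisation in ParaView or similar.  Export only; the
#' package never reads VTK.
#'
#' @param network A `vessel_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_vtk_polylines <- function(network, path) {
  nd <- network$nodes
  sg <- network$segments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vesselflow network polylines", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(nd))), con)
  writeLines(sprintf("%.12g %.12g 0", nd$x, nd$y), con)
  writeLines(sprintf("LINES %d %d", nrow(sg), 3L * nrow(sg)), con)
  ia <- match(sg$node_a, nd$id) - 1L
  ib <- match(sg$node_b, nd$id) - 1L
  writeLines(sprintf("2 %d %d", ia, ib), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(sg)),
               "SCALARS radius_m double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.12g", sg$radius), con)
  invisible(path)
}
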