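#' Physiological arterial ranges
#'
#' Inclusive threshold windows used to flag non-physiological segments:
#' arterial wall shear stress 0.6-4 Pa, arterial velocity 0.049-0.19 m/s,
#' vessel diameter 0.1-10 mm.
#'
#' @param wss_low,wss_high Wall-shear window in Pa.
#' @param velocity_low,velocity_high Velocity window in m/s.
#' @param diameter_low,diameter_high Diameter window in m.
#' @return An object of class `physiological_ranges`.
#' @export
physiological_ranges <- function(wss_low = 0.6, wss_high = 4.0,
                                 velocity_low = 0.049, velocity_high = 0.19,
                                 diameter_low = 1e-4, diameter_high = 1e-2) {
  pairs <- list(c(wss_low, wss_high), c(velocity_low, velocity_high),
                c(diameter_low, diameter_high))
  for (p in pairs) if (!(p[1] < p[2])) stop("each low must be < its high")
  structure(list(wss_low = wss_low, wss_high = wss_high,
                 velocity_low = velocity_low, velocity_high = velocity_high,
                 diameter_low = diameter_low, diameter_high = diameter_high),
            class = "physiological_ranges")
}

raw_wall_range <- function(solution, wall_label) {
  seg <- solution$segments
  tau <- seg$wall_shear[!is.na(seg$wall_label) &
                          seg$wall_label == wall_label]
  if (length(tau) == 0L) stop("unknown wall_label '", wall_label, "'")
  c(min(tau), max(tau))
}

#' Snapped shear interval of a named wall
#'
#' The contour interval spanning the minimum and maximum wall shear over
#' all segments sharing `wall_label`, widened outward to bin edges.  The
#' raw (unsnapped) extremes are attached as attributes `raw_low` /
#' `raw_high` so reports can show values such as 5.5e-6 Pa as printed.
#'
#' @param solution A `flow_solution`.
#' @param wall_label Wall name, e.g. `"wall_3"`.
#' @param scheme A [binning_scheme()].
#' @return A snapped `shear_interval`.
#' @export
wall_interval <- function(solution, wall_label, scheme = binning_scheme()) {
  stopifnot(inherits(solution, "flow_solution"))
  rng <- raw_wall_range(solution, wall_label)
  out <- snap_to_bins(rng[1], rng[2], scheme)
  attr(out, "raw_low") <- rng[1]
  attr(out, "raw_high") <- rng[2]
  out
}

# shear values of segments incident to a labelled junction, with the
# stagnant-branch rule applied: branches below the stagnation floor are
# discarded when at least one incident branch is above it
junction_active_shear <- function(solution, junction_name,
                                  scheme = binning_scheme()) {
  net <- solution$network
  if (!junction_name %in% names(net$junction_labels))
    stop("unknown junction '", junction_name, "'")
  node <- net$junction_labels[[junction_name]]
  seg <- solution$segments
  inc <- seg$node_a == node | seg$node_b == node
  tau <- seg$wall_shear[inc]
  if (length(tau) == 0L)
    stop("junction '", junction_name, "' has no incident segments")
  active <- tau >= scheme$stagnation_floor
  if (any(tau > scheme$stagnation_floor)) tau[active] else tau
}

#' Snapped shear interval of a labelled junction
#'
#' The contour interval spanning the shear of the segments incident to the
#' junction, after discarding stagnant branches (shear below the
#' stagnation floor) whenever at least one incident branch flows.  This
#' reproduces how the reported junction regions exclude the near-zero
#' shear of adjoining stagnant walls.
#'
#' @inheritParams wall_interval
#' @param junction_name Junction name, e.g. `"junction_1"`.
#' @return A snapped `shear_interval` with `raw_low` / `raw_high`
#'   attributes.
#' @export
junction_interval <- function(solution, junction_name,
                              scheme = binning_scheme()) {
  stopifnot(inherits(solution, "flow_solution"))
  tau <- junction_active_shear(solution, junction_name, scheme)
  out <- snap_to_bins(min(tau), max(tau), scheme)
  attr(out, "raw_low") <- min(tau)
  attr(out, "raw_high") <- max(tau)
  out
}

#' Junction overlap region of a model
#'
#' The intersection of the (snapped) wall-shear intervals at the model's
#' junctions: the statistic used to decide where new vessels may sprout.
#' Touching intervals count as no overlap.
#'
#' For a solved network, junctions with fewer than `min_active_branches`
#' flowing (supra-floor) branches are treated as pass-through points
#' rather than junction regions: with a single flowing branch there is no
#' confluence and the reduced-order model cannot attribute a contour range
#' to the junction.  Set `min_active_branches = 0` to force the literal
#' all-junctions intersection.  For a region sample table every region of
#' kind `"junction"` contributes.
#'
#' @param x A `flow_solution` or a `region_sample_table`.
#' @param scheme A [binning_scheme()].
#' @param min_active_branches Minimum flowing branches for a junction of a
#'   solved network to count as a region (default 2).
#' @return List of class `overlap_result` with elements `interval` (a
#'   `shear_interval`, possibly empty) and `contributing_junctions`.
#' @export
junction_overlap_region <- function(x, scheme = binning_scheme(),
                                    min_active_branches = 2L) {
  UseMethod("junction_overlap_region")
}

#' @export
junction_overlap_region.flow_solution <- function(x,
                                                  scheme = binning_scheme(),
                                                  min_active_branches = 2L) {
  jn <- names(x$network$junction_labels)
  if (length(jn) == 0L) stop("network has no labelled junction regions")
  keep <- character(0)
  ivs <- list()
  for (j in jn) {
    tau <- junction_active_shear(x, j, scheme)
    n_active <- sum(tau > scheme$stagnation_floor)
    if (n_active < min_active_branches) next
    keep <- c(keep, j)
    ivs[[length(ivs) + 1L]] <- junction_interval(x, j, scheme)
  }
  if (length(ivs) == 0L)
    return(structure(list(interval = empty_interval(),
                          contributing_junctions = character(0)),
                     class = "overlap_result"))
  structure(list(interval = intersect_intervals(ivs),
                 contributing_junctions = keep),
            class = "overlap_result")
}

#' @export
junction_overlap_region.region_sample_table <- function(x,
                                                        scheme = binning_scheme(),
                                                        min_active_branches = 2L) {
  jt <- x[x$region_kind == "junction", ]
  if (nrow(jt) == 0L) stop("table has no junction regions")
  labels <- unique(jt$region_label)
  ivs <- lapply(labels, function(l) region_interval(x, l, scheme))
  structure(list(interval = intersect_intervals(ivs),
                 contributing_junctions = labels),
            class = "overlap_result")
}

#' @export
junction_overlap_region.data.frame <- function(x, scheme = binning_scheme(),
                                               min_active_branches = 2L) {
  need <- c("region_label", "region_kind", "wss_pa")
  if (!all(need %in% names(x)))
    stop("data.frame is not a region sample table (need columns ",
         paste(need, collapse = ", "), ")")
  class(x) <- c("region_sample_table", "data.frame")
  junction_overlap_region(x, scheme, min_active_branches)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> ", format_interval(x$interval), sep = "")
  if (length(x$contributing_junctions))
    cat("  (", paste(x$contributing_junctions, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Flag segments against the physiological arterial ranges
#'
#' Pure inclusive threshold comparisons per segment: wall shear within the
#' arterial shear window, absolute mean velocity within the arterial
#' velocity window, diameter within the arterial diameter window.
#'
#' @param solution A `flow_solution`.
#' @param ranges A [physiological_ranges()].
#' @return data.frame with columns `id`, `wall_label`, `wss_ok`,
#'   `velocity_ok`, `diameter_ok`.
#' @export
classify_physiological <- function(solution,
                                   ranges = physiological_ranges()) {
  stopifnot(inherits(solution, "flow_solution"))
  seg <- solution$segments
  dia <- 2 * seg$radius
  v <- abs(seg$mean_velocity)
  data.frame(id = seg$id, wall_label = seg$wall_label,
             wss_ok = seg$wall_shear >= ranges$wss_low &
               seg$wall_shear <= ranges$wss_high,
             velocity_ok = v >= ranges$velocity_low &
               v <= ranges$velocity_high,
             diameter_ok = dia >= ranges$diameter_low &
               dia <= ranges$diameter_high,
             stringsAsFactors = FALSE)
}

#' Read a region sample table from delimited text
#'
#' Expected columns: `region_label`, `region_kind` (`wall` or `junction`),
#' `wss_pa` (non-negative, Pa).  Separator is sniffed from the header
#' (comma or tab).  Malformed rows raise an error naming the row.
#'
#' @param path Input file.
#' @return data.frame of class `region_sample_table`.
#' @export
read_region_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("'", path, "': empty file")
  sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("region_label", "region_kind", "wss_pa")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("'", path, "': header missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) stop("'", path, "': no sample rows")
  wss <- suppressWarnings(as.numeric(tab$wss_pa))
  bad <- which(is.na(wss) | wss < 0)
  if (length(bad))
    stop("'", path, "': row ", bad[1] + 1L,
         ": wss_pa must be a non-negative number")
  badk <- which(!tab$region_kind %in% c("wall", "junction"))
  if (length(badk))
    stop("'", path, "': row ", badk[1] + 1L,
         ": region_kind must be 'wall' or 'junction'")
  tab$wss_pa <- wss
  class(tab) <- c("region_sample_table", "data.frame")
  tab
}

#' Write a region sample table
#' @param table A `region_sample_table`.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_region_samples <- function(table, path, sep = ",") {
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Snapped interval of one labelled region
#'
#' Min/max of the region's samples, widened outward to contour-bin edges.
#'
#' @param table A `region_sample_table`.
#' @param label Region label.
#' @param scheme A [binning_scheme()].
#' @return A snapped `shear_interval` with raw extremes as attributes.
#' @export
region_interval <- function(table, label, scheme = binning_scheme()) {
  s <- table$wss_pa[table$region_label == label]
  if (length(s) == 0L) stop("region '", label, "' has no samples")
  out <- snap_to_bins(min(s), max(s), scheme)
  attr(out, "raw_low") <- min(s)
  attr(out, "raw_high") <- max(s)
  out
}

snap_velocity <- function(lo, hi, width = 0.055) {
  sc <- binning_scheme(bin_width = width, max_edge = 20 * width,
                       stagnation_floor = width)
  iv <- snap_to_bins(lo, hi, sc)
  sprintf("%.3g-%.3g", iv$low, iv$high)
}

#' Model report table (walls, junctions, overlap, velocity)
#'
#' One row per wall and per junction with the raw and snapped shear
#' ranges, the model-wide junction overlap repeated on the junction rows
#' (the literal `"No overlap"` when empty), and the velocity range snapped
#' to 0.055 m/s bins (solved networks only).
#'
#' @param x A `flow_solution` or `region_sample_table`.
#' @param scheme A [binning_scheme()].
#' @param ranges A [physiological_ranges()] (kept for signature
#'   stability; thresholds do not alter the table).
#' @param velocity_bin Velocity bin width in m/s.
#' @param min_active_branches Passed to [junction_overlap_region()] for
#'   solved networks.
#' @return data.frame with columns `location`, `region_kind`,
#'   `wss_raw_low`, `wss_raw_high`, `wss_range`, `junction_overlap`,
#'   `velocity_range`.
#' @export
report_model_table <- function(x, scheme = binning_scheme(),
                               ranges = physiological_ranges(),
                               velocity_bin = 0.055,
                               min_active_branches = 2L) {
  rows <- list()
  if (inherits(x, "flow_solution")) {
    ov <- junction_overlap_region(x, scheme, min_active_branches)
    ov_str <- format_interval(ov$interval)
    seg <- x$segments
    for (j in names(x$network$junction_labels)) {
      iv <- junction_interval(x, j, scheme)
      node <- x$network$junction_labels[[j]]
      inc <- seg$node_a == node | seg$node_b == node
      # velocity hull over the same branches that define the shear range
      tau <- seg$wall_shear[inc]
      keep <- if (any(tau > scheme$stagnation_floor))
        tau >= scheme$stagnation_floor else rep(TRUE, sum(inc))
      vs <- abs(seg$mean_velocity[inc][keep])
      rows[[length(rows) + 1L]] <- data.frame(
        location = j, region_kind = "junction",
        wss_raw_low = attr(iv, "raw_low"),
        wss_raw_high = attr(iv, "raw_high"),
        wss_range = format_interval(iv),
        junction_overlap = ov_str,
        velocity_range = snap_velocity(min(vs), max(vs), velocity_bin),
        stringsAsFactors = FALSE)
    }
    for (w in wall_labels(x$network)) {
      iv <- wall_interval(x, w, scheme)
      vs <- abs(seg$mean_velocity[!is.na(seg$wall_label) &
                                    seg$wall_label == w])
      rows[[length(rows) + 1L]] <- data.frame(
        location = w, region_kind = "wall",
        wss_raw_low = attr(iv, "raw_low"),
        wss_raw_high = attr(iv, "raw_high"),
        wss_range = format_interval(iv),
        junction_overlap = "",
        velocity_range = snap_velocity(min(vs), max(vs), velocity_bin),
        stringsAsFactors = FALSE)
    }
  } else {
    need <- c("region_label", "region_kind", "wss_pa")
    if (!all(need %in% names(x)))
      stop("report_model_table() needs a flow_solution or a region sample table")
    class(x) <- c("region_sample_table", "data.frame")
    has_junctions <- any(x$region_kind == "junction")
    ov_str <- if (has_junctions)
      format_interval(junction_overlap_region(x, scheme)$interval)
    else stop("table has no junction regions")
    for (l in unique(x$region_label)) {
      kind <- x$region_kind[x$region_label == l][1]
      iv <- region_interval(x, l, scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        location = l, region_kind = kind,
        wss_raw_low = attr(iv, "raw_low"),
        wss_raw_high = attr(iv, "raw_high"),
        wss_range = format_interval(iv),
        junction_overlap = if (kind == "junction") ov_str else "",
        velocity_range = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
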