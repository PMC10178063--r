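#' Contour binning scheme for wall shear stress
#'
#' Wall-shear-stress values are reported on contour bins of width
#' `bin_width` (Pa).  Every printed endpoint in the reference tables is an
#' integer multiple of 0.42 Pa, which fixes the defaults.  The
#' `stagnation_floor` is the level (one bin width) below which an incident
#' segment is treated as non-flowing when characterising a junction.
#'
#' @param bin_width Bin width in Pa.
#' @param max_edge Largest reported contour edge in Pa; must be an integer
#'   multiple of `bin_width`.
#' @param stagnation_floor Shear level in Pa below which a branch is
#'   considered stagnant at a junction.
#' @return An object of class `binning_scheme`.
#' @export
#' @examples
#' binning_scheme()
binning_scheme <- function(bin_width = 0.42, max_edge = 4.20,
                           stagnation_floor = 0.42) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0,
            is.numeric(max_edge), max_edge > 0, stagnation_floor >= 0)
  k <- max_edge / bin_width
  if (abs(k - round(k)) > 1e-9)
    stop("max_edge must be an integer multiple of bin_width")
  structure(list(bin_width = bin_width, max_edge = max_edge,
                 stagnation_floor = stagnation_floor),
            class = "binning_scheme")
}

#' Shear-stress interval
#'
#' A `[low, high]` interval in Pa.  `snapped` records whether the endpoints
#' lie on contour-bin edges.  The empty interval (no overlap) is represented
#' by [empty_interval()].
#'
#' @param low,high Endpoints in Pa, `0 <= low <= high`.
#' @param snapped Logical; endpoints lie on bin edges.
#' @return An object of class `shear_interval`.
#' @export
shear_interval <- function(low, high, snapped = FALSE) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, is.finite(low), is.finite(high))
  if (low < 0 || high < low)
    stop("invalid interval: need 0 <= low <= high")
  structure(list(low = low, high = high, snapped = isTRUE(snapped),
                 empty = FALSE),
            class = "shear_interval")
}

#' @rdname shear_interval
#' @export
empty_interval <- function() {
  structure(list(low = NA_real_, high = NA_real_, snapped = TRUE,
                 empty = TRUE),
            class = "shear_interval")
}

#' @rdname shear_interval
#' @param x Object to test.
#' @export
is_empty_interval <- function(x) {
  inherits(x, "shear_interval") && isTRUE(x$empty)
}

#' @export
print.shear_interval <- function(x, ...) {
  cat("<shear_interval> ", format_interval(x), "\n", sep = "")
  invisible(x)
}

#' Format an interval the way the report tables print it
#'
#' `"0.840-1.260"` with three decimals, or the literal `"No overlap"` for an
#' empty interval.
#'
#' @param x A `shear_interval`.
#' @param digits Decimals to print.
#' @return A character scalar.
#' @export
format_interval <- function(x, digits = 3) {
  if (is_empty_interval(x)) return("No overlap")
  sprintf("%.*f-%.*f", digits, x$low, digits, x$high)
}

#' Snap a raw range outward to contour-bin edges
#'
#' Widens `[low, high]` to the nearest enclosing bin edges.  Values exactly
#' on an edge (relative tolerance 1e-9) stay on that edge; a degenerate
#' on-edge value is assigned to the bin *below* (so a reading of exactly
#' 1.26 Pa snaps to `[0.84, 1.26]`), matching how edge values appear as
#' upper endpoints throughout the reference tables.
#'
#' @param low,high Raw range in Pa (`high` defaults to `low`).
#' @param scheme A [binning_scheme()].
#' @return A snapped `shear_interval` containing `[low, high]`.
#' @export
#' @examples
#' snap_to_bins(0.90, 1.10)   # [0.84, 1.26]
#' snap_to_bins(1.26)         # [0.84, 1.26] (edge value, bin below)
#' snap_to_bins(0, 0)         # [0.00, 0.42]
snap_to_bins <- function(low, high = low, scheme = binning_scheme()) {
  stopifnot(is.numeric(low), is.numeric(high))
  if (high < low) stop("low must not exceed high")
  if (low < 0) stop("shear values must be non-negative")
  w <- scheme$bin_width
  tol <- 1e-9
  lo <- w * floor(low / w + tol)
  hi <- w * ceiling(high / w - tol)
  if (hi <= lo + w * tol) {
    # degenerate: the whole range sits on one bin edge
    if (lo <= w * tol) {
      lo <- 0
      hi <- w
    } else {
      hi <- lo
      lo <- hi - w
    }
  }
  shear_interval(max(lo, 0), hi, snapped = TRUE)
}

#' Intersect shear intervals (the junction-overlap rule)
#'
#' Returns `[max of lows, min of highs]` when that interval has strictly
#' positive width, otherwise the empty interval: intervals sharing only a
#' single endpoint count as *no* overlap (forced by the Model 1F rows,
#' whose junction intervals touch at 1.260 Pa yet are reported
#' "No overlap").
#'
#' @param intervals Non-empty list of `shear_interval`s.
#' @return A `shear_interval` (possibly empty).
#' @export
#' @examples
#' intersect_intervals(list(shear_interval(0.42, 1.26, TRUE),
#'                          shear_interval(0.84, 2.52, TRUE)))
intersect_intervals <- function(intervals) {
  if (!is.list(intervals) || length(intervals) == 0L)
    stop("intersect_intervals() needs a non-empty list of intervals")
  ok <- vapply(intervals, inherits, logical(1), what = "shear_interval")
  if (!all(ok)) stop("all elements must be shear_interval objects")
  if (any(vapply(intervals, is_empty_interval, logical(1))))
    return(empty_interval())
  lo <- max(vapply(intervals, function(x) x$low, numeric(1)))
  hi <- min(vapply(intervals, function(x) x$high, numeric(1)))
  if (hi - lo <= 1e-12) return(empty_interval())
  shear_interval(lo, hi,
                 snapped = all(vapply(intervals, function(x) x$snapped,
                                      logical(1))))
}

# positive-measure intersection of two intervals, NULL if none
interval_intersection <- function(a, b) {
  if (is_empty_interval(a) || is_empty_interval(b)) return(NULL)
  lo <- max(a$low, b$low)
  hi <- min(a$high, b$high)
  if (hi - lo <= 1e-12) return(NULL)
  shear_interval(lo, hi, snapped = a$snapped && b$snapped)
}
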