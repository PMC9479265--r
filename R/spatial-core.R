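#' Planar Euclidean distance between points
#'
#' Distances are computed on already-projected planar metric coordinates
#' (the study grid is an abstract metre canvas; real deployments would
#' project lon/lat to a metric CRS such as the British National Grid
#' before any geometry is done — see [project_lonlat()]).
#'
#' @param p,q points: a length-2 numeric `c(x, y)`, a two-column
#'   matrix, or a data frame with columns `x` and `y`. Rows are recycled
#'   when one argument has a single point.
#' @return numeric vector of distances in metres.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(p, q) {
  p <- as_xy(p)
  q <- as_xy(q)
  if (nrow(p) == 1L && nrow(q) > 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1L && nrow(p) > 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
  if (nrow(p) != nrow(q)) stop("p and q must have the same number of points")
  assert_finite_coords(p[, 1], p[, 2])
  assert_finite_coords(q[, 1], q[, 2])
  sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2)
}

as_xy <- function(p) {
  if (is.data.frame(p)) {
    assert_cols(p, c("x", "y"), "point input")
    return(cbind(p$x, p$y))
  }
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("point matrix must have two columns")
    return(p)
  }
  if (is.numeric(p) && length(p) == 2L) return(matrix(p, ncol = 2L))
  stop("cannot interpret input as planar points")
}

#' Link each GPS fix to its nearest alcohol outlet
#'
#' For every fix the globally nearest outlet (of either licence class) is
#' found by Euclidean distance; its id, distance and licence class are
#' recorded on the fix. Equidistant ties resolve to the lowest
#' `outlet_id`, so the result is invariant to the input ordering of the
#' outlet table. A grid spatial index is used internally; results are
#' identical to an exhaustive scan.
#'
#' @param fixes data frame of GPS fixes with columns `x`, `y` (metres);
#'   any further columns (child id, timestamp, ...) are passed through.
#' @param outlets data frame with columns `outlet_id`, `licence`
#'   (`"on_sales"` or `"off_sales"`), `x`, `y`.
#' @return `fixes` with columns `nearest_outlet_id`, `nearest_distance`
#'   (metres) and `nearest_licence` appended.
#' @export
link_nearest_outlet <- function(fixes, outlets) {
  assert_cols(fixes, c("x", "y"), "fixes")
  assert_cols(outlets, c("outlet_id", "licence", "x", "y"), "outlets")
  if (nrow(outlets) == 0L) {
    stop("outlet table is empty: linkage requires at least one outlet")
  }
  if (!all(outlets$licence %in% LICENCE_LEVELS)) {
    stop("outlet licence must be one of: ", paste(LICENCE_LEVELS, collapse = ", "))
  }
  assert_finite_coords(fixes$x, fixes$y, "fix coordinates")
  assert_finite_coords(outlets$x, outlets$y, "outlet coordinates")
  if (anyDuplicated(outlets$outlet_id)) stop("duplicate outlet_id in outlet table")

  o <- outlets[order(outlets$outlet_id), , drop = FALSE]
  idx <- .nearest_point_index(as.numeric(fixes$x), as.numeric(fixes$y),
                              as.numeric(o$x), as.numeric(o$y))
  out <- tibble::as_tibble(fixes)
  out$nearest_outlet_id <- o$outlet_id[idx]
  out$nearest_distance <- sqrt((fixes$x - o$x[idx])^2 + (fixes$y - o$y[idx])^2)
  out$nearest_licence <- o$licence[idx]
  out
}

#' Append home and school distances to fixes
#'
#' @param fixes data frame with `child_id`, `x`, `y`.
#' @param children data frame with `child_id`, `home_x`, `home_y`,
#'   `school_x`, `school_y`.
#' @return `fixes` with `dist_home` and `dist_school` columns (metres).
#' @export
annotate_anchor_distances <- function(fixes, children) {
  assert_cols(fixes, c("child_id", "x", "y"), "fixes")
  assert_cols(children, c("child_id", "home_x", "home_y", "school_x", "school_y"),
              "children")
  i <- match(fixes$child_id, children$child_id)
  if (anyNA(i)) stop("fixes contain child_id values absent from the child table")
  out <- tibble::as_tibble(fixes)
  out$dist_home <- sqrt((fixes$x - children$home_x[i])^2 +
                          (fixes$y - children$home_y[i])^2)
  out$dist_school <- sqrt((fixes$x - children$school_x[i])^2 +
                            (fixes$y - children$school_y[i])^2)
  out
}

#' Wear-time inclusion filter
#'
#' A child is retained only if every tracked day carries strictly more
#' than `min_fixes_per_day` GPS fixes (the default, 360, is one hour of
#' fixes at the 10-second device cadence). "Day" means the calendar date
#' of the timestamp in `tz`.
#'
#' @param fixes data frame with `child_id` and `timestamp` (POSIXct, Date,
#'   or anything `as.Date()` accepts).
#' @param min_fixes_per_day integer; a day with `<= min_fixes_per_day`
#'   fixes disqualifies the child.
#' @param tz time zone used to assign fixes to calendar dates.
#' @return character vector of retained child ids (empty input gives an
#'   empty vector).
#' @export
apply_wear_filter <- function(fixes, min_fixes_per_day = 360, tz = "UTC") {
  if (nrow(fixes) == 0L) return(character(0))
  assert_cols(fixes, c("child_id", "timestamp"), "fixes")
  day <- if (inherits(fixes$timestamp, "Date")) fixes$timestamp
         else as.Date(fixes$timestamp, tz = tz)
  counts <- dplyr::count(
    tibble::tibble(child_id = as.character(fixes$child_id), day = day),
    .data$child_id, .data$day)
  ok <- tapply(counts$n, counts$child_id, function(n) all(n > min_fixes_per_day))
  sort(names(ok)[ok])
}
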