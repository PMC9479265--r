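#' Classify per-fix exposure at a distance threshold
#'
#' A fix is exposed when the distance to its nearest outlet is less than
#' or equal to `threshold` (inclusive; the 10 m default reflects typical
#' GPS receiver accuracy). An exposed fix takes the licence class of its
#' single nearest outlet only -- a fix within threshold of outlets of
#' both classes counts once, for the nearer one.
#'
#' @param linked output of [link_nearest_outlet()].
#' @param threshold metres, strictly positive.
#' @return `linked` with logical `exposed` and character
#'   `exposed_licence` (NA for unexposed fixes) appended.
#' @export
classify_exposure <- function(linked, threshold = 10) {
  assert_cols(linked, c("nearest_distance", "nearest_licence"), "linked fixes")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number of metres")
  }
  out <- tibble::as_tibble(linked)
  out$exposed <- out$nearest_distance <= threshold
  out$exposed_licence <- ifelse(out$exposed, out$nearest_licence, NA_character_)
  out
}

#' Per-child exposure summaries
#'
#' Counts exposed fixes by licence class and expresses them as
#' proportions of each child's total fixes. `prop_any` is the sum of the
#' on- and off-sales proportions (each exposed fix has exactly one
#' nearest licence class), and `any_exposed` flags children with at
#' least one exposed fix.
#'
#' @param classified output of [classify_exposure()] with a `child_id`
#'   column.
#' @return tibble, one row per child: `child_id`, `n_fixes`,
#'   `n_exposed_on`, `n_exposed_off`, `prop_on`, `prop_off`, `prop_any`,
#'   `any_exposed`.
#' @export
summarise_exposure <- function(classified) {
  assert_cols(classified, c("child_id", "exposed", "exposed_licence"),
              "classified fixes")
  if (nrow(classified) == 0L) stop("no fixes to summarise")
  f <- factor(classified$child_id)
  n <- as.integer(rowsum(rep(1L, nrow(classified)), f))
  on <- as.numeric(rowsum(
    as.integer(classified$exposed &
                 classified$exposed_licence == "on_sales"), f))
  off <- as.numeric(rowsum(
    as.integer(classified$exposed &
                 classified$exposed_licence == "off_sales"), f))
  tibble::tibble(
    child_id = levels(f),
    n_fixes = n,
    n_exposed_on = on,
    n_exposed_off = off,
    prop_on = on / n,
    prop_off = off / n,
    prop_any = (on + off) / n,
    any_exposed = (on + off) > 0)
}

#' Exposure summary for a single child
#'
#' @param classified classified fixes belonging to one child.
#' @return one-row tibble as in [summarise_exposure()].
#' @export
summarise_child <- function(classified) {
  if (nrow(classified) == 0L) stop("child has zero fixes")
  if (length(unique(classified$child_id)) != 1L) {
    stop("summarise_child expects fixes from exactly one child")
  }
  summarise_exposure(classified)
}

#' Weighted share of children with any exposure
#'
#' Horvitz-Thompson style weighted proportion,
#' sum(w * exposed) / sum(w).
#'
#' @param summaries a [summarise_exposure()] table.
#' @param weights positive sampling weights aligned with `summaries`
#'   rows (equal weights by default).
#' @return a single proportion in `[0, 1]`.
#' @export
cohort_exposed_share <- function(summaries, weights = rep(1, nrow(summaries))) {
  assert_cols(summaries, "any_exposed", "summaries")
  if (nrow(summaries) == 0L) stop("empty cohort")
  if (length(weights) != nrow(summaries)) {
    stop("weights must align with summary rows")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  sum(weights * as.numeric(summaries$any_exposed)) / sum(weights)
}

#' Hours of device wear represented by a fix count
#'
#' Each fix stands for one `fix_interval`-second time slice, so
#' `n_fixes` fixes at the default 10-s cadence represent
#' `n_fixes / 360` hours of wear.
#'
#' @param n_fixes fix count(s).
#' @param fix_interval seconds between fixes.
#' @return hours of wear.
#' @examples
#' wear_hours(24280) # about 67.4 h
#' @export
wear_hours <- function(n_fixes, fix_interval = 10) {
  n_fixes * fix_interval / 3600
}
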