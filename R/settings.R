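#' Classify a fix into home/school settings by distance band
#'
#' Membership of each anchor's setting is inclusive (`distance <= band`).
#' A fix can fall inside both settings at once; such fixes are classed
#' `both`, separate from fixes exclusive to one setting.
#'
#' @param dist_home,dist_school metres, non-negative, recycled to a
#'   common length.
#' @param band metres, strictly positive.
#' @return factor with levels `home_only`, `school_only`, `both`,
#'   `neither`.
#' @export
classify_setting <- function(dist_home, dist_school, band) {
  if (!is.numeric(band) || length(band) != 1L || band <= 0) {
    stop("band must be a single positive number of metres")
  }
  if (any(dist_home < 0, na.rm = TRUE) || any(dist_school < 0, na.rm = TRUE)) {
    stop("distances must be non-negative")
  }
  h <- dist_home <= band
  s <- dist_school <= band
  out <- ifelse(h & s, "both",
                ifelse(h, "home_only",
                       ifelse(s, "school_only", "neither")))
  factor(out, levels = SETTING_LEVELS)
}

#' Decompose exposed fixes into licence-by-setting cells
#'
#' Each exposed fix of each child is assigned one of eight cells,
#' licence class (on/off-sales) crossed with setting (`home_only`,
#' `school_only`, `both`, `neither`) at the given band, and cell counts
#' are expressed relative to the child's total exposed fixes, so the
#' eight proportions sum to one per child.
#'
#' @param classified classified fixes ([classify_exposure()]) carrying
#'   `dist_home` and `dist_school` ([annotate_anchor_distances()]).
#' @param band distance band in metres.
#' @return tibble: `child_id`, `band`, `licence`, `setting`, `n`,
#'   `prop`; eight rows per child with at least one exposed fix.
#' @export
decompose_exposure <- function(classified, band) {
  assert_cols(classified,
              c("child_id", "exposed", "exposed_licence",
                "dist_home", "dist_school"), "classified fixes")
  e <- classified[classified$exposed, , drop = FALSE]
  if (nrow(e) == 0L) {
    return(tibble::tibble(child_id = character(), band = numeric(),
                          licence = character(), setting = character(),
                          n = integer(), prop = numeric()))
  }
  e$setting <- classify_setting(e$dist_home, e$dist_school, band)
  e$licence <- factor(e$exposed_licence, levels = LICENCE_LEVELS)
  counts <- dplyr::count(e, .data$child_id, .data$licence, .data$setting,
                         .drop = FALSE)
  counts <- dplyr::group_by(counts, .data$child_id)
  counts <- dplyr::mutate(counts, band = band, prop = .data$n / sum(.data$n))
  counts <- dplyr::ungroup(counts)
  counts$licence <- as.character(counts$licence)
  counts$setting <- as.character(counts$setting)
  counts[, c("child_id", "band", "licence", "setting", "n", "prop")]
}

#' Setting decomposition for one exposed child
#'
#' @param classified classified, anchor-annotated fixes of one child;
#'   the child must have at least one exposed fix.
#' @param band distance band in metres.
#' @return eight-row tibble as in [decompose_exposure()], plus
#'   aggregated rows `home_setting` (= `home_only` + `both`) and
#'   `school_setting` (= `school_only` + `both`) per licence class.
#' @export
relative_exposure_decomposition <- function(classified, band) {
  if (nrow(classified) == 0L) stop("child has zero fixes")
  if (length(unique(classified$child_id)) != 1L) {
    stop("expects fixes from exactly one child")
  }
  if (!any(classified$exposed)) stop("child has zero exposed fixes")
  cells <- decompose_exposure(classified, band)
  dplyr::bind_rows(cells, aggregate_settings(cells))
}

# home_setting / school_setting aggregates from an 8-cell decomposition
aggregate_settings <- function(cells) {
  agg <- function(keep, label) {
    a <- dplyr::summarise(
      dplyr::group_by(cells[cells$setting %in% keep, , drop = FALSE],
                      .data$child_id, .data$band, .data$licence),
      n = sum(.data$n), prop = sum(.data$prop), .groups = "drop")
    a$setting <- label
    a[, c("child_id", "band", "licence", "setting", "n", "prop")]
  }
  dplyr::bind_rows(agg(c("home_only", "both"), "home_setting"),
                   agg(c("school_only", "both"), "school_setting"))
}

#' Eligible children for home- and school-setting analyses
#'
#' Setting analyses are restricted to children with at least one exposed
#' fix. The home analysis additionally drops children whose residence
#' co-occurs with an outlet (home within the exposure threshold of any
#' outlet, e.g. a child living above a shop); the school analysis drops
#' children never located within `school_band` of their school
#' (assumed to be tracked outside normal school attendance).
#'
#' @param children child table with `child_id`, `home_x`, `home_y`.
#' @param summaries a [summarise_exposure()] table.
#' @param classified anchor-annotated fixes (needs `dist_school`).
#' @param outlets outlet table.
#' @param school_band metres; school-eligibility radius (held at 500
#'   regardless of the analysis band).
#' @param threshold metres; exposure threshold used for home/outlet
#'   co-location.
#' @return list with character id vectors: `exposed`, `home`, `school`,
#'   `excluded_home_colocated`, `excluded_school_never`.
#' @export
settings_cohort_filter <- function(children, summaries, classified, outlets,
                                   school_band = 500, threshold = 10) {
  assert_cols(children, c("child_id", "home_x", "home_y"), "children")
  exposed_ids <- summaries$child_id[summaries$any_exposed]
  homes <- tibble::tibble(child_id = children$child_id,
                          x = children$home_x, y = children$home_y)
  home_link <- link_nearest_outlet(homes, outlets)
  colocated <- home_link$child_id[home_link$nearest_distance <= threshold]
  near_school <- tapply(classified$dist_school <= school_band,
                        classified$child_id, any)
  never_near <- names(near_school)[!near_school]
  list(
    exposed = sort(exposed_ids),
    home = sort(setdiff(exposed_ids, colocated)),
    school = sort(setdiff(exposed_ids, never_near)),
    excluded_home_colocated = sort(intersect(exposed_ids, colocated)),
    excluded_school_never = sort(intersect(exposed_ids, never_near)))
}

#' Proportion of all fixes spent within band of home and of school
#'
#' Settings are not mutually exclusive here: a fix within band of both
#' anchors counts towards both proportions, so the two shares can sum
#' to more than 1.
#'
#' @param fixes anchor-annotated fixes (`child_id`, `dist_home`,
#'   `dist_school`).
#' @param band metres.
#' @return tibble: `child_id`, `n_fixes`, `prop_near_home`,
#'   `prop_near_school`.
#' @export
time_in_setting <- function(fixes, band = 500) {
  assert_cols(fixes, c("child_id", "dist_home", "dist_school"), "fixes")
  if (nrow(fixes) == 0L) stop("zero fixes")
  f <- factor(fixes$child_id)
  n <- as.integer(rowsum(rep(1L, nrow(fixes)), f))
  tibble::tibble(
    child_id = levels(f),
    n_fixes = n,
    prop_near_home = as.numeric(rowsum(as.integer(fixes$dist_home <= band), f)) / n,
    prop_near_school = as.numeric(rowsum(as.integer(fixes$dist_school <= band), f)) / n)
}

#' Band sensitivity of the setting decomposition
#'
#' Recomputes the weighted-mean licence-by-setting decomposition at each
#' candidate band. Eligibility follows the single stated cohort rule at
#' every band: home analysis excludes outlet-co-located homes, school
#' analysis excludes children never within `school_band` (500 m) of
#' school -- the school-eligibility radius does not shrink with the
#' band. Cohort-level values are design-weighted means of child-level
#' proportions, not pooled fix counts.
#'
#' @param children child table with `child_id`, `quintile`, `weight`,
#'   `home_x`, `home_y`.
#' @param classified classified, anchor-annotated fixes.
#' @param outlets outlet table.
#' @param bands metre bands to evaluate.
#' @param school_band,threshold see [settings_cohort_filter()].
#' @return tibble: `band`, `analysis` (home/school), `quintile`
#'   (`"all"` or `"1"`..`"5"`), `licence`, `setting`, `mean_prop`,
#'   `n_children`.
#' @export
band_sensitivity <- function(children, classified, outlets,
                             bands = c(300, 400, 500),
                             school_band = 500, threshold = 10) {
  if (!length(bands)) stop("bands must be non-empty")
  assert_cols(children, c("child_id", "quintile"), "children")
  w <- children$weight %||% rep(1, nrow(children))
  summaries <- summarise_exposure(classified)
  elig <- settings_cohort_filter(children, summaries, classified, outlets,
                                 school_band = school_band,
                                 threshold = threshold)
  rows <- lapply(sort(bands), function(b) {
    cells <- decompose_exposure(classified, b)
    cells <- dplyr::bind_rows(cells, aggregate_settings(cells))
    per_analysis <- lapply(c(home = "home", school = "school"), function(a) {
      ids <- elig[[a]]
      cc <- cells[cells$child_id %in% ids, , drop = FALSE]
      i <- match(cc$child_id, children$child_id)
      cc$quintile <- children$quintile[i]
      cc$w <- w[i]
      both <- dplyr::bind_rows(cc, dplyr::mutate(cc, quintile = NA))
      out <- dplyr::summarise(
        dplyr::group_by(both, .data$quintile, .data$licence, .data$setting),
        mean_prop = sum(.data$w * .data$prop) / sum(.data$w),
        n_children = dplyr::n_distinct(.data$child_id),
        .groups = "drop")
      out$analysis <- a
      out
    })
    res <- dplyr::bind_rows(per_analysis)
    res$band <- b
    res
  })
  out <- dplyr::bind_rows(rows)
  out$quintile <- ifelse(is.na(out$quintile), "all", as.character(out$quintile))
  out[, c("band", "analysis", "quintile", "licence", "setting",
          "mean_prop", "n_children")]
}
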