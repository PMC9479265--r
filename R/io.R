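#' Read and write the pipeline's plain-text tables
#'
#' Outlet tables hold `outlet_id,licence,x,y`; GPS tables hold
#' `child_id,timestamp,x,y` with ISO-8601 timestamps; child tables hold
#' the cohort covariates, anchors and design fields. All coordinates
#' are planar metres.
#'
#' @param path file path.
#' @name alcospace-io
NULL

#' @rdname alcospace-io
#' @export
read_outlets_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(out, c("outlet_id", "licence", "x", "y"), "outlet CSV")
  if (!all(out$licence %in% LICENCE_LEVELS)) {
    stop("outlet CSV licence values must be on_sales/off_sales")
  }
  out
}

#' @param outlets,fixes,children tables to write.
#' @rdname alcospace-io
#' @export
write_outlets_csv <- function(outlets, path) {
  readr::write_csv(outlets, path)
  invisible(path)
}

#' @rdname alcospace-io
#' @export
read_gps_csv <- function(path) {
  fx <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(fx, c("child_id", "timestamp", "x", "y"), "GPS CSV")
  if (!inherits(fx$timestamp, "POSIXct")) {
    fx$timestamp <- as.POSIXct(fx$timestamp, tz = "UTC")
  }
  fx
}

#' @rdname alcospace-io
#' @export
write_gps_csv <- function(fixes, path) {
  fx <- fixes
  fx$timestamp <- format(fx$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(fx, path)
  invisible(path)
}

#' @rdname alcospace-io
#' @export
read_children_csv <- function(path) {
  ch <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(ch, c("child_id", "home_x", "home_y", "school_x", "school_y"),
              "child CSV")
  ch
}

#' @rdname alcospace-io
#' @export
write_children_csv <- function(children, path) {
  readr::write_csv(children, path)
  invisible(path)
}

#' Project longitude/latitude to local planar metres
#'
#' Equirectangular (local tangent-plane) approximation around an origin:
#' `x = R cos(lat0) (lon - lon0)`, `y = R (lat - lat0)` with angles in
#' radians and `R` the WGS84 equatorial radius. Adequate for the
#' city-scale extents this package works at; it is not a national-grid
#' transform, and studies holding coordinates in a projected metric CRS
#' should supply those directly.
#'
#' @param lon,lat degrees.
#' @param origin `c(lon0, lat0)` in degrees; defaults to the centroid of
#'   the input.
#' @return tibble with `x`, `y` in metres.
#' @export
project_lonlat <- function(lon, lat, origin = c(mean(lon), mean(lat))) {
  r_earth <- 6378137
  to_rad <- pi / 180
  tibble::tibble(
    x = r_earth * cos(origin[2] * to_rad) * (lon - origin[1]) * to_rad,
    y = r_earth * (lat - origin[2]) * to_rad)
}

#' Read GPX track points as GPS fixes
#'
#' Parses `<trkpt>` elements (lat/lon/time) and projects them to local
#' planar metres with [project_lonlat()].
#'
#' @param path GPX file path.
#' @param child_id id to stamp on the fixes (defaults to the track name,
#'   or the file name).
#' @param origin projection origin `c(lon0, lat0)`; defaults to the
#'   track centroid.
#' @return tibble of fixes: `child_id`, `timestamp`, `x`, `y`, plus the
#'   raw `lon`/`lat`.
#' @export
read_gpx <- function(path, child_id = NULL, origin = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (!length(pts)) stop("no track points in GPX file")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tm <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  if (is.null(child_id)) {
    nm <- xml2::xml_text(xml2::xml_find_first(doc, ".//trk/name"))
    child_id <- if (is.na(nm) || !nzchar(nm)) basename(path) else nm
  }
  xy <- project_lonlat(lon, lat, origin %||% c(mean(lon), mean(lat)))
  tibble::tibble(child_id = child_id,
                 timestamp = as.POSIXct(tm, format = "%Y-%m-%dT%H:%M:%S",
                                        tz = "UTC"),
                 x = xy$x, y = xy$y, lon = lon, lat = lat)
}

#' Write a simulation configuration as a flat key-value file
#'
#' Scalars and short vectors only, serialised as YAML; the companion
#' reader restores an [simulation_config()] object (re-validating it).
#'
#' @param config an `alcospace_sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$study_start <- as.character(cfg$study_start)
  if (is.matrix(cfg$outlets_per_quintile)) {
    cfg$outlets_on <- unname(cfg$outlets_per_quintile[, "on"])
    cfg$outlets_off <- unname(cfg$outlets_per_quintile[, "off"])
    cfg$outlets_per_quintile <- NULL
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$outlets_on)) {
    cfg$outlets_per_quintile <- cbind(on = cfg$outlets_on,
                                      off = cfg$outlets_off)
    cfg$outlets_on <- NULL
    cfg$outlets_off <- NULL
  }
  do.call(simulation_config, cfg)
}
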