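#' Configuration for the synthetic cohort and trajectory simulator
#'
#' The simulator emulates the structure of a national child-mobility
#' study: five area income-deprivation quintile zones laid out on a
#' planar metre canvas, alcohol outlets scattered within each zone at a
#' quintile-specific density for each licence class, and children whose
#' GPS trajectories are an anchor mixture around home and school. The
#' defaults encode the study conditions the package is validated
#' against: a cohort of 688 children; an outlet landscape of roughly
#' 16,700 premises of which ~31% hold off-sales licences, with off-sales
#' density rising steeply with deprivation; children spending a little
#' over half their time within 500 m of home and of school; shorter
#' home-school separations in deprived areas; and per-fix exposure
#' probabilities of order 1e-3 to 1e-2.
#'
#' @param n_children cohort size.
#' @param quintile_shares length-5 probabilities (sum 1) of a child
#'   living in deprivation quintile 1 (most deprived) .. 5 (least).
#' @param outlets_per_quintile either a 5 x 2 matrix with columns
#'   `on` and `off` giving outlet counts per quintile zone and licence
#'   class, or a length-5 vector of zone totals whose licences are then
#'   drawn Bernoulli(`off_sales_share`).
#' @param off_sales_share probability an outlet is off-sales when
#'   `outlets_per_quintile` is given as totals only.
#' @param zone_size `c(width, height)` of each quintile zone in metres;
#'   zones are contiguous along the x axis.
#' @param clusters_per_stratum number of sampling clusters (primary
#'   sampling units) per quintile stratum.
#' @param cluster_radius metres; children's homes scatter uniformly in a
#'   disc of this radius around their cluster centre.
#' @param home_time_share,school_time_share mixture probabilities that a
#'   fix is drawn from the home kernel / the school kernel; the
#'   remainder is roaming. Must not sum above 1.
#' @param home_kernel_radius,school_kernel_radius metres; anchor kernels
#'   are uniform discs of these radii, so kernel fixes always lie within
#'   a 500 m band of their anchor.
#' @param roam_radius metres; roaming fixes are uniform in a disc of
#'   this radius around home, excluding the 500 m discs of both anchors
#'   (so the realised within-500 m shares match the configured mixture
#'   shares whenever home and school are far enough apart).
#' @param roam_exclusion_radius metres; see above.
#' @param home_school_distance_by_quintile length-5 metres between a
#'   child's home and school; deprived areas are configured shorter.
#' @param fixes_per_day,n_days,fix_interval trajectory sampling effort;
#'   the defaults give 7 x 3470 = 24,290 fixes at a 10-s cadence,
#'   approximately 67 hours of wear.
#' @param exposure_odds_multipliers length-5 positive scalers applied to
#'   the configured outlet counts of a quintile; at the small per-fix
#'   probabilities the simulator operates in, scaling outlet density
#'   scales the exposure odds nearly proportionally. Ground truth is
#'   nevertheless always established by long-run simulation
#'   ([calibrate_ground_truth()]), not read off these multipliers.
#' @param female_share probability a child is female.
#' @param urban_share_by_quintile length-5 probability of an urban
#'   (six-class code 1-3) residence.
#' @param response_propensity_by_quintile length-5 simulated study
#'   response propensities; sampling weights are their inverses with
#'   multiplicative log-normal jitter, normalised to mean 1.
#' @param weight_jitter_sd standard deviation of the log-normal jitter.
#' @param study_start,study_days tracking start dates are uniform on
#'   `study_start + 0:(study_days - 1)`.
#' @param seed default root seed for the generators.
#' @return a validated `alcospace_sim_config` list.
#' @export
simulation_config <- function(
    n_children = 688,
    quintile_shares = c(0.229, 0.165, 0.179, 0.194, 0.233),
    outlets_per_quintile = cbind(on = c(2500, 2700, 2350, 2100, 1850),
                                 off = c(2000, 1300, 900, 650, 350)),
    off_sales_share = 0.31,
    zone_size = c(20000, 20000),
    clusters_per_stratum = 24,
    cluster_radius = 1000,
    home_time_share = 0.53,
    school_time_share = 0.42,
    home_kernel_radius = 450,
    school_kernel_radius = 450,
    roam_radius = 3000,
    roam_exclusion_radius = 500,
    home_school_distance_by_quintile = c(750, 900, 1100, 1300, 1500),
    fixes_per_day = 3470,
    n_days = 7,
    fix_interval = 10,
    exposure_odds_multipliers = rep(1, 5),
    female_share = 0.55,
    urban_share_by_quintile = c(0.90, 0.85, 0.80, 0.75, 0.70),
    response_propensity_by_quintile = c(0.62, 0.68, 0.74, 0.80, 0.86),
    weight_jitter_sd = 0.15,
    study_start = as.Date("2015-05-01"),
    study_days = 366,
    seed = 1L) {
  cfg <- list(
    n_children = n_children, quintile_shares = quintile_shares,
    outlets_per_quintile = outlets_per_quintile,
    off_sales_share = off_sales_share, zone_size = zone_size,
    clusters_per_stratum = clusters_per_stratum,
    cluster_radius = cluster_radius,
    home_time_share = home_time_share,
    school_time_share = school_time_share,
    home_kernel_radius = home_kernel_radius,
    school_kernel_radius = school_kernel_radius,
    roam_radius = roam_radius,
    roam_exclusion_radius = roam_exclusion_radius,
    home_school_distance_by_quintile = home_school_distance_by_quintile,
    fixes_per_day = fixes_per_day, n_days = n_days,
    fix_interval = fix_interval,
    exposure_odds_multipliers = exposure_odds_multipliers,
    female_share = female_share,
    urban_share_by_quintile = urban_share_by_quintile,
    response_propensity_by_quintile = response_propensity_by_quintile,
    weight_jitter_sd = weight_jitter_sd,
    study_start = as.Date(study_start), study_days = study_days,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "alcospace_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(quintile_shares) != 5L ||
        abs(sum(quintile_shares) - 1) > 1e-9 || any(quintile_shares < 0)) {
      stop("quintile_shares must be 5 non-negative proportions summing to 1")
    }
    om <- outlet_counts(cfg)
    if (any(om < 0, na.rm = TRUE)) stop("outlet counts must be non-negative")
    if (off_sales_share < 0 || off_sales_share > 1) {
      stop("off_sales_share must lie in [0, 1]")
    }
    if (n_children < 0) stop("n_children must be non-negative")
    if (any(zone_size <= 0)) stop("zone_size must be positive: empty region")
    if (home_time_share < 0 || school_time_share < 0 ||
        home_time_share + school_time_share > 1) {
      stop("home_time_share + school_time_share must lie in [0, 1]")
    }
    if (fix_interval <= 0) stop("fix_interval must be positive")
    if (any(exposure_odds_multipliers <= 0)) {
      stop("exposure_odds_multipliers must be positive")
    }
    if (any(home_school_distance_by_quintile < 0)) {
      stop("home-school distances must be non-negative")
    }
    if (any(response_propensity_by_quintile <= 0)) {
      stop("response propensities must be positive")
    }
  })
  invisible(cfg)
}

# per-quintile on/off outlet counts after applying the odds multipliers;
# NA in the "off" column marks totals-only mode (licence drawn later)
outlet_counts <- function(cfg) {
  opq <- cfg$outlets_per_quintile
  m <- cfg$exposure_odds_multipliers
  if (is.matrix(opq)) {
    if (!all(c("on", "off") %in% colnames(opq)) || nrow(opq) != 5L) {
      stop("outlets_per_quintile matrix must be 5 rows with columns 'on' and 'off'")
    }
    cbind(on = round(opq[, "on"] * m), off = round(opq[, "off"] * m))
  } else {
    if (length(opq) != 5L) stop("outlets_per_quintile must have 5 entries")
    if (any(opq < 0)) stop("outlet counts must be non-negative")
    cbind(total = round(opq * m), off = NA_real_)
  }
}

#' Quintile zone rectangles of the simulated region
#'
#' Five contiguous rectangles along the x axis, quintile 1 (most
#' deprived) leftmost. Coordinates are abstract metres.
#'
#' @param config an [simulation_config()] object.
#' @return tibble with `quintile`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
quintile_zones <- function(config) {
  w <- config$zone_size[1]
  h <- config$zone_size[2]
  tibble::tibble(quintile = 1:5,
                 xmin = (0:4) * w, xmax = (1:5) * w,
                 ymin = 0, ymax = h)
}

#' Generate a synthetic outlet landscape
#'
#' Outlets are scattered uniformly within each quintile zone at the
#' configured per-class counts (after the quintile odds multipliers).
#' In totals-only mode each outlet's licence is an independent
#' Bernoulli(`off_sales_share`) draw.
#'
#' @param config an [simulation_config()] object.
#' @param zones zone rectangles, by default [quintile_zones()] of the
#'   config.
#' @param seed integer seed; same seed, same landscape.
#' @return tibble of outlets: `outlet_id`, `licence`, `x`, `y`,
#'   `quintile`.
#' @export
generate_outlets <- function(config, zones = quintile_zones(config),
                             seed = config$seed) {
  validate_sim_config(config)
  if (nrow(zones) == 0L || any(zones$xmax <= zones$xmin) ||
      any(zones$ymax <= zones$ymin)) {
    stop("empty region: zones must have positive area")
  }
  counts <- outlet_counts(config)
  withr::with_seed(seed, {
    per_zone <- lapply(seq_len(nrow(zones)), function(i) {
      if (is.na(counts[i, 2])) {
        n <- counts[i, 1]
        lic <- ifelse(runif(n) < config$off_sales_share,
                      "off_sales", "on_sales")
      } else {
        n <- counts[i, "on"] + counts[i, "off"]
        lic <- rep(c("on_sales", "off_sales"), c(counts[i, "on"], counts[i, "off"]))
      }
      tibble::tibble(
        licence = lic,
        x = runif(n, zones$xmin[i], zones$xmax[i]),
        y = runif(n, zones$ymin[i], zones$ymax[i]),
        quintile = zones$quintile[i])
    })
    out <- dplyr::bind_rows(per_zone)
    out$outlet_id <- sprintf("O%06d", seq_len(nrow(out)))
    out[, c("outlet_id", "licence", "x", "y", "quintile")]
  })
}

#' Generate a synthetic child cohort with survey design structure
#'
#' Children are allocated to deprivation quintiles by the configured
#' shares and to geographic sampling clusters (primary sampling units)
#' within their quintile stratum; homes scatter around cluster centres,
#' schools sit at the quintile's configured home-school distance in a
#' random direction. Sampling weights are inverse simulated response
#' propensities (lower in deprived quintiles) with log-normal jitter,
#' normalised to mean 1.
#'
#' @param config an [simulation_config()] object.
#' @param seed integer seed.
#' @param quintiles optional integer vector of length `n_children`
#'   fixing each child's quintile instead of drawing it from
#'   `quintile_shares` (used e.g. for balanced calibration cohorts).
#' @return tibble of children: ids, quintile, stratum/cluster ids,
#'   weight, sex, six-class urban-rural code, tracking start date, and
#'   home/school coordinates.
#' @export
generate_cohort <- function(config, seed = config$seed, quintiles = NULL) {
  validate_sim_config(config)
  n <- config$n_children
  if (n == 0L) {
    return(tibble::tibble(child_id = character(), quintile = integer(),
                          stratum = character(), cluster = character(),
                          weight = numeric(), sex = character(),
                          urban_rural_code = integer(),
                          start_date = as.Date(character()),
                          home_x = numeric(), home_y = numeric(),
                          school_x = numeric(), school_y = numeric()))
  }
  zones <- quintile_zones(config)
  if (!is.null(quintiles) &&
      (length(quintiles) != n || !all(quintiles %in% 1:5))) {
    stop("quintiles must be a length-n_children vector of values in 1..5")
  }
  withr::with_seed(seed, {
    q <- quintiles %||%
      sample.int(5L, n, replace = TRUE, prob = config$quintile_shares)
    # cluster centres kept off the zone boundary so home discs stay inside
    margin <- min(config$cluster_radius + 100,
                  0.45 * min(config$zone_size))
    centres <- lapply(1:5, function(k) {
      list(x = runif(config$clusters_per_stratum,
                     zones$xmin[k] + margin, zones$xmax[k] - margin),
           y = runif(config$clusters_per_stratum,
                     zones$ymin[k] + margin, zones$ymax[k] - margin))
    })
    cl <- sample.int(config$clusters_per_stratum, n, replace = TRUE)
    cx <- vapply(seq_len(n), function(i) centres[[q[i]]]$x[cl[i]], 0)
    cy <- vapply(seq_len(n), function(i) centres[[q[i]]]$y[cl[i]], 0)
    home <- runif_disc(n, cx, cy, config$cluster_radius)
    dir <- runif(n, 0, 2 * pi)
    d_hs <- config$home_school_distance_by_quintile[q]
    w <- (1 / config$response_propensity_by_quintile[q]) *
      exp(rnorm(n, 0, config$weight_jitter_sd))
    tibble::tibble(
      child_id = sprintf("C%04d", seq_len(n)),
      quintile = q,
      stratum = sprintf("S%d", q),
      cluster = sprintf("S%dC%02d", q, cl),
      weight = w / mean(w),
      sex = ifelse(runif(n) < config$female_share, "female", "male"),
      urban_rural_code = ifelse(runif(n) < config$urban_share_by_quintile[q],
                                sample(1:3, n, replace = TRUE),
                                sample(4:6, n, replace = TRUE)),
      start_date = config$study_start +
        sample.int(config$study_days, n, replace = TRUE) - 1L,
      home_x = home$x, home_y = home$y,
      school_x = home$x + d_hs * cos(dir),
      school_y = home$y + d_hs * sin(dir))
  })
}

# component draw + coordinates for a block of fixes; shared by the one-
# child and whole-cohort simulators. Anchors are parallel vectors of
# length n.
draw_fix_coords <- function(n, hx, hy, sx, sy, config) {
  h <- config$home_time_share
  s <- config$school_time_share
  u <- runif(n)
  comp <- ifelse(u < h, 1L, ifelse(u < h + s, 2L, 3L))
  x <- numeric(n)
  y <- numeric(n)
  i <- comp == 1L
  if (any(i)) {
    p <- runif_disc(sum(i), hx[i], hy[i], config$home_kernel_radius)
    x[i] <- p$x; y[i] <- p$y
  }
  i <- comp == 2L
  if (any(i)) {
    p <- runif_disc(sum(i), sx[i], sy[i], config$school_kernel_radius)
    x[i] <- p$x; y[i] <- p$y
  }
  i <- which(comp == 3L)
  if (length(i)) {
    excl <- config$roam_exclusion_radius
    todo <- i
    for (tries in 1:100) {
      p <- runif_disc(length(todo), hx[todo], hy[todo], config$roam_radius)
      x[todo] <- p$x; y[todo] <- p$y
      bad <- (p$x - hx[todo])^2 + (p$y - hy[todo])^2 <= excl^2 |
        (p$x - sx[todo])^2 + (p$y - sy[todo])^2 <= excl^2
      todo <- todo[bad]
      if (!length(todo)) break
    }
    # pathological geometry (exclusion discs covering the roam disc)
    # falls back to accepting the last proposal
  }
  list(x = x, y = y, component = comp)
}

fix_timestamps <- function(start_date, n_days, fixes_per_day, fix_interval,
                           day_start_hour = 8) {
  day0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  offs <- rep((seq_len(n_days) - 1) * 86400, each = fixes_per_day) +
    day_start_hour * 3600 +
    rep((seq_len(fixes_per_day) - 1) * fix_interval, times = n_days)
  day0 + offs
}

#' Simulate a GPS trajectory for one child
#'
#' Fixes are i.i.d. draws from a two-anchor mixture: with probability
#' `home_time_share` a point uniform in the home kernel disc, with
#' probability `school_time_share` uniform in the school kernel disc,
#' otherwise a roaming point uniform in a wide disc around home but
#' outside the 500 m exclusion discs of both anchors. There is no
#' temporal autocorrelation by design: the downstream analysis consumes
#' only per-fix distances, never movement dynamics. Timestamps run at
#' `fix_interval` seconds from 08:00 on each tracked day.
#'
#' @param child one row of a [generate_cohort()] table.
#' @param config an [simulation_config()] object.
#' @param seed integer seed.
#' @return tibble of fixes: `child_id`, `timestamp`, `x`, `y`.
#' @export
simulate_gps <- function(child, config, seed = config$seed) {
  validate_sim_config(config)
  if (is.data.frame(child)) {
    stopifnot(nrow(child) == 1L)
    child <- as.list(child)
  }
  n <- config$fixes_per_day * config$n_days
  if (n <= 0L) stop("fixes_per_day x n_days must be positive")
  withr::with_seed(seed, {
    p <- draw_fix_coords(n, rep(child$home_x, n), rep(child$home_y, n),
                         rep(child$school_x, n), rep(child$school_y, n),
                         config)
    tibble::tibble(
      child_id = child$child_id,
      timestamp = fix_timestamps(child$start_date, config$n_days,
                                 config$fixes_per_day, config$fix_interval),
      x = p$x, y = p$y)
  })
}

#' Simulate GPS trajectories for a whole cohort
#'
#' Vectorised equivalent of calling [simulate_gps()] per child (a single
#' random stream is used across the cohort, so per-child draws differ
#' from one-child calls, but the whole-cohort output is deterministic
#' given the seed).
#'
#' @param cohort a [generate_cohort()] table.
#' @param config an [simulation_config()] object.
#' @param seed integer seed.
#' @return tibble of fixes for all children.
#' @export
simulate_cohort_gps <- function(cohort, config, seed = config$seed) {
  validate_sim_config(config)
  if (nrow(cohort) == 0L) {
    return(tibble::tibble(child_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          x = numeric(), y = numeric()))
  }
  n_per <- config$fixes_per_day * config$n_days
  if (n_per <= 0L) stop("fixes_per_day x n_days must be positive")
  n <- n_per * nrow(cohort)
  withr::with_seed(seed, {
    idx <- rep(seq_len(nrow(cohort)), each = n_per)
    p <- draw_fix_coords(n, cohort$home_x[idx], cohort$home_y[idx],
                         cohort$school_x[idx], cohort$school_y[idx], config)
    ts <- lapply(seq_len(nrow(cohort)), function(i) {
      fix_timestamps(cohort$start_date[i], config$n_days,
                     config$fixes_per_day, config$fix_interval)
    })
    tibble::tibble(child_id = cohort$child_id[idx],
                   timestamp = do.call(c, ts),
                   x = p$x, y = p$y)
  })
}

#' Establish ground-truth exposure parameters by long-run simulation
#'
#' The generator induces exposure geometrically -- through outlet
#' density around the places children go -- rather than by labelling
#' fixes, so the true per-fix exposure probability of each quintile is
#' itself estimated, by simulating a large calibration cohort (equal
#' children per quintile), running the full linkage + classification
#' stages, and pooling fixes within quintile. True odds ratios are
#' quoted against the least-deprived quintile (5), whose OR is 1 by
#' construction.
#'
#' @param config an [simulation_config()] object; its per-child sampling
#'   effort (`fixes_per_day * n_days`) is respected, and enough children
#'   are simulated to reach `n_fixes_per_quintile`.
#' @param n_fixes_per_quintile minimum pooled fixes per quintile,
#'   across all batches.
#' @param n_batches number of independent landscape/cohort batches the
#'   fixes are spread over; batching bounds memory and averages over
#'   outlet landscapes, so the truth refers to the generative process,
#'   not one realisation.
#' @param threshold exposure distance threshold in metres.
#' @param seed integer seed.
#' @return an `alcospace_ground_truth` list: `probabilities` (tibble of
#'   per-quintile p for any/on/off exposure), `odds_ratios` (vs
#'   quintile 5), `n_fixes_per_quintile`, `seed`.
#' @export
calibrate_ground_truth <- function(config, n_fixes_per_quintile = 1e5,
                                   n_batches = 1L, threshold = 10,
                                   seed = config$seed) {
  validate_sim_config(config)
  n_per_child <- config$fixes_per_day * config$n_days
  per_batch <- ceiling(n_fixes_per_quintile / n_batches)
  n_child_q <- max(20L, ceiling(per_batch / n_per_child))
  cal_cfg <- config
  cal_cfg$n_children <- 5L * n_child_q
  cal_cfg$quintile_shares <- rep(0.2, 5)
  n_fix <- n_exp <- n_off <- numeric(5)
  for (b in seq_len(n_batches)) {
    tag <- sprintf("gt_batch%d", b)
    outlets <- generate_outlets(cal_cfg,
                                seed = substream_seed(seed, paste0(tag, "_o")))
    cohort <- generate_cohort(cal_cfg,
                              seed = substream_seed(seed, paste0(tag, "_c")),
                              quintiles = rep(1:5, each = n_child_q))
    fixes <- simulate_cohort_gps(cohort, cal_cfg,
                                 seed = substream_seed(seed, paste0(tag, "_g")))
    linked <- link_nearest_outlet(fixes, outlets)
    exposed <- linked$nearest_distance <= threshold
    off <- exposed & linked$nearest_licence == "off_sales"
    qf <- factor(cohort$quintile[match(linked$child_id, cohort$child_id)],
                 levels = 1:5)
    n_fix <- n_fix + as.numeric(table(qf))
    n_exp <- n_exp + as.numeric(tapply(exposed, qf, sum))
    n_off <- n_off + as.numeric(tapply(off, qf, sum))
  }
  odds <- function(p) p / (1 - p)
  probs <- tibble::tibble(quintile = 1:5,
                          p_any = n_exp / n_fix,
                          p_on = (n_exp - n_off) / n_fix,
                          p_off = n_off / n_fix,
                          n_fixes = n_fix)
  ors <- tibble::tibble(
    quintile = 1:5,
    or_any = odds(probs$p_any) / odds(probs$p_any[5]),
    or_on = odds(probs$p_on) / odds(probs$p_on[5]),
    or_off = odds(probs$p_off) / odds(probs$p_off[5]))
  structure(list(probabilities = probs, odds_ratios = ors,
                 n_fixes_per_quintile = min(probs$n_fixes),
                 threshold = threshold, seed = seed),
            class = "alcospace_ground_truth")
}

#' @export
print.alcospace_ground_truth <- function(x, ...) {
  cat("Ground-truth exposure calibration (",
      format(x$n_fixes_per_quintile, big.mark = ","),
      "+ fixes per quintile, threshold ", x$threshold, " m)\n", sep = "")
  print(dplyr::left_join(x$probabilities, x$odds_ratios, by = "quintile"))
  invisible(x)
}
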