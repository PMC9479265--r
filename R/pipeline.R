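#' Derive model covariates from raw child attributes
#'
#' Applies the study's coding rules: season is winter when the tracking
#' start date falls inside the daylight-saving winter window (default
#' 25 Oct 2015 - 27 Mar 2016, inclusive) and summer otherwise; the
#' six-category urban/rural classification dichotomises to urban for
#' codes 1-3 and rural for 4-6; the deprivation quintile is
#' `ceiling(5 * rank / N)` on the area income-deprivation rank with the
#' lowest rank the most deprived (quintile 1). When the table already
#' carries a `quintile` column and no `income_rank`, that quintile is
#' used as-is. A `quintile_f` factor with the least-deprived quintile
#' (IncQ5) as reference level is added for modelling.
#'
#' @param children child table with `start_date`, `urban_rural_code`,
#'   and either `income_rank` or `quintile`.
#' @param winter_window length-2 Date vector, inclusive.
#' @param n_ranks total number of ranked areas (defaults to
#'   `max(income_rank)`).
#' @return `children` with `season`, `urbanicity`, `quintile` and
#'   `quintile_f` columns.
#' @export
derive_covariates <- function(children,
                              winter_window = as.Date(c("2015-10-25",
                                                        "2016-03-27")),
                              n_ranks = NULL) {
  for (f in c("start_date", "urban_rural_code")) {
    if (!f %in% names(children)) stop("missing attribute: ", f)
  }
  if (!"income_rank" %in% names(children) && !"quintile" %in% names(children)) {
    stop("missing attribute: income_rank (or quintile)")
  }
  if (anyNA(children$start_date) || anyNA(children$urban_rural_code)) {
    stop("missing values in start_date or urban_rural_code")
  }
  if (!all(children$urban_rural_code %in% 1:6)) {
    stop("urban_rural_code must be a six-class code in 1..6")
  }
  out <- tibble::as_tibble(children)
  sd <- as.Date(out$start_date)
  out$season <- factor(
    ifelse(sd >= winter_window[1] & sd <= winter_window[2],
           "winter", "summer"),
    levels = c("winter", "summer"))
  out$urbanicity <- factor(
    ifelse(out$urban_rural_code %in% 1:3, "urban", "rural"),
    levels = c("urban", "rural"))
  if ("income_rank" %in% names(out)) {
    n <- n_ranks %||% max(out$income_rank)
    out$quintile <- as.integer(ceiling(5 * out$income_rank / n))
  }
  if (!all(out$quintile %in% 1:5)) stop("quintile must be in 1..5")
  out$quintile_f <- factor(paste0("IncQ", out$quintile),
                           levels = paste0("IncQ", 5:1))
  if ("sex" %in% names(out)) {
    out$sex <- factor(out$sex, levels = c("male", "female"))
  }
  out
}

#' Configure an end-to-end pipeline run
#'
#' @param simulation an [simulation_config()] to generate inputs, or
#'   `NULL` to read them from files.
#' @param outlets_csv,gps_csv,children_csv input paths (ignored when
#'   simulating).
#' @param threshold exposure distance threshold, metres.
#' @param bands setting distance bands, metres (sorted ascending).
#' @param school_band school-eligibility radius, metres.
#' @param winter_window inclusive Date interval defining winter.
#' @param min_fixes_per_day wear-filter minimum (a day needs strictly
#'   more fixes than this); `NULL` disables the filter.
#' @param model_terms right-hand side of the outcome models.
#' @param wear_minutes wear period for predicted exposure durations
#'   (default 4020 = 67 h).
#' @param output_dir directory for stage CSVs, manifest and log; `NULL`
#'   keeps everything in memory.
#' @param seed root seed; every stage draws from a named substream.
#' @return a validated `alcospace_pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            outlets_csv = NULL, gps_csv = NULL,
                            children_csv = NULL,
                            threshold = 10,
                            bands = c(300, 400, 500),
                            school_band = 500,
                            winter_window = as.Date(c("2015-10-25",
                                                      "2016-03-27")),
                            min_fixes_per_day = 360,
                            model_terms = ~ quintile_f + urbanicity +
                              season + sex,
                            wear_minutes = 4020,
                            output_dir = NULL,
                            seed = 1L) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!length(bands) || any(bands <= 0)) stop("bands must be positive")
  bands <- sort(bands)
  if (length(winter_window) != 2L || winter_window[1] > winter_window[2]) {
    stop("winter_window must be a valid date interval")
  }
  if (is.null(simulation) &&
      (is.null(outlets_csv) || is.null(gps_csv) || is.null(children_csv))) {
    stop("either a simulation config or all three input paths are required")
  }
  structure(list(simulation = simulation, outlets_csv = outlets_csv,
                 gps_csv = gps_csv, children_csv = children_csv,
                 threshold = threshold, bands = bands,
                 school_band = school_band,
                 winter_window = as.Date(winter_window),
                 min_fixes_per_day = min_fixes_per_day,
                 model_terms = model_terms,
                 wear_minutes = wear_minutes,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "alcospace_pipeline_config")
}

#' Run the full exposure pipeline
#'
#' Stages, in order: acquire inputs (simulate or read), derive model
#' covariates, wear-time filter, nearest-outlet linkage and anchor
#' distances, per-fix exposure classification and per-child summaries,
#' setting decomposition with band sensitivity, design-weighted
#' outcome models (any-exposure; proportion exposed to off-sales; to
#' on-sales), and predicted probabilities/durations by deprivation
#' quintile. A filter ledger records children in/retained/excluded at
#' every stage, and a manifest captures the config hash, seed and row
#' counts, making runs idempotent given the seed. When fewer than two
#' analyzable children remain after filtering, modelling is skipped and
#' the report says so.
#'
#' @param config an [pipeline_config()] object.
#' @param quiet suppress progress messages.
#' @return a report bundle (list): `children`, `summaries`, `linked`
#'   row count, exposure table, `time_in_setting`, `sensitivity`,
#'   `models`, `or_table`, `durations`, `ledger`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "alcospace_pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
    invisible(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ledger <- tibble::tibble(stage = character(), n_in = integer(),
                           n_retained = integer(), n_excluded = integer())
  note <- function(stg, n_in, n_keep) {
    ledger <<- dplyr::bind_rows(ledger, tibble::tibble(
      stage = stg, n_in = as.integer(n_in),
      n_retained = as.integer(n_keep),
      n_excluded = as.integer(n_in - n_keep)))
    say("stage %-18s in=%d retained=%d excluded=%d",
        stg, n_in, n_keep, n_in - n_keep)
  }

  # -- acquire -------------------------------------------------------
  inputs <- stage("acquire", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      list(outlets = generate_outlets(
             sim, seed = substream_seed(config$seed, "outlets")),
           children = generate_cohort(
             sim, seed = substream_seed(config$seed, "cohort")),
           fixes = NULL, sim = sim)
    } else {
      list(outlets = read_outlets_csv(config$outlets_csv),
           children = read_children_csv(config$children_csv),
           fixes = read_gps_csv(config$gps_csv), sim = NULL)
    }
  })
  children <- stage("covariates", derive_covariates(
    inputs$children, winter_window = config$winter_window))
  if (!"weight" %in% names(children)) children$weight <- 1
  say("acquired %d outlets, %d children",
      nrow(inputs$outlets), nrow(children))
  fixes <- stage("trajectories", {
    if (is.null(inputs$fixes)) {
      simulate_cohort_gps(children, inputs$sim,
                          seed = substream_seed(config$seed, "gps"))
    } else inputs$fixes
  })

  # -- wear filter ---------------------------------------------------
  if (!is.null(config$min_fixes_per_day)) {
    keep <- stage("wear_filter",
                  apply_wear_filter(fixes, config$min_fixes_per_day))
    note("wear_filter", nrow(children), length(keep))
    children <- children[children$child_id %in% keep, , drop = FALSE]
    fixes <- fixes[fixes$child_id %in% keep, , drop = FALSE]
  }

  if (nrow(children) == 0L) {
    say("no analyzable children after filtering; nothing to model")
    return(invisible(finish_pipeline(config, children, NULL, NULL, NULL,
                                     NULL, NULL, NULL, NULL, ledger,
                                     log_lines, t0)))
  }

  # -- link + classify ----------------------------------------------
  linked <- stage("linkage", {
    lf <- link_nearest_outlet(fixes, inputs$outlets)
    annotate_anchor_distances(lf, children)
  })
  classified <- stage("exposure", classify_exposure(linked, config$threshold))
  summaries <- stage("exposure", summarise_exposure(classified))
  summaries <- summaries[match(children$child_id, summaries$child_id), ]
  design <- survey_design(children$weight, children$stratum,
                          children$cluster)
  share <- cohort_exposed_share(summaries, children$weight)
  say("weighted share of children exposed: %.1f%%", 100 * share)

  # -- settings ------------------------------------------------------
  tis <- stage("settings", time_in_setting(classified,
                                           max(config$bands)))
  sens <- stage("settings", band_sensitivity(
    children, classified, inputs$outlets, bands = config$bands,
    school_band = config$school_band, threshold = config$threshold))
  elig <- stage("settings", settings_cohort_filter(
    children, summaries, classified, inputs$outlets,
    school_band = config$school_band, threshold = config$threshold))
  note("settings_exposed", nrow(children), length(elig$exposed))
  note("settings_home", length(elig$exposed), length(elig$home))
  note("settings_school", length(elig$exposed), length(elig$school))

  # -- models --------------------------------------------------------
  model_data <- droplevels(children)
  model_data$any_exposed <- as.numeric(summaries$any_exposed)
  model_data$prop_off <- summaries$prop_off
  model_data$prop_on <- summaries$prop_on
  models <- NULL
  or_table <- NULL
  durations <- NULL
  can_model <- nrow(model_data) >= 2L &&
    length(unique(model_data$quintile)) > 1L
  if (can_model) {
    # covariates constant in the analysed cohort carry no information
    # and would make the design matrix degenerate; drop them
    terms_all <- all.vars(config$model_terms)
    keep <- terms_all[vapply(terms_all, function(v) {
      length(unique(model_data[[v]])) > 1L
    }, TRUE)]
    dropped <- setdiff(terms_all, keep)
    if (length(dropped)) {
      say("dropping constant model term(s): %s",
          paste(dropped, collapse = ", "))
    }
    rhs <- paste(keep, collapse = " + ")
    fit_one <- function(resp, trials) {
      fit_quasibinomial(as.formula(paste(resp, "~", rhs)),
                        model_data, design, trials = trials)
    }
    models <- stage("models", list(
      any_exposed = fit_one("any_exposed", 1),
      off_sales = fit_one("prop_off", summaries$n_fixes),
      on_sales = fit_one("prop_on", summaries$n_fixes)))
    or_table <- stage("models", dplyr::bind_rows(lapply(
      names(models),
      function(m) dplyr::mutate(odds_ratios(models[[m]]), model = m,
                                pseudo_r2 = models[[m]]$pseudo_r2,
                                n = models[[m]]$nobs))))
    say("models fitted: %s", paste(names(models), collapse = ", "))
    # profile prediction: quintile varied over its observed levels,
    # every other fitted factor held at its reference level
    xlev <- models$off_sales$xlevels
    qlev <- xlev$quintile_f %||% levels(model_data$quintile_f)
    profile <- tibble::tibble(
      quintile_f = factor(qlev, levels = qlev))
    for (v in setdiff(names(xlev), "quintile_f")) {
      profile[[v]] <- factor(xlev[[v]][1], levels = xlev[[v]])
    }
    durations <- stage("predictions", dplyr::bind_rows(lapply(
      c("off_sales", "on_sales", "any_exposed"), function(m) {
        pr <- predict_probability(models[[m]], profile)
        dur <- exposure_duration(pr, config$wear_minutes)
        tibble::tibble(model = m,
                       quintile = as.integer(sub("IncQ", "", qlev)),
                       p = pr$p, p_lower = pr$lower, p_upper = pr$upper,
                       duration_min = dur$duration,
                       duration_lower = dur$lower,
                       duration_upper = dur$upper)
      })))
  } else {
    say("too few analyzable children or a single quintile: models skipped")
  }

  finish_pipeline(config, children, summaries, share, tis, sens, models,
                  or_table, durations, ledger, log_lines, t0)
}

finish_pipeline <- function(config, children, summaries, share, tis, sens,
                            models, or_table, durations, ledger,
                            log_lines, t0) {
  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    seed = config$seed,
    threshold = config$threshold,
    bands = config$bands,
    n_children = nrow(children),
    n_fixes = if (is.null(summaries)) 0L else sum(summaries$n_fixes),
    exposed_share = share,
    ledger = ledger,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  bundle <- list(children = children, summaries = summaries,
                 exposed_share = share, time_in_setting = tis,
                 sensitivity = sens, models = models, or_table = or_table,
                 durations = durations, ledger = ledger,
                 manifest = manifest, log = log_lines)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    write_children_csv(children, p("children.csv"))
    if (!is.null(summaries)) readr::write_csv(summaries, p("child_exposure.csv"))
    if (!is.null(tis)) readr::write_csv(tis, p("time_in_setting.csv"))
    if (!is.null(sens)) readr::write_csv(sens, p("band_sensitivity.csv"))
    if (!is.null(or_table)) readr::write_csv(or_table, p("model_or_table.csv"))
    if (!is.null(durations)) readr::write_csv(durations, p("durations.csv"))
    readr::write_csv(ledger, p("filter_ledger.csv"))
    jsonlite::write_json(manifest[setdiff(names(manifest), "ledger")],
                         p("manifest.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, p("run.log"))
  }
  invisible(bundle)
}
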