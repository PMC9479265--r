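# Shared simulator configurations for the test suite.

# small landscape with the default outlet densities per km^2 (zones
# scaled from 20x20 km to 6x6 km) -- keeps unit tests fast
tiny_config <- function(n_children = 40, fixes_per_day = 300, n_days = 1,
                        ...) {
  simulation_config(
    n_children = n_children,
    zone_size = c(6000, 6000),
    clusters_per_stratum = 8,
    outlets_per_quintile = cbind(on = c(225, 243, 212, 189, 167),
                                 off = c(180, 117, 81, 59, 32)),
    fixes_per_day = fixes_per_day, n_days = n_days, ...)
}

# the parameter-recovery validation design: default outlet densities on
# 8x8 km zones, 300 PSUs (60 per quintile stratum), 2400 fixes/child
# (enough per-cohort information that the arithmetic mean of OR
# estimates is not dominated by its Jensen bias)
recovery_config <- function(n_children = 688) {
  simulation_config(
    n_children = n_children,
    zone_size = c(8000, 8000),
    clusters_per_stratum = 60,
    outlets_per_quintile = cbind(on = c(400, 432, 376, 336, 296),
                                 off = c(320, 208, 144, 104, 56)),
    fixes_per_day = 2400, n_days = 1)
}

# simulate one cohort under `cfg`, link, classify, and return children +
# per-child summaries ready for modelling
simulate_linked_cohort <- function(cfg, seed, threshold = 10) {
  outlets <- generate_outlets(cfg, seed = substream_seed(seed, "o"))
  children <- generate_cohort(cfg, seed = substream_seed(seed, "c"))
  fixes <- simulate_cohort_gps(children, cfg, seed = substream_seed(seed, "g"))
  linked <- annotate_anchor_distances(link_nearest_outlet(fixes, outlets),
                                      children)
  classified <- classify_exposure(linked, threshold)
  summaries <- summarise_exposure(classified)
  summaries <- summaries[match(children$child_id, summaries$child_id), ]
  list(outlets = outlets, children = derive_covariates(children),
       classified = classified, summaries = summaries)
}
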