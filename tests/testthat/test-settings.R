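# classified fixture: one child, hand-placed exposed fixes
fixture_child_fixes <- function() {
  # 10 exposed fixes: 4 off in home only, 2 off in both, 1 on in school
  # only, 3 off in neither; plus 5 unexposed fixes
  tibble::tibble(
    child_id = "C1",
    x = 0, y = 0,
    nearest_distance = c(rep(5, 10), rep(60, 5)),
    nearest_licence = c(rep("off_sales", 4), rep("off_sales", 2),
                        "on_sales", rep("off_sales", 3),
                        rep("on_sales", 5)),
    dist_home = c(rep(200, 4), rep(450, 2), 900, rep(800, 3), rep(100, 5)),
    dist_school = c(rep(900, 4), rep(450, 2), 300, rep(900, 3), rep(900, 5)))
}

test_that("setting classification uses inclusive band membership", {
  expect_identical(as.character(classify_setting(200, 900, 500)), "home_only")
  expect_identical(as.character(classify_setting(450, 450, 500)), "both")
  expect_identical(as.character(classify_setting(900, 300, 500)), "school_only")
  expect_identical(as.character(classify_setting(501, 501, 500)), "neither")
  # boundary: exactly at the band is inside
  expect_identical(as.character(classify_setting(500, 900, 500)), "home_only")
  expect_error(classify_setting(-1, 10, 500), "non-negative")
  expect_error(classify_setting(1, 10, 0), "positive")
})

test_that("relative decomposition reproduces hand-computed cells", {
  fx <- classify_exposure(fixture_child_fixes(), 10)
  d <- relative_exposure_decomposition(fx, band = 500)
  cell <- function(lic, set) d$prop[d$licence == lic & d$setting == set]
  expect_equal(cell("off_sales", "home_only"), 0.4)
  expect_equal(cell("off_sales", "both"), 0.2)
  expect_equal(cell("on_sales", "school_only"), 0.1)
  expect_equal(cell("off_sales", "neither"), 0.3)
  eight <- d[d$setting %in% c("home_only", "school_only", "both", "neither"), ]
  expect_equal(sum(eight$prop), 1, tolerance = 1e-9)
  # aggregates: home = home_only + both, school = school_only + both
  expect_equal(cell("off_sales", "home_setting"), 0.6)
  expect_equal(cell("off_sales", "school_setting"), 0.2)
  expect_equal(cell("on_sales", "school_setting"), 0.1)
  expect_error(relative_exposure_decomposition(
    classify_exposure(fixture_child_fixes(), 0.001), 500), "zero exposed")
})

test_that("decomposition matches an exhaustive per-fix tabulation", {
  run <- simulate_linked_cohort(tiny_config(n_children = 30), seed = 41)
  cl <- run$classified
  for (band in c(300, 500)) {
    d <- decompose_exposure(cl, band)
    # oracle: literal per-fix loop tabulation
    e <- cl[cl$exposed, ]
    key <- paste(e$child_id,
                 e$exposed_licence,
                 ifelse(e$dist_home <= band & e$dist_school <= band, "both",
                        ifelse(e$dist_home <= band, "home_only",
                               ifelse(e$dist_school <= band, "school_only",
                                      "neither"))))
    ref <- table(key)
    got <- setNames(d$n, paste(d$child_id, d$licence, d$setting))
    expect_equal(unname(got[names(ref)]), unname(as.numeric(ref)))
    # untouched cells are zero, and proportions sum to 1 per child
    expect_equal(sum(d$n), length(key))
    sums <- tapply(d$prop, d$child_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("setting membership is nested across widening bands", {
  run <- simulate_linked_cohort(tiny_config(n_children = 20), seed = 43)
  cl <- run$classified
  in_band <- function(b) (cl$dist_home <= b) | (cl$dist_school <= b)
  expect_true(all(in_band(300) <= in_band(400)))
  expect_true(all(in_band(400) <= in_band(500)))
  # per child, the aggregated home+school share of exposure never
  # shrinks as the band widens
  share <- function(b) {
    d <- decompose_exposure(cl, b)
    tapply(d$prop[d$setting != "neither"],
           d$child_id[d$setting != "neither"], sum)
  }
  s3 <- share(300); s4 <- share(400); s5 <- share(500)
  expect_true(all(s4 - s3 > -1e-12))
  expect_true(all(s5 - s4 > -1e-12))
})

test_that("settings cohort filter applies the stated exclusions", {
  outlets <- tibble::tibble(outlet_id = "O1", licence = "off_sales",
                            x = 0, y = 0)
  children <- tibble::tibble(
    child_id = c("A", "B", "C", "D"),
    home_x = c(5, 2000, 2000, 2000), home_y = 0, # A lives 5 m from outlet
    school_x = 3000, school_y = 0)
  mk <- function(id, n_exp, d_school) tibble::tibble(
    child_id = id, x = 0, y = 0,
    nearest_distance = c(rep(1, n_exp), rep(50, 10 - n_exp)),
    nearest_licence = "off_sales",
    dist_home = 100, dist_school = d_school)
  cl <- classify_exposure(dplyr::bind_rows(
    mk("A", 3, 200), mk("B", 2, 200),
    mk("C", 0, 200),       # never exposed
    mk("D", 2, 700)), 10)  # never within 500 m of school
  s <- summarise_exposure(cl)
  elig <- settings_cohort_filter(children, s, cl, outlets)
  expect_identical(elig$exposed, c("A", "B", "D"))
  expect_identical(elig$home, c("B", "D"))
  expect_identical(elig$school, c("A", "B"))
  expect_identical(elig$excluded_home_colocated, "A")
  expect_identical(elig$excluded_school_never, "D")
})

test_that("time in setting is non-exclusive", {
  fx <- tibble::tibble(child_id = "C1", dist_home = c(0, 0, 600),
                       dist_school = c(600, 600, 0))
  t1 <- time_in_setting(fx, 500)
  expect_equal(t1$prop_near_home, 2 / 3)
  expect_equal(t1$prop_near_school, 1 / 3)
  # anchors 100 m apart, fixes at the midpoint: both shares are 1
  fx2 <- tibble::tibble(child_id = "C2", dist_home = 50, dist_school = 50)
  t2 <- time_in_setting(fx2, 500)
  expect_equal(t2$prop_near_home, 1)
  expect_equal(t2$prop_near_school, 1)
  expect_error(time_in_setting(fx[0, ], 500), "zero fixes")
})

test_that("band sensitivity matches direct recomputation", {
  run <- simulate_linked_cohort(tiny_config(n_children = 40), seed = 47)
  sens <- band_sensitivity(run$children, run$classified, run$outlets,
                           bands = c(300, 500))
  expect_setequal(unique(sens$band), c(300, 500))
  # direct recomputation of one cell: weighted mean of per-child
  # off-sales home_setting proportion over home-eligible children
  elig <- settings_cohort_filter(run$children, run$summaries,
                                 run$classified, run$outlets)
  d <- decompose_exposure(run$classified, 500)
  per_child <- tapply(
    d$prop[d$licence == "off_sales" & d$setting %in% c("home_only", "both")],
    d$child_id[d$licence == "off_sales" & d$setting %in% c("home_only", "both")],
    sum)
  per_child <- per_child[names(per_child) %in% elig$home]
  w <- run$children$weight[match(names(per_child), run$children$child_id)]
  ref <- sum(w * per_child) / sum(w)
  got <- sens$mean_prop[sens$band == 500 & sens$analysis == "home" &
                          sens$quintile == "all" &
                          sens$licence == "off_sales" &
                          sens$setting == "home_setting"]
  expect_equal(got, ref, tolerance = 1e-12)
  # single band gives a single-band table
  one <- band_sensitivity(run$children, run$classified, run$outlets,
                          bands = 400)
  expect_identical(unique(one$band), 400)
  expect_error(band_sensitivity(run$children, run$classified, run$outlets,
                                bands = numeric(0)), "non-empty")
})
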