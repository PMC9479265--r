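test_that("weighted means and their linearized errors are correct", {
  d_eq <- survey_design(rep(1, 3))
  expect_equal(weighted_mean_ci(c(0.2, 0.4, 0.6), d_eq)$mean, 0.4)
  d_w <- survey_design(c(1, 3))
  expect_equal(weighted_mean_ci(c(0, 1), d_w)$mean, 0.75)

  # random fixture vs an independently coded estimator and SE
  withr::with_seed(71, {
    n <- 120
    x <- runif(n)
    w <- runif(n, 0.5, 2)
    strata <- sample(c("S1", "S2", "S3"), n, replace = TRUE)
    clusters <- paste0(strata, sample(1:6, n, replace = TRUE))
  })
  des <- survey_design(w, strata, clusters)
  got <- weighted_mean_ci(x, des)
  ref <- oracle_weighted_mean(x, w, strata, clusters)
  expect_equal(got$mean, ref$mean, tolerance = 1e-12)
  expect_equal(got$se, ref$se, tolerance = 1e-12)
  expect_equal(got$lower, got$mean - 1.96 * got$se)

  # a cluster bootstrap agrees with the linearized SE to first order
  withr::with_seed(72, {
    boot <- replicate(400, {
      cl <- unique(clusters)
      pick <- sample(cl, length(cl), replace = TRUE)
      idx <- unlist(lapply(pick, function(g) which(clusters == g)))
      sum(w[idx] * x[idx]) / sum(w[idx])
    })
  })
  expect_equal(got$se, stats::sd(boot), tolerance = 0.3)
})

test_that("lonely PSUs are flagged and handled per configuration", {
  x <- c(0.1, 0.5, 0.9)
  des_adj <- survey_design(rep(1, 3), strata = c("A", "A", "B"),
                           clusters = c("c1", "c2", "c3"))
  out <- weighted_mean_ci(x, des_adj)
  expect_equal(out$lonely_strata, 1)
  expect_true(is.finite(out$se))
  des_fail <- survey_design(rep(1, 3), strata = c("A", "A", "B"),
                            clusters = c("c1", "c2", "c3"), lonely = "fail")
  expect_error(weighted_mean_ci(x, des_fail), "lonely")
})

test_that("design validation catches malformed inputs", {
  expect_error(survey_design(c(1, -1)), "positive")
  expect_error(survey_design(numeric(0)), "empty")
  expect_error(survey_design(rep(1, 4), strata = c("A", "A", "B", "B"),
                             clusters = c("c1", "c1", "c1", "c2")),
               "exactly one stratum")
})

test_that("intercept-only fit recovers the pooled logit exactly", {
  y <- c(rep(1, 9), rep(0, 91)) # pooled p = 0.09
  des <- survey_design(rep(1, 100))
  fit <- fit_quasibinomial(y ~ 1, data.frame(y = y), des)
  expect_equal(unname(coef(fit)), qlogis(0.09), tolerance = 1e-8)
  # with binomial denominators the pooled proportion is trial-weighted
  d2 <- data.frame(y = c(0.2, 0.05))
  tr <- c(100, 300)
  fit2 <- fit_quasibinomial(y ~ 1, d2, survey_design(rep(1, 2)), trials = tr)
  expect_equal(unname(coef(fit2)), qlogis(sum(d2$y * tr) / sum(tr)),
               tolerance = 1e-8)
})

test_that("unweighted fits equal the reference quasibinomial GLM", {
  withr::with_seed(81, {
    n <- 60
    dat <- data.frame(
      g = factor(sample(c("a", "b", "c"), n, replace = TRUE)),
      u = runif(n))
    tr <- sample(50:200, n, replace = TRUE)
    p <- plogis(-2 + 0.7 * (dat$g == "b") + 1.1 * (dat$g == "c") - 0.5 * dat$u)
    dat$y <- rbinom(n, tr, p) / tr
  })
  fit <- fit_quasibinomial(y ~ g + u, dat, survey_design(rep(1, n)),
                           trials = tr)
  ref <- stats::glm(y ~ g + u, family = stats::quasibinomial(), data = dat,
                    weights = tr)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(fit$dispersion, summary(ref)$dispersion, tolerance = 1e-6)
  expect_equal(fit$deviance, ref$deviance, tolerance = 1e-6)
  expect_equal(fit$null.deviance, ref$null.deviance, tolerance = 1e-6)
  expect_equal(fit$pseudo_r2, 1 - ref$deviance / ref$null.deviance,
               tolerance = 1e-8)
})

test_that("group-effect recovery sits within sampling error", {
  # direct two-group binomial cohorts with known log-odds difference
  beta <- log(3)
  withr::with_seed(91, {
    z <- replicate(20, {
      n <- 200
      g <- rep(c(0, 1), each = n / 2)
      tr <- rep(400, n)
      p <- plogis(-5 + beta * g)
      y <- rbinom(n, tr, p) / tr
      fit <- fit_quasibinomial(y ~ g, data.frame(y = y, g = g),
                               survey_design(rep(1, n)), trials = tr)
      (coef(fit)["g"] - beta) / sqrt(vcov(fit)["g", "g"])
    })
  })
  expect_gte(mean(abs(z) <= 3), 0.95)
  expect_lt(abs(mean(z)), 3 / sqrt(20))
})

test_that("a saturated perfect fit has pseudo-R2 of one", {
  dat <- data.frame(y = c(0, 0, 1, 1), g = factor(c("a", "a", "b", "b")))
  fit <- fit_quasibinomial(y ~ g, dat, survey_design(rep(1, 4)))
  expect_true(fit$separation)
  expect_gt(fit$pseudo_r2, 0.999)
})

test_that("odds ratios transform and invert correctly", {
  run <- simulate_linked_cohort(tiny_config(n_children = 50,
                                            fixes_per_day = 400), seed = 61)
  ch <- run$children
  ch$prop_any <- run$summaries$prop_any
  des <- survey_design(ch$weight, ch$stratum, ch$cluster)
  fit <- fit_quasibinomial(prop_any ~ urbanicity + sex, ch, des,
                           trials = run$summaries$n_fixes)
  or <- odds_ratios(fit)
  expect_equal(or$or, exp(or$estimate))
  expect_equal(or$lower, exp(or$estimate - 1.96 * or$se))
  # a literal coefficient of ln(4.83) formats as OR 4.83
  expect_equal(exp(log(4.83)), 4.83)
  # swapping the reference level reciprocates the OR
  ch$urbanicity <- stats::relevel(ch$urbanicity, "rural")
  fit2 <- fit_quasibinomial(prop_any ~ urbanicity + sex, ch, des,
                            trials = run$summaries$n_fixes)
  expect_equal(odds_ratios(fit2)$or[2], 1 / or$or[2], tolerance = 1e-6)
})

test_that("probability predictions back-transform and bound correctly", {
  # intercept-only round trip at a study-scale probability
  y <- rep(c(1, 0), c(79, 9921)) / 1 # pooled 0.0079
  des <- survey_design(rep(1, 10000))
  fit <- fit_quasibinomial(y ~ 1, data.frame(y = y), des)
  pr <- predict_probability(fit, data.frame(x = 1))
  expect_equal(pr$p, 0.0079, tolerance = 1e-8)
  expect_true(pr$lower < pr$p && pr$p < pr$upper)
  expect_true(pr$lower >= 0 && pr$upper <= 1)

  # in a groups-only model, profile predictions equal the group's
  # trial-weighted pooled proportion (the linear-predictor averaging
  # choice the package documents)
  dat <- data.frame(y = c(0.1, 0.3, 0.02, 0.08),
                    g = factor(c("a", "a", "b", "b")))
  tr <- c(100, 100, 400, 100)
  fitg <- fit_quasibinomial(y ~ g, dat, survey_design(rep(1, 4)), trials = tr)
  prg <- predict_probability(fitg, data.frame(g = factor(c("a", "b"))))
  expect_equal(prg$p, c(0.2, (0.02 * 400 + 0.08 * 100) / 500),
               tolerance = 1e-7)
  expect_error(predict_probability(fitg, data.frame(g = "zzz")),
               "unknown level")
})

test_that("exposure durations scale probabilities by wear time", {
  expect_equal(exposure_duration(0.0079, 4020), 31.758)
  expect_equal(exposure_duration(0, 4020), 0)
  expect_equal(wear_hours(24280) * 60, 4046.667, tolerance = 1e-3)
  expect_equal(67 * 60, 4020) # the wear period used for durations
  tab <- exposure_duration(
    tibble::tibble(p = 0.0079, lower = 0.0045, upper = 0.0113), 4020)
  expect_equal(tab$duration, 31.758)
  expect_equal(tab$lower, 18.09)
  expect_equal(tab$upper, 45.426)
  expect_error(exposure_duration(1.2, 10), "\\[0, 1\\]")
  expect_error(exposure_duration(0.5, -1), "non-negative")
})
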