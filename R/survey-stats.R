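#' Describe a stratified, clustered sampling design
#'
#' Carries the per-child sampling weight and the stratum and cluster
#' (primary sampling unit) memberships used for design-based variance
#' estimation by Taylor linearization.
#'
#' @param weights positive sampling weights.
#' @param strata stratum ids (single stratum if omitted).
#' @param clusters cluster / PSU ids (each element its own cluster if
#'   omitted, i.e. independent children).
#' @param lonely how to handle a stratum containing a single cluster:
#'   `"adjust"` (default) centres its score at the grand mean,
#'   `"fail"` raises an error.
#' @param crit critical value for confidence intervals (1.96 for
#'   normal-theory 95% intervals; a design-df t quantile can be
#'   supplied instead).
#' @return an `alcospace_design` object.
#' @export
survey_design <- function(weights, strata = NULL, clusters = NULL,
                          lonely = c("adjust", "fail"), crit = 1.96) {
  lonely <- match.arg(lonely)
  n <- length(weights)
  if (n == 0L) stop("empty design")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }
  strata <- as.character(strata %||% rep("S1", n))
  clusters <- as.character(clusters %||% seq_len(n))
  if (length(strata) != n || length(clusters) != n) {
    stop("weights, strata and clusters must have equal length")
  }
  # a cluster may not span strata
  if (any(rowSums(table(clusters, strata) > 0) > 1)) {
    stop("each cluster must belong to exactly one stratum")
  }
  structure(list(weights = as.numeric(weights), strata = strata,
                 clusters = clusters, lonely = lonely, crit = crit,
                 n = n),
            class = "alcospace_design")
}

#' @export
print.alcospace_design <- function(x, ...) {
  cat("Survey design:", x$n, "units,",
      length(unique(x$strata)), "strata,",
      length(unique(x$clusters)), "clusters\n")
  invisible(x)
}

# Stratified between-cluster variance of a total from per-unit score
# contributions (n x p). Scores are summed within cluster; each stratum
# contributes n_h/(n_h - 1) times the centred cluster-total
# cross-products. A lonely stratum (single cluster) is centred at the
# grand mean of all cluster totals ("adjust") or rejected ("fail").
taylor_var <- function(scores, design) {
  scores <- as.matrix(scores)
  p <- ncol(scores)
  key <- paste(design$strata, design$clusters, sep = "\r")
  z <- rowsum(scores, key, reorder = TRUE)
  z_str <- vapply(strsplit(rownames(z), "\r", fixed = TRUE), `[`, "", 1L)
  lone <- names(which(table(z_str) == 1L))
  if (length(lone) && design$lonely == "fail") {
    stop("lonely PSU: stratum with a single cluster: ",
         paste(lone, collapse = ", "))
  }
  grand <- colMeans(z)
  V <- matrix(0, p, p)
  for (h in unique(z_str)) {
    zh <- z[z_str == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh == 1L) {
      d <- zh[1L, ] - grand
      V <- V + tcrossprod(d)
    } else {
      d <- sweep(zh, 2L, colMeans(zh))
      V <- V + crossprod(d) * nh / (nh - 1)
    }
  }
  attr(V, "lonely_strata") <- lone
  V
}

#' Design-weighted mean with linearized confidence interval
#'
#' Hajek (ratio) estimator `sum(w x) / sum(w)`, with a variance from
#' first-order Taylor linearization: the residual scores
#' `w (x - mean) / sum(w)` are summed within clusters and their
#' between-cluster variance is accumulated over strata.
#'
#' @param x numeric values.
#' @param design an [survey_design()] aligned with `x`.
#' @return one-row tibble: `mean`, `se`, `lower`, `upper`, `n`,
#'   `lonely_strata` (count of single-cluster strata encountered).
#' @export
weighted_mean_ci <- function(x, design) {
  if (length(x) != design$n) stop("x must align with the design")
  if (anyNA(x)) stop("missing values in x")
  w <- design$weights
  m <- sum(w * x) / sum(w)
  scores <- matrix(w * (x - m) / sum(w), ncol = 1L)
  V <- taylor_var(scores, design)
  se <- sqrt(V[1L, 1L])
  tibble::tibble(mean = m, se = se,
                 lower = m - design$crit * se,
                 upper = m + design$crit * se,
                 n = design$n,
                 lonely_strata = length(attr(V, "lonely_strata")))
}

#' Design-weighted quasibinomial GLM
#'
#' Fits a logit-link model to per-child proportions by iteratively
#' reweighted least squares, with working prior weight
#' `sampling weight x trials` (the binomial denominator, i.e. the
#' child's fix count, enters through the prior weight so that the
#' response "number of exposed fixes" may be non-integer after
#' weighting). The dispersion parameter is the weighted Pearson
#' chi-square over residual degrees of freedom. The coefficient
#' covariance is design-based: a Taylor-linearized sandwich whose meat
#' accumulates between-cluster variation of score totals within strata
#' (the score residuals already carry any overdispersion, so the
#' sandwich is not additionally scaled by the dispersion).
#'
#' With equal weights and every child its own cluster in one stratum,
#' point estimates coincide with `glm(family = quasibinomial)`.
#'
#' @param formula model formula whose response is a proportion in
#'   `[0, 1]` (e.g. `prop_off ~ quintile_f + urbanicity + season + sex`).
#' @param data data frame holding the response and covariates.
#' @param design an [survey_design()] aligned with `data` rows.
#' @param trials binomial denominators (fix counts); scalar or vector,
#'   default 1 (binary response).
#' @param tol IRLS convergence tolerance on the max absolute
#'   coefficient change.
#' @param max_iter iteration cap; non-convergence is an error carrying
#'   the iteration trace.
#' @return an `alcospace_glm` fit: coefficients, design-based `vcov`,
#'   `dispersion`, null and residual deviance, `pseudo_r2`
#'   (1 - residual/null deviance), convergence info, and a separation
#'   flag.
#' @export
fit_quasibinomial <- function(formula, data, design, trials = 1,
                              tol = 1e-8, max_iter = 100L) {
  mf <- model.frame(formula, data = data, na.action = stats::na.fail)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  if (n != design$n) stop("data rows must align with the design")
  if (length(trials) == 1L) trials <- rep(trials, n)
  if (any(trials <= 0)) stop("trials must be positive")
  if (any(y < 0 | y > 1)) stop("response must be a proportion in [0, 1]")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  a <- design$weights * trials # prior working weight
  beta <- irls_quasibinomial(y, X, a, tol, max_iter)
  eta <- drop(X %*% beta$coef)
  mu <- plogis(eta)

  # dispersion: weighted Pearson chi-square / residual df
  p <- ncol(X)
  pearson <- sum(a * (y - mu)^2 / (mu * (1 - mu)))
  dispersion <- pearson / (n - p)

  # design-based sandwich
  W <- a * mu * (1 - mu)
  A <- crossprod(X, W * X)
  Ainv <- solve(A)
  scores <- X * (a * (y - mu)) # n x p estimating-function contributions
  B <- taylor_var(scores, design)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2

  dev <- sum(binomial()$dev.resids(y, mu, a))
  mu0 <- sum(a * y) / sum(a)
  dev_null <- sum(binomial()$dev.resids(y, rep(mu0, n), a))

  sep <- any(mu < 1e-8 | mu > 1 - 1e-8)
  structure(list(
    coefficients = setNames(drop(beta$coef), colnames(X)),
    vcov = `dimnames<-`(V, list(colnames(X), colnames(X))),
    dispersion = dispersion,
    deviance = dev, null.deviance = dev_null,
    pseudo_r2 = 1 - dev / dev_null,
    df.residual = n - p, nobs = n,
    fitted.values = mu, linear.predictors = eta,
    prior.weights = a, trials = trials,
    converged = beta$converged, iter = beta$iter,
    separation = sep,
    formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    contrasts = attr(X, "contrasts"),
    design = design,
    lonely_strata = attr(B, "lonely_strata")),
    class = "alcospace_glm")
}

irls_quasibinomial <- function(y, X, a, tol, max_iter) {
  mu <- (a * y + 0.5) / (a + 1)
  eta <- qlogis(mu)
  beta <- rep(0, ncol(X))
  trace <- numeric(0)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    mu <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    W <- a * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    new_beta <- solve(crossprod(X, W * X), crossprod(X, W * z))
    delta <- max(abs(new_beta - beta))
    trace <- c(trace, delta)
    beta <- new_beta
    eta <- drop(X %*% beta)
    if (delta < tol) {
      return(list(coef = beta, converged = TRUE, iter = it))
    }
    # under complete separation coefficients diverge while the deviance
    # plateaus at its infimum; accept the fit (flagged by the caller via
    # boundary fitted values) instead of spinning to the iteration cap
    dev <- sum(binomial()$dev.resids(y, pmin(pmax(plogis(eta), 1e-10),
                                             1 - 1e-10), a))
    if (is.finite(dev_old) && abs(dev - dev_old) <
        1e-12 * (abs(dev) + 0.1)) {
      return(list(coef = beta, converged = TRUE, iter = it))
    }
    dev_old <- dev
  }
  stop(sprintf(
    "IRLS did not converge in %d iterations (last coefficient changes: %s)",
    max_iter, paste(signif(utils::tail(trace, 5), 3), collapse = ", ")))
}

#' @export
coef.alcospace_glm <- function(object, ...) object$coefficients

#' @export
vcov.alcospace_glm <- function(object, ...) object$vcov

#' @export
print.alcospace_glm <- function(x, ...) {
  cat("Design-weighted quasibinomial GLM\n")
  cat("  ", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, dispersion = %.3f, pseudo R2 = %.3f\n",
              x$nobs, x$dispersion, x$pseudo_r2))
  tab <- odds_ratios(x)
  print(as.data.frame(tab), digits = 3, row.names = FALSE)
  if (x$separation) cat("  note: fitted probabilities at the boundary (possible separation)\n")
  invisible(x)
}

#' Odds ratios with design-based confidence intervals
#'
#' `OR = exp(coef)` with Wald intervals `exp(coef +/- crit * SE)` on the
#' design-based standard errors, plus two-sided normal p-values and the
#' conventional significance stars.
#'
#' @param fit an [fit_quasibinomial()] result.
#' @param crit critical value; defaults to the design's (1.96).
#' @return tibble: `term`, `estimate` (log-odds), `se`, `or`, `lower`,
#'   `upper`, `p_value`, `stars`.
#' @export
odds_ratios <- function(fit, crit = fit$design$crit) {
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    term = names(b), estimate = unname(b), se = unname(se),
    or = exp(unname(b)),
    lower = exp(unname(b - crit * se)),
    upper = exp(unname(b + crit * se)),
    p_value = unname(p),
    stars = ifelse(p < 0.001, "***",
                   ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Predicted exposure probability for covariate profiles
#'
#' Back-transforms the linear predictor to the response scale (the
#' expected proportion of fixes exposed). Intervals are delta-method on
#' the logit scale, then back-transformed, so they are always ordered
#' and inside `[0, 1]`.
#'
#' @param fit an [fit_quasibinomial()] result.
#' @param newdata data frame of covariate profiles; factor columns must
#'   use levels seen in fitting.
#' @param crit critical value.
#' @return tibble: one row per profile with `eta`, `se_eta`, `p`,
#'   `lower`, `upper`.
#' @export
predict_probability <- function(fit, newdata, crit = fit$design$crit) {
  tt <- delete.response(fit$terms)
  for (v in names(fit$xlevels)) {
    if (v %in% names(newdata)) {
      bad <- setdiff(unique(as.character(newdata[[v]])), fit$xlevels[[v]])
      if (length(bad)) {
        stop(sprintf("unknown level(s) for %s: %s", v,
                     paste(bad, collapse = ", ")))
      }
    }
  }
  mf <- model.frame(tt, newdata, xlev = fit$xlevels)
  X <- model.matrix(tt, mf, contrasts.arg = fit$contrasts)
  eta <- unname(drop(X %*% coef(fit)))
  se <- unname(sqrt(rowSums((X %*% vcov(fit)) * X)))
  tibble::tibble(eta = eta, se_eta = se, p = plogis(eta),
                 lower = plogis(eta - crit * se),
                 upper = plogis(eta + crit * se))
}

#' Expected exposure duration over a wear period
#'
#' Converts a per-fix exposure probability (the expected proportion of
#' wear time exposed) into minutes over a wear period:
#' `duration = wear_minutes x p`. Interval endpoints scale identically.
#' Note that fixes are equal 10-s time slices, so 67 hours of wear is
#' 4020 minutes.
#'
#' @param p probability/ies in `[0, 1]`, or a [predict_probability()]
#'   tibble (columns `p`, `lower`, `upper`).
#' @param wear_minutes minutes of device wear (>= 0).
#' @return minutes, or a tibble `duration`, `lower`, `upper` when `p`
#'   is a prediction table.
#' @examples
#' exposure_duration(0.0079, 67 * 60) # 31.76 min
#' @export
exposure_duration <- function(p, wear_minutes) {
  if (any(wear_minutes < 0)) stop("wear_minutes must be non-negative")
  if (is.data.frame(p)) {
    assert_cols(p, c("p", "lower", "upper"), "prediction table")
    return(tibble::tibble(duration = wear_minutes * p$p,
                          lower = wear_minutes * p$lower,
                          upper = wear_minutes * p$upper))
  }
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  wear_minutes * p
}
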