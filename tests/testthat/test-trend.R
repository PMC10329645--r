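make_points <- function(year, h, D) {
  data.frame(year_index = year,
             period_start = as.Date(sprintf("%d-11-01", year)),
             h = h, D = D, K = h * D)
}

test_that("hazard points are K/D with exposure carried along", {
  r <- wolf_records("a", "male", "adult", "2010-11-01", "2011-10-31",
                    "dead", "human")
  pts <- hazard_points(summarize_by_year(r))
  expect_equal(pts$h, 1 / 365)
  expect_equal(pts$D, 365L)
  # zero-death period gives h = 0, zero-D periods are dropped with warning
  r2 <- wolf_records("b", "male", "adult", "2013-11-01", "2014-10-31",
                     "censored")
  s <- summarize_by_year(rbind(r, r2))
  expect_warning(pts2 <- hazard_points(s), "zero radio-days")
  expect_equal(pts2$h[pts2$year_index == 2013], 0)
})

test_that("points on an exact line are recovered with zero residual", {
  pts <- make_points(2005:2012, 1e-4 + 2e-5 * (0:7), rep(3000, 8))
  for (scheme in c("radio_days_squared", "inverse_variance", "unweighted")) {
    f <- fit_weighted_trend(pts, scheme)
    expect_equal(f$slope, 2e-5, tolerance = 1e-10)
    expect_equal(f$intercept, 1e-4, tolerance = 1e-10)
    expect_equal(f$residual_se, 0, tolerance = 1e-8)
  }
})

test_that("a two-point unweighted fit interpolates exactly", {
  pts <- make_points(c(2005, 2010), c(1e-4, 3e-4), c(2000, 4000))
  f <- fit_weighted_trend(pts, "unweighted")
  p <- predict_hazard(f, c(2005, 2010))
  expect_equal(p$h, c(1e-4, 3e-4))
  expect_true(is.na(f$residual_se))
  expect_error(fit_weighted_trend(pts[1, , drop = FALSE]), "at least 2")
})

test_that("coefficients match the normal-equations oracle on random data", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    year <- 2004 + sort(sample(0:15, n))
    D <- sample(500:6000, n, replace = TRUE)
    h <- pmax(rnorm(n, 1e-3, 5e-4), 1e-5)
    pts <- make_points(year, h, D)
    for (scheme in c("radio_days_squared", "inverse_variance",
                     "unweighted")) {
      f <- fit_weighted_trend(pts, scheme)
      w <- switch(scheme,
                  radio_days_squared = D^2,
                  inverse_variance = {
                    hbar <- sum(pts$K) / sum(D)
                    D / (hbar * (1 - hbar))
                  },
                  unweighted = rep(1, n))
      beta <- oracle_wls(year - min(year), h, w)
      expect_equal(f$intercept, beta[1], tolerance = 1e-10)
      expect_equal(f$slope, beta[2], tolerance = 1e-10)
    }
  }
})

test_that("fits are invariant to rescaling the weights", {
  pts <- make_points(2005:2015, abs(rnorm(11, 1e-3, 3e-4)), 1:11 * 500)
  f1 <- fit_weighted_trend(pts, "radio_days_squared")
  pts2 <- pts
  pts2$D <- pts$D * 10 # scales weights by 100
  # rescaled weights via direct lm comparison: same slope
  f2 <- fit_weighted_trend(pts2, "radio_days_squared")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
})

test_that("exposure-squared and inverse-variance schemes agree closely
           on study-like data", {
  sim <- simulate_wolves(sim_config(seed = 5))
  pts <- suppressWarnings(hazard_points(summarize_by_year(sim$records)))
  pre <- pts[pts$period_start < as.Date("2012-11-01") & pts$D > 300, ]
  f1 <- fit_weighted_trend(pre, "radio_days_squared")
  f2 <- fit_weighted_trend(pre, "inverse_variance")
  se1 <- sqrt(f1$covariance[2, 2])
  se2 <- sqrt(f2$covariance[2, 2])
  expect_lt(abs(f1$slope - f2$slope), se1 + se2)
})

test_that("survival trend is the exact transform of the hazard trend", {
  pts <- make_points(2005:2012, rep(6.705e-4, 8), rep(3000, 8))
  f <- fit_weighted_trend(pts)
  s <- survival_trend_from_hazard(f, 2005:2012)
  expect_equal(s$S_y, rep(yearly_survival(1 - 6.705e-4), 8),
               tolerance = 1e-9)
  # monotone decreasing transform swaps the band edges
  p <- predict_hazard(f, 2005:2012)
  expect_equal(s$S_low, (1 - p$h_high)^365, tolerance = 1e-12)
  # zero hazard means certain survival
  pts0 <- make_points(2005:2008, rep(0, 4), rep(3000, 4))
  s0 <- survival_trend_from_hazard(fit_weighted_trend(pts0), 2006)
  expect_equal(s0$S_y, 1)
})

test_that("the offset scan pinpoints a noise-free step month exactly", {
  # deterministic construction: 40 wolves continuously on air in annual
  # Nov-Oct cohorts, deaths placed so the empirical daily hazard is
  # exactly piecewise constant with its step at Nov 1, 2012. The aligned
  # anchor then fits both segments with zero residual, while any other
  # anchor has a straddling period with intermediate hazard.
  cohorts <- lapply(2004:2018, function(y) {
    n <- 40
    k <- if (y < 2012) 2 else 8
    suppressWarnings(wolf_records(
      wolf_id = sprintf("c%d-%02d", y, seq_len(n)),
      sex = "female", age_class = "adult",
      start_date = sprintf("%d-11-01", y),
      end_date = sprintf("%d-10-31", y + 1),
      fate = rep(c("dead", "censored"), c(k, n - k)),
      cause = rep(c("natural", "not_applicable"), c(k, n - k))))
  })
  rec <- do.call(rbind, cohorts)
  os <- suppressWarnings(offset_scan(rec, segmentation = "split_at_hunt"))
  best <- attr(os, "best")
  expect_equal(best[["before"]], 11)
  expect_equal(best[["during_and_after"]], 11)
  # leap-year periods hold 366 real days, so the aligned residual is not
  # exactly zero; it sits orders of magnitude below any misaligned anchor
  aligned <- os[os$anchor_month == 11, ]
  expect_true(all(aligned$residual_se < 1e-6))
  expect_true(all(os$residual_se[os$anchor_month != 11] > 2e-6))

  # single-segment scan runs and reports all 12 anchors
  os1 <- suppressWarnings(offset_scan(rec, segmentation = "single"))
  expect_equal(sort(os1$anchor_month), 1:12)
  expect_true(all(is.finite(os1$residual_se)))
})

test_that("cause-fraction trends are consistent and mirror symmetric causes", {
  sim <- simulate_wolves(sim_config(seed = 3))
  ys <- summarize_by_year(sim$records)
  ct <- cause_fraction_trend(ys)
  expect_equal(ct$points$M_human + ct$points$M_natural, ct$points$M_y,
               tolerance = 1e-12)
  expect_named(ct$fits, c("before", "during_and_after"))

  # all-human deaths: natural trend identically zero
  r <- wolf_records(sprintf("h%d", 1:12), "male", "adult",
                    sprintf("%d-11-01", 2005:2016),
                    sprintf("%d-10-20", 2006:2017),
                    "dead", "human")
  ct2 <- cause_fraction_trend(summarize_by_year(r))
  expect_true(all(ct2$points$M_natural == 0))
  expect_true(all(ct2$points$M_human == ct2$points$M_y))
})
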