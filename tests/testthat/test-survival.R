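test_that("daily survival is (D-K)/D with guarded inputs", {
  expect_equal(daily_survival(22373, 15), 22358 / 22373)
  expect_equal(daily_survival(100, 0), 1)
  expect_equal(daily_survival(10, 10), 0)
  expect_error(daily_survival(0, 0), "positive")
  expect_error(daily_survival(10, 11), "0 <= K <= D")
  # fractional K from imputation is accepted
  expect_equal(daily_survival(100, 2.5), 0.975)
})

test_that("yearly survival exponentiates daily survival", {
  expect_equal(yearly_survival(1), 1)
  expect_equal(round(yearly_survival(daily_survival(22373, 15)), 3), 0.783)
  expect_equal(round(yearly_survival(daily_survival(28233, 44)), 3), 0.566)
  expect_equal(yearly_mortality(yearly_survival(0.999)),
               1 - 0.999^365)
})

test_that("survival is monotone in deaths and exposure", {
  ks <- seq(0, 40, by = 5)
  sy_k <- yearly_survival(daily_survival(20000, ks))
  expect_true(all(diff(sy_k) < 0)) # more deaths, less survival
  ds <- seq(10000, 60000, by = 10000)
  sy_d <- yearly_survival(daily_survival(ds, 20))
  expect_true(all(diff(sy_d) > 0)) # more exposure at fixed K, more survival
})

test_that("cause partition splits mortality proportionally and exactly", {
  m <- cause_partitioned_mortality(0.2171, 6.92, 8.08)
  expect_equal(unname(m["human"] + m["natural"]), 0.2171)
  expect_equal(round(unname(m), 3), c(0.100, 0.117))
  expect_equal(cause_partitioned_mortality(0, 0, 0),
               c(human = 0, natural = 0))
  expect_error(cause_partitioned_mortality(0.2, 0, 0), "inconsistent")
  # hazard-based variant differs slightly from the proportional split
  mh <- cause_partitioned_mortality(0.2171, 6.92, 8.08,
                                    method = "hazard", D = 22373)
  expect_gt(abs(mh[["human"]] - m[["human"]]), 1e-4)
})

test_that("the confidence interval narrows as exposure grows", {
  widths <- vapply(c(1, 4, 16), function(f) {
    ci <- yearly_survival_ci(22373 * f, 15 * f)
    ci[["high"]] - ci[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # roughly 1/sqrt(D) on the daily scale: 4x exposure about halves it
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.2)
})

test_that("K = 0 intervals behave at the boundary", {
  ci <- yearly_survival_ci(5000, 0)
  expect_equal(ci[["low"]], 1)
  expect_equal(ci[["high"]], 1)
  ci2 <- yearly_survival_ci(3933, 2, clip = TRUE)
  expect_lte(ci2[["high"]], 1)
})

test_that("period_summary ties the pieces together consistently", {
  p <- period_summary(22373, 6.92, 8.08, label = "before")
  expect_equal(p$S_y, p$S_d^365)
  expect_equal(p$M_y, 1 - p$S_y)
  expect_equal(p$M_human + p$M_natural, p$M_y)
  expect_true(p$ci_low <= p$S_y && p$S_y <= p$ci_high)
})

test_that("the published table regenerates cell-for-cell from its inputs", {
  # printed survival (3 dp), CI bounds (2 dp), and mortalities (1 dp in %)
  expected <- data.frame(
    stratum = rep(c("all", "adult", "male", "female", "juvenile"), each = 3),
    period = rep(c("before", "during_and_after", "all"), 5),
    S_y = c(0.783, 0.566, 0.653, 0.773, 0.574, 0.656, 0.754, 0.583, 0.655,
            0.792, 0.565, 0.658, 0.831, 0.538, 0.640),
    lo = c(0.69, 0.48, 0.59, 0.67, 0.48, 0.58, 0.61, 0.45, 0.55,
           0.66, 0.43, 0.56, 0.64, 0.37, 0.50),
    hi = c(0.89, 0.67, 0.73, 0.89, 0.69, 0.74, 0.93, 0.76, 0.78,
           0.95, 0.74, 0.78, 1.07, 0.79, 0.82),
    M_y = c(21.7, 43.4, 34.7, 22.7, 42.6, 34.4, 24.6, 41.7, 34.5,
            20.8, 43.5, 34.2, 16.9, 46.2, 36.0),
    M_h = c(10.0, 35.8, 25.4, 11.3, 33.0, 24.0, 14.1, 23.8, 19.7,
            8.3, 41.0, 27.6, 0.0, 46.2, 30.0),
    M_n = c(11.7, 7.6, 9.3, 11.3, 9.6, 10.4, 10.6, 17.9, 14.8,
            12.5, 2.6, 6.6, 16.9, 0.0, 6.0))
  fix <- table1_fixture()
  got <- merge(fix, expected, by = c("stratum", "period"))
  expect_equal(nrow(got), 15)
  for (i in seq_len(nrow(got))) {
    p <- period_summary(got$D[i], got$K_human[i], got$K_natural[i])
    expect_equal(round(p$S_y, 3), got$S_y[i],
                 info = paste(got$stratum[i], got$period[i]))
    expect_equal(round(p$ci_low, 2), got$lo[i])
    expect_equal(round(p$ci_high, 2), got$hi[i])
    expect_equal(round(100 * p$M_y, 1), got$M_y[i])
    expect_equal(round(100 * p$M_human, 1), got$M_h[i])
    expect_equal(round(100 * p$M_natural, 1), got$M_n[i])
  }
})

test_that("fixture known counts re-impute to the printed fractional counts", {
  fix <- table1_fixture()
  per <- fix[fix$period != "all", ]
  for (i in seq_len(nrow(per))) {
    imp <- impute_causes(per$K_human_known[i], per$K_natural_known[i],
                         per$K_unknown[i])
    expect_equal(round(imp$K_human, 2), per$K_human[i],
                 info = paste(per$stratum[i], per$period[i]))
    expect_equal(round(imp$K_natural, 2), per$K_natural[i])
  }
})

test_that("mortality_table imputes per stratum and period on real-shaped data", {
  sim <- simulate_wolves(sim_config(n_wolves = 120, seed = 11))
  tab <- mortality_table(sim$records)
  expect_equal(nrow(tab), 15)
  # per-row internal consistency
  expect_equal(tab$M_human + tab$M_natural, tab$M_y)
  expect_equal(tab$S_y, tab$S_d^365)
  # the combined period sums the two imputed periods
  for (s in unique(tab$stratum)) {
    sub <- tab[tab$stratum == s, ]
    expect_equal(sub$K_human[sub$label == "all"],
                 sum(sub$K_human[sub$label != "all"]))
    expect_equal(sub$D[sub$label == "all"],
                 sum(sub$D[sub$label != "all"]))
  }
})
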