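#' Published period-by-stratum inputs of the Minnesota wolf study
#'
#' The printed radio-day totals and (imputation-resolved) death counts of
#' the 2004--2019 Minnesota wolf radiotelemetry study, one row per
#' demographic stratum and analysis period, as machine-readable fixtures
#' for regression tests and worked examples. `K_human` and `K_natural`
#' are the published fractional counts after proportional allocation of
#' the six unknown-cause deaths; `K_human_known`, `K_natural_known` and
#' `K_unknown` are the integer counts they imply (recovered by inverting
#' the allocation formula, which has a unique integer solution for every
#' row).
#'
#' @return A data.frame with columns `stratum` (`all`, `adult`, `male`,
#'   `female`, `juvenile`), `period` (`before`, `during_and_after`,
#'   `all`), `D`, `K_human`, `K_natural`, `K_human_known`,
#'   `K_natural_known`, `K_unknown`.
#' @examples
#' t1 <- table1_fixture()
#' subset(t1, stratum == "all" & period == "before")
#' @export
table1_fixture <- function() {
  df <- data.frame(
    stratum = rep(c("all", "adult", "male", "female", "juvenile"),
                  each = 3),
    period = rep(c("before", "during_and_after", "all"), 5),
    D = c(22373, 28233, 50606,
          18440, 22341, 40781,
          9035, 10841, 19876,
          9405, 11500, 20905,
          3933, 5892, 9825),
    K_human = c(6.92, 36.30, 43.22,
                6.50, 26.32, 32.82,
                4.00, 9.14, 13.14,
                2.40, 16.94, 19.34,
                0.00, 10.00, 10.00),
    K_natural = c(8.08, 7.70, 15.78,
                  6.50, 7.68, 14.18,
                  3.00, 6.86, 9.86,
                  3.60, 1.06, 4.66,
                  2.00, 0.00, 2.00),
    K_human_known = c(6, 33, 39,
                      6, 24, 30,
                      4, 8, 12,
                      2, 16, 18,
                      0, 9, 9),
    K_natural_known = c(7, 7, 14,
                        6, 7, 13,
                        3, 6, 9,
                        3, 1, 4,
                        1, 0, 1),
    K_unknown = c(2, 4, 6,
                  1, 3, 4,
                  0, 2, 2,
                  1, 1, 2,
                  1, 1, 2),
    stringsAsFactors = FALSE)
  df
}
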