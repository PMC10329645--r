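#' Radio-days of records inside a half-open window
#'
#' Counts the monitored days of each record that fall inside the window
#' `[window_start, window_end)`. An animal is monitored on every calendar
#' day from `start_date` through `end_date` inclusive: the death or
#' censoring day is an at-risk day, following the transmitter-day framing
#' of known-fate designs.
#'
#' @param records a `wolf_records` table.
#' @param window_start,window_end `Date`; half-open window
#'   `[window_start, window_end)`.
#' @return Integer vector of per-record day counts (0 for disjoint windows).
#' @examples
#' r <- wolf_records("a", "male", "adult", "2010-10-01", "2010-11-10",
#'                   "dead", "natural")
#' radio_days_in_window(r, as.Date("2010-11-01"), as.Date("2011-11-01")) # 10
#' @export
radio_days_in_window <- function(records, window_start, window_end) {
  lo <- pmax(as.numeric(records$start_date), as.numeric(as.Date(window_start)))
  hi <- pmin(as.numeric(records$end_date), as.numeric(as.Date(window_end)) - 1)
  as.integer(pmax(hi - lo + 1, 0))
}

# Date on which each record's animal is first counted as an adult
# (graduation is closed on the adult side: adult on the graduation day
# itself). Adult-collared animals are adult from start; a yearling
# graduates on the first graduation day strictly after collaring; a pup
# passes through yearling and graduates one graduation day later.
adult_from_date <- function(records, config = study_config()) {
  g1 <- next_month_day(records$start_date, config$graduation)
  out <- records$start_date
  yr <- records$age_class == "yearling"
  pp <- records$age_class == "pup"
  out[yr] <- g1[yr]
  out[pp] <- as.Date(sprintf("%04d-%02d-%02d",
                             as.integer(format(g1[pp], "%Y")) + 1L,
                             config$graduation[1], config$graduation[2]))
  out
}

#' Age class of an animal on a given day
#'
#' Applies the graduation-day rule: pups and yearlings are `"juvenile"`;
#' a yearling becomes `"adult"` on the first graduation day (April 15 by
#' default) after collaring, a pup one graduation day later; the animal is
#' adult on the graduation day itself.
#'
#' @param records a `wolf_records` table (recycled against `date`).
#' @param date `Date` within each record's monitored interval.
#' @param config a [study_config()].
#' @return Character vector, `"juvenile"` or `"adult"`.
#' @export
age_class_on <- function(records, date, config = study_config()) {
  date <- as.Date(date)
  if (any(date < records$start_date | date > records$end_date))
    stop("date outside the monitored interval for some record(s)")
  ifelse(date >= adult_from_date(records, config), "adult", "juvenile")
}

.strata <- c("all", "adult", "juvenile", "male", "female")

#' Aggregate collar histories into statistical-year summaries
#'
#' Partitions the data span into consecutive 12-month "statistical years"
#' anchored at `config$year_start` (half-open windows, so every monitored
#' day falls in exactly one period regardless of anchor), and accumulates
#' radio-days and cause-specific death counts per period and demographic
#' stratum. A death is assigned to the period containing `end_date`.
#' Age strata are filled day-accurately: an animal contributes juvenile
#' radio-days before its graduation date and adult radio-days from it,
#' within the same period if graduation falls inside it. Animals of
#' unknown sex are excluded from the sex strata but counted in `"all"`.
#'
#' @param records a `wolf_records` table.
#' @param config a [study_config()]; `config$year_start` sets the anchor.
#' @param strata if `FALSE`, only the `"all"` stratum is computed (faster;
#'   used by simulation-heavy scans).
#' @return A data.frame of class `"year_summary"` with columns
#'   `year_index` (calendar year of the period start), `period_start`,
#'   `period_end` (exclusive), `stratum`, `D`, `K_human`, `K_natural`,
#'   `K_unknown`, `K_total`. Periods may hold 366 real calendar days in
#'   leap years; the survival exponent stays 365 downstream.
#' @examples
#' r <- wolf_records("a", "female", "adult", "2010-11-01", "2011-10-31",
#'                   "censored")
#' summarize_by_year(r)[, c("year_index", "stratum", "D", "K_total")]
#' @export
summarize_by_year <- function(records, config = study_config(),
                              strata = TRUE) {
  if (nrow(records) == 0) return(empty_year_summary())
  first <- prev_month_day(min(records$start_date), config$year_start)
  starts <- seq(first, by = "12 months",
                length.out = 1 +
                  ceiling(as.numeric(max(records$end_date) - first) / 365))
  starts <- starts[starts <= max(records$end_date)]
  ends <- seq(starts[1], by = "12 months", length.out = length(starts) + 1)[-1]

  afrom <- if (strata) adult_from_date(records, config)
  dead <- records$fate == "dead"
  strat_names <- if (strata) .strata else "all"

  rows <- vector("list", length(starts) * length(strat_names))
  k <- 0L
  for (i in seq_along(starts)) {
    ps <- starts[i]; pe <- ends[i]
    died_here <- dead & records$end_date >= ps & records$end_date < pe
    d_all <- radio_days_in_window(records, ps, pe)
    for (s in strat_names) {
      if (s == "all") {
        D <- sum(d_all); sel <- died_here
      } else if (s %in% c("male", "female")) {
        in_s <- records$sex == s
        D <- sum(d_all[in_s]); sel <- died_here & in_s
      } else if (s == "adult") {
        lo <- pmax(as.numeric(records$start_date),
                   as.numeric(ps), as.numeric(afrom))
        hi <- pmin(as.numeric(records$end_date), as.numeric(pe) - 1)
        D <- sum(pmax(hi - lo + 1, 0))
        sel <- died_here & records$end_date >= afrom
      } else { # juvenile
        lo <- pmax(as.numeric(records$start_date), as.numeric(ps))
        hi <- pmin(as.numeric(records$end_date), as.numeric(pe) - 1,
                   as.numeric(afrom) - 1)
        D <- sum(pmax(hi - lo + 1, 0))
        sel <- died_here & records$end_date < afrom
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        year_index = as.integer(format(ps, "%Y")),
        period_start = ps, period_end = pe, stratum = s, D = D,
        K_human = sum(records$cause[sel] == "human"),
        K_natural = sum(records$cause[sel] == "natural"),
        K_unknown = sum(records$cause[sel] == "unknown"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$K_total <- out$K_human + out$K_natural + out$K_unknown
  class(out) <- c("year_summary", "data.frame")
  out
}

empty_year_summary <- function() {
  out <- data.frame(year_index = integer(0),
                    period_start = as.Date(character(0)),
                    period_end = as.Date(character(0)),
                    stratum = character(0), D = integer(0),
                    K_human = integer(0), K_natural = integer(0),
                    K_unknown = integer(0), K_total = integer(0))
  class(out) <- c("year_summary", "data.frame")
  out
}

#' Total radio-days of each record
#'
#' @param records a `wolf_records` table.
#' @return Integer vector: inclusive day count `end_date - start_date + 1`.
#' @export
total_radio_days <- function(records) {
  as.integer(records$end_date - records$start_date + 1)
}
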