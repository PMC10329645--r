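# Independent oracles used across tests.
#
# The day-ledger oracle expands every record into explicit per-day entries
# and tallies radio-days and deaths by period and stratum by brute force;
# it shares no code with summarize_by_year(). The WLS oracle solves the
# normal equations directly rather than going through lm()'s QR path.

random_records <- function(n, seed,
                           span = as.Date(c("2008-01-01", "2012-12-31"))) {
  set.seed(seed)
  s0 <- as.numeric(span[1])
  s1 <- as.numeric(span[2])
  start <- sample(s0:(s1 - 30), n, replace = TRUE)
  end <- pmin(start + sample(1:700, n, replace = TRUE), s1)
  fate <- sample(c("dead", "censored"), n, replace = TRUE)
  cause <- ifelse(fate == "dead",
                  sample(c("human", "natural", "unknown"), n, replace = TRUE),
                  "not_applicable")
  suppressWarnings(wolf_records(
    wolf_id = sprintf("R-%03d", seq_len(n)),
    sex = sample(c("male", "female", "unknown"), n, replace = TRUE),
    age_class = sample(c("pup", "yearling", "adult"), n, replace = TRUE),
    start_date = as.Date(start, origin = "1970-01-01"),
    end_date = as.Date(end, origin = "1970-01-01"),
    fate = fate, cause = cause))
}

# age class on each of a record's days, by counting graduation days passed
oracle_ages <- function(rec_row, days) {
  yrs <- seq(as.integer(format(rec_row$start_date, "%Y")) - 1,
             as.integer(format(max(days), "%Y")) + 1)
  apr15 <- as.Date(sprintf("%d-04-15", yrs))
  apr15 <- apr15[apr15 > rec_row$start_date]
  g <- findInterval(as.numeric(days), as.numeric(apr15)) # graduations passed
  need <- switch(rec_row$age_class, adult = 0, yearling = 1, pup = 2)
  ifelse(g >= need, "adult", "juvenile")
}

# expand records into one explicit per-day ledger (anchor-independent)
oracle_ledger <- function(records) {
  idx <- rep(seq_len(nrow(records)), total_radio_days(records))
  day <- do.call(c, lapply(seq_len(nrow(records)), function(i)
    seq(records$start_date[i], records$end_date[i], by = "1 day")))
  age <- do.call(c, lapply(seq_len(nrow(records)), function(i)
    oracle_ages(records[i, ],
                seq(records$start_date[i], records$end_date[i],
                    by = "1 day"))))
  lt <- as.POSIXlt(day)
  list(day = day, y = lt$year + 1900L, m = lt$mon + 1L, age = age,
       sex = records$sex[idx],
       death = records$fate[idx] == "dead" & day == records$end_date[idx],
       cause = records$cause[idx])
}

# per-day ledger aggregation for anchor (month, 1)
oracle_summarize <- function(records, anchor_month,
                             ledger = oracle_ledger(records)) {
  day <- ledger$day
  y <- ledger$y
  period <- ifelse(ledger$m >= anchor_month, y, y - 1L)
  age <- ledger$age
  sex <- ledger$sex
  death <- ledger$death
  cause <- ledger$cause

  out <- list()
  for (s in c("all", "adult", "juvenile", "male", "female")) {
    mask <- switch(s, all = rep(TRUE, length(day)),
                   adult = age == "adult", juvenile = age == "juvenile",
                   male = sex == "male", female = sex == "female")
    m <- rowsum(cbind(D = 1,
                      K_human = death & cause == "human",
                      K_natural = death & cause == "natural",
                      K_unknown = death & cause == "unknown")[mask, ,
                                                              drop = FALSE],
                period[mask])
    if (nrow(m) == 0) next
    out[[s]] <- data.frame(year_index = as.integer(rownames(m)),
                           stratum = s, D = m[, "D"],
                           K_human = m[, "K_human"],
                           K_natural = m[, "K_natural"],
                           K_unknown = m[, "K_unknown"],
                           row.names = NULL)
  }
  do.call(rbind, out)
}

# closed-form weighted least squares via the normal equations
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1])
}

# study-scale synthetic defaults reused by several stochastic tests
flat_sim_config <- function(h_human = 6.92 / 22373,
                            h_natural = 8.08 / 22373, ...) {
  sim_config(hazard_schedule = data.frame(
    start = as.Date("2004-01-01"),
    h_human = h_human, h_natural = h_natural), ...)
}

step_sim_config <- function(mult, ...) {
  sim_config(hazard_schedule = data.frame(
    start = as.Date(c("2004-01-01", "2012-11-01")),
    h_human = c(6.92 / 22373, mult * 6.92 / 22373),
    h_natural = c(8.08 / 22373, mult * 8.08 / 22373)), ...)
}
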