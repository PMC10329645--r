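#' Annual daily-hazard points from year summaries
#'
#' Converts per-statistical-year summaries into the points used by the
#' trend regressions: the daily unit hazard `h = K_total / D` (the
#' complement of the daily survival estimate) with its exposure `D`
#' carried along for weighting. Periods with `D = 0` carry no information
#' and are dropped with a warning.
#'
#' @param summaries a `year_summary` table; only the `"all"` stratum is
#'   used if several strata are present.
#' @return A data.frame with columns `year_index`, `h`, `D`, `K`.
#' @export
hazard_points <- function(summaries) {
  s <- summaries[summaries$stratum == "all", ]
  drop <- s$D == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " period(s) with zero radio-days: ",
            paste(s$year_index[drop], collapse = ", "))
    s <- s[!drop, ]
  }
  data.frame(year_index = s$year_index, period_start = s$period_start,
             h = s$K_total / s$D, D = s$D, K = s$K_total)
}

#' Weighted linear trend of annual daily hazard
#'
#' Fits `h ~ year` by weighted least squares. Yearly radio-day coverage in
#' a staggered-entry study is uneven, so unweighted regression would let
#' sparsely monitored years (few collared animals, or a partial first
#' year) pull the trend; weighting suppresses that bias. Supported
#' schemes:
#' \describe{
#'   \item{`radio_days_squared`}{weights \eqn{D^2} (default).}
#'   \item{`inverse_variance`}{weights \eqn{1/\widehat{Var}(h)} with
#'     \eqn{\widehat{Var}(h) = \bar h (1 - \bar h)/D}, where \eqn{\bar h}
#'     is the pooled hazard \eqn{\sum K / \sum D}. Using the pooled rate
#'     keeps the weights defined for years with zero deaths; since
#'     \eqn{\bar h} is a constant factor, these weights are proportional
#'     to \eqn{D} and the fit is invariant to it.}
#'   \item{`unweighted`}{ordinary least squares.}
#' }
#' The year covariate is centred at the first fitted year
#' (`ref_year`), so the intercept is the fitted hazard at the start of the
#' segment.
#'
#' @param points data.frame with columns `year_index`, `h`, `D` (and
#'   optionally `K`), as from [hazard_points()].
#' @param scheme weighting scheme, see Details.
#' @param ci_level level for the confidence band, default 0.95.
#' @return An object of class `"trend_fit"`: list with `slope`,
#'   `intercept` (hazard at `ref_year`), `ref_year`, `scheme`,
#'   `residual_se` (weighted residual standard error; `NA` with 2 points),
#'   `n_points`, `covariance` (2x2), `ci_level` and the underlying `lm`
#'   fit.
#' @export
fit_weighted_trend <- function(points,
                               scheme = c("radio_days_squared",
                                          "inverse_variance", "unweighted"),
                               ci_level = 0.95) {
  scheme <- match.arg(scheme)
  if (nrow(points) < 2)
    stop("at least 2 annual points are required to fit a trend")
  w <- switch(scheme,
    radio_days_squared = points$D^2,
    inverse_variance = {
      if (!"K" %in% names(points))
        points$K <- points$h * points$D
      hbar <- sum(points$K) / sum(points$D)
      if (hbar <= 0 || hbar >= 1)
        stop("inverse_variance weights degenerate (pooled hazard ",
             signif(hbar, 3), "); use scheme = 'radio_days_squared'")
      points$D / (hbar * (1 - hbar))
    },
    unweighted = rep(1, nrow(points)))
  # normalize to mean 1: coefficients are invariant to weight scale, and
  # this makes residual_se comparable across fits (e.g. anchor scans)
  w <- w / mean(w)
  ref <- min(points$year_index)
  df <- data.frame(h = points$h, t = points$year_index - ref, w = w)
  fit <- lm(h ~ t, data = df, weights = w)
  structure(list(
    slope = unname(coef(fit)[["t"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    ref_year = ref,
    scheme = scheme,
    residual_se = if (nrow(points) > 2) summary(fit)$sigma else NA_real_,
    n_points = nrow(points),
    covariance = vcov(fit),
    ci_level = ci_level,
    lm_fit = fit), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted hazard trend (%s): h(year) = %.4g %+.4g * (year - %d)\n",
    x$scheme, x$intercept, x$slope, x$ref_year))
  cat(sprintf("  n = %d, residual SE = %.4g\n", x$n_points, x$residual_se))
  invisible(x)
}

#' Fitted hazard and pointwise confidence band
#'
#' @param fit a [fit_weighted_trend()] object.
#' @param years integer years at which to evaluate the trend.
#' @return Data.frame `year`, `h`, `h_low`, `h_high` (pointwise
#'   mean-prediction band at the fit's `ci_level`).
#' @export
predict_hazard <- function(fit, years) {
  nd <- data.frame(t = years - fit$ref_year)
  p <- predict(fit$lm_fit, newdata = nd, interval = "confidence",
               level = fit$ci_level)
  data.frame(year = years, h = p[, "fit"],
             h_low = p[, "lwr"], h_high = p[, "upr"])
}

#' Yearly-survival trend derived from a hazard trend
#'
#' Transforms the fitted daily-hazard line and its pointwise band to the
#' yearly-survival scale: \eqn{S_y(year) = (1 - \hat h(year))^{365}}. The
#' transform is decreasing, so the hazard band's upper edge maps to the
#' survival band's lower edge.
#'
#' @param fit a [fit_weighted_trend()] object.
#' @param years years at which to evaluate.
#' @param year_length_days exponent, default 365.
#' @return Data.frame `year`, `S_y`, `S_low`, `S_high`.
#' @export
survival_trend_from_hazard <- function(fit, years, year_length_days = 365) {
  p <- predict_hazard(fit, years)
  bad <- p$h < 0 | p$h > 1
  if (any(bad))
    stop("fitted hazard outside [0, 1] in year(s) ",
         paste(p$year[bad], collapse = ", "))
  data.frame(year = p$year,
             S_y = (1 - p$h)^year_length_days,
             S_low = (1 - pmin(pmax(p$h_high, 0), 1))^year_length_days,
             S_high = (1 - pmin(pmax(p$h_low, 0), 1))^year_length_days)
}

#' Scan statistical-year anchors for the best-fitting trend
#'
#' Re-aggregates the collar histories under each of the 12 first-of-month
#' statistical-year anchors, fits the weighted hazard trend (one trend
#' over the whole span, or two trends split at `config$hunt_start`), and
#' records each segment's weighted residual standard error. The anchor
#' aligning the statistical year with the true structure of the hazard
#' (e.g. a step change at a season opening) yields the smallest residual
#' scatter, so the minimizing anchor is an internal, data-driven check on
#' the choice of statistical year.
#'
#' @param records a `wolf_records` table spanning at least 3 statistical
#'   years.
#' @param config a [study_config()]; its anchor is ignored (all 12 are
#'   tried), `hunt_start` sets the split.
#' @param segmentation `"single"` (one trend) or `"split_at_hunt"` (one
#'   trend per side of `config$hunt_start`).
#' @param scheme weighting scheme for [fit_weighted_trend()].
#' @return A data.frame of class `"offset_scan"`: `anchor_month`,
#'   `segment` (`"single"`, `"before"`, `"during_and_after"`),
#'   `residual_se`, `n_points`; attribute `"best"` names the minimizing
#'   anchor month per segment.
#' @export
offset_scan <- function(records, config = study_config(),
                        segmentation = c("split_at_hunt", "single"),
                        scheme = "radio_days_squared") {
  segmentation <- match.arg(segmentation)
  span_years <- as.numeric(max(records$end_date) - min(records$start_date)) / 365
  if (span_years < 3)
    stop("records must span at least 3 statistical years")
  rows <- list()
  for (m in 1:12) {
    cfg <- config
    cfg$year_start <- c(m, 1L)
    pts <- hazard_points(summarize_by_year(records, cfg, strata = FALSE))
    if (segmentation == "single") {
      f <- fit_weighted_trend(pts, scheme)
      rows[[length(rows) + 1]] <- data.frame(
        anchor_month = m, segment = "single",
        residual_se = f$residual_se, n_points = f$n_points)
    } else {
      # a period belongs to the post-hunt segment if most of it falls
      # after the hunt start (midpoint rule; exact boundary when the
      # anchor aligns with the hunt month)
      post_side <- pts$period_start + 182 >= config$hunt_start
      pre <- pts[!post_side, ]
      post <- pts[post_side, ]
      for (seg in list(list("before", pre),
                       list("during_and_after", post))) {
        if (nrow(seg[[2]]) >= 3) {
          f <- fit_weighted_trend(seg[[2]], scheme)
          rows[[length(rows) + 1]] <- data.frame(
            anchor_month = m, segment = seg[[1]],
            residual_se = f$residual_se, n_points = f$n_points)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  best <- vapply(split(out, out$segment), function(d)
    d$anchor_month[which.min(d$residual_se)], numeric(1))
  attr(out, "best") <- best
  class(out) <- c("offset_scan", "data.frame")
  out
}

#' Per-year cause-specific mortality trends
#'
#' Computes each statistical year's yearly mortality, partitions it into
#' human and natural components (unknown-cause deaths allocated by the
#' containing analysis period's known-cause ratio), and fits *unweighted*
#' linear trends of each component against year, separately within the
#' before and during-and-after segments.
#'
#' @param summaries a `year_summary` table (stratum `"all"` used).
#' @param config a [study_config()]; `hunt_start` splits the segments.
#' @param year_length_days exponent, default 365.
#' @return A list of class `"cause_trend"`: `points` (data.frame `year`,
#'   `segment`, `M_y`, `M_human`, `M_natural`) and `fits`, a nested list
#'   `fits[[segment]][[cause]]` of `lm` objects.
#' @export
cause_fraction_trend <- function(summaries, config = study_config(),
                                 year_length_days = 365) {
  s <- summaries[summaries$stratum == "all" & summaries$D > 0, ]
  seg <- ifelse(s$period_start < config$hunt_start,
                "before", "during_and_after")
  # period-level imputation ratio applied to each year's unknown deaths
  ratio <- lapply(split(s, seg), function(d) {
    kh <- sum(d$K_human); kn <- sum(d$K_natural)
    if (kh + kn == 0) c(human = 0.5, natural = 0.5)
    else c(human = kh / (kh + kn), natural = kn / (kh + kn))
  })
  kh_imp <- s$K_human + s$K_unknown *
    vapply(seg, function(g) ratio[[g]][["human"]], numeric(1))
  kn_imp <- s$K_natural + s$K_unknown *
    vapply(seg, function(g) ratio[[g]][["natural"]], numeric(1))
  m_y <- 1 - daily_survival(s$D, s$K_total)^year_length_days
  ktot <- pmax(kh_imp + kn_imp, 1e-12)
  pts <- data.frame(year = s$year_index, segment = seg, M_y = m_y,
                    M_human = ifelse(s$K_total == 0, 0, m_y * kh_imp / ktot),
                    M_natural = ifelse(s$K_total == 0, 0, m_y * kn_imp / ktot))
  fits <- lapply(split(pts, pts$segment), function(d) {
    if (nrow(d) < 2)
      stop("segment with fewer than 2 yearly points: cannot fit trend")
    list(human = lm(M_human ~ year, data = d),
         natural = lm(M_natural ~ year, data = d))
  })
  structure(list(points = pts, fits = fits), class = "cause_trend")
}
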