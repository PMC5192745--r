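#' Environmental-harshness metrics for one nonbreeding season
#'
#' Summarizes the daily weather over the window from the end of
#' reproduction (July 1 of `season_start_year`) to the beginning of the
#' next breeding season (March 31 of `season_start_year + 1`), inclusive:
#'
#' * `tnz_days`: days outside the thermal neutral zone, i.e. with
#'   temperature >= 35 C or <= 15 C. The hot criterion is evaluated on the
#'   daily maximum and the cold criterion on the daily minimum (the
#'   physiologically binding extremes); `temp_stat = "mean"` applies both
#'   bounds to the daily mean instead.
#' * `fdd`: freezing-degree days, days with minimum temperature below 0 C
#'   (strict inequality).
#' * `accumulated_precip`: summed daily precipitation (mm).
#'
#' @param w weather data.frame (see [read_weather()]).
#' @param season_start_year integer year t; the window runs July 1 year t
#'   to March 31 year t+1.
#' @param temp_stat `"extreme"` (default) or `"mean"`.
#' @param partial allow an incompletely covered window? If `FALSE`
#'   (default), missing days raise an error; if `TRUE`, a warning.
#' @return data.frame row with `season_start_year`, `tnz_days`, `fdd`,
#'   `accumulated_precip`, `n_days`.
#' @export
harshness_metrics <- function(w, season_start_year,
                              temp_stat = c("extreme", "mean"),
                              partial = FALSE) {
  temp_stat <- match.arg(temp_stat)
  from <- as.Date(sprintf("%d-07-01", season_start_year))
  to <- as.Date(sprintf("%d-03-31", season_start_year + 1))
  win <- w[w$date >= from & w$date <= to, , drop = FALSE]
  expected <- as.integer(to - from) + 1L
  if (nrow(win) == 0) stop("no weather data in window ", from, " to ", to)
  if (nrow(win) < expected) {
    msg <- sprintf("window %s to %s has %d missing day(s)",
                   from, to, expected - nrow(win))
    if (!partial) stop(msg) else warning(msg)
  }
  tnz <- if (temp_stat == "extreme") {
    sum(win$tmax >= 35 | win$tmin <= 15)
  } else {
    tm <- (win$tmin + win$tmax) / 2
    sum(tm >= 35 | tm <= 15)
  }
  data.frame(season_start_year = season_start_year,
             tnz_days = tnz,
             fdd = sum(win$tmin < 0),
             accumulated_precip = sum(win$precip),
             n_days = nrow(win))
}

#' Harshness metrics for a series of seasons
#'
#' @param w weather data.frame.
#' @param years integer vector of season start years.
#' @param ... passed to [harshness_metrics()].
#' @return data.frame, one row per season.
#' @export
harshness_series <- function(w, years, ...) {
  do.call(rbind, lapply(years, function(y) harshness_metrics(w, y, ...)))
}

#' Selection differential on heterozygosity
#'
#' Directional selection differential `S = cov(omega, het)` where
#' `omega = w / mean(w)` is relative fitness (here recruitment 0/1 divided
#' by the recruitment rate) and the covariance uses the population
#' (denominator n) convention, so that S equals the recruits' mean
#' heterozygosity minus the population mean exactly.
#'
#' @param het numeric heterozygosity vector.
#' @param recruited 0/1 fitness component.
#' @param denom `"n"` (population covariance, default) or `"n-1"`.
#' @return the selection differential (0 when fitness or heterozygosity is
#'   constant).
#' @export
selection_differential <- function(het, recruited, denom = c("n", "n-1")) {
  denom <- match.arg(denom)
  ok <- !is.na(het) & !is.na(recruited)
  het <- het[ok]; w <- as.numeric(recruited[ok])
  n <- length(w)
  if (n < 2) stop("need at least 2 individuals")
  if (mean(w) == 0) stop("relative fitness undefined: zero recruits")
  omega <- w / mean(w)
  S <- mean(omega * het) - mean(omega) * mean(het)
  if (denom == "n-1") S <- S * n / (n - 1)
  S
}

#' Per-year selection differentials by marker subset
#'
#' @param yd data.frame with `year`, `recruited` and the three subset
#'   heterozygosities (`het_total`, `het_neutral`, `het_functional`), e.g.
#'   from [year_dataset()] with `year = NULL`.
#' @param denom covariance denominator convention, see
#'   [selection_differential()].
#' @return data.frame with one row per year: `S_total`, `S_neutral`,
#'   `S_functional`, `n`, and the per-subset mean heterozygosities.
#' @export
selection_series <- function(yd, denom = "n") {
  years <- sort(unique(yd$year))
  rows <- lapply(years, function(y) {
    d <- yd[yd$year == y & !is.na(yd$recruited), , drop = FALSE]
    S <- vapply(c("het_total", "het_neutral", "het_functional"),
                function(cl) selection_differential(d[[cl]], d$recruited,
                                                    denom = denom),
                numeric(1))
    data.frame(year = y, S_total = S[1], S_neutral = S[2],
               S_functional = S[3], n = nrow(d),
               mean_het_total = mean(d$het_total, na.rm = TRUE),
               mean_het_neutral = mean(d$het_neutral, na.rm = TRUE),
               mean_het_functional = mean(d$het_functional, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simple linear regression between two yearly series
#'
#' Pearson correlation, OLS slope, and the two-sided p-value from the t
#' distribution with n - 2 degrees of freedom (identical for the
#' correlation and the slope).
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs; `x` must not be
#'   constant).
#' @return list with `r`, `slope`, `intercept`, `p`, `n`.
#' @export
regress_series <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  if (var(x) == 0) stop("x is constant: regression undefined")
  r <- cor(x, y)
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, slope = slope, intercept = intercept, p = p, n = n)
}

#' Selection differentials versus environmental harshness
#'
#' Regresses each subset's yearly selection differential on each harshness
#' metric (the Table-3-style layout) and appends the temporal trend rows of
#' annual mean heterozygosity on year.
#'
#' @param sel output of [selection_series()].
#' @param harsh output of [harshness_series()] for the same years.
#' @return data.frame with one row per (subset x metric) regression plus
#'   one trend row per subset: `subset`, `metric`, `r`, `slope`, `p`, `n`.
#' @export
selection_vs_harshness <- function(sel, harsh) {
  stopifnot(all(sel$year %in% harsh$season_start_year))
  h <- harsh[match(sel$year, harsh$season_start_year), ]
  metrics <- c(tnz_days = "tnz_days", fdd = "fdd",
               accumulated_precip = "accumulated_precip")
  subsets <- c(total = "S_total", neutral = "S_neutral",
               functional = "S_functional")
  rows <- list()
  for (s in names(subsets)) {
    for (m in names(metrics)) {
      rg <- regress_series(h[[metrics[m]]], sel[[subsets[s]]])
      rows[[paste(s, m)]] <- data.frame(
        subset = s, metric = m, r = rg$r, slope = rg$slope, p = rg$p,
        n = rg$n, stringsAsFactors = FALSE)
    }
    tr <- regress_series(sel$year, sel[[paste0("mean_het_", s)]])
    rows[[paste(s, "trend")]] <- data.frame(
      subset = s, metric = "het_trend_year", r = tr$r, slope = tr$slope,
      p = tr$p, n = tr$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
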