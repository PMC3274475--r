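# Percentile day-rank summaries, NAAQS exceedance counting, map class breaks
# and population-at-risk tables.

#' Daily-standard configuration for a pollutant
#'
#' Bundles the daily NAAQS threshold and the map-classification geometry.
#' Defaults follow the daily standards used throughout the package: 35 ug/m3
#' (24-hour PM2.5) and 75 ppb (8-hour ozone), with five map classes of width
#' 10 units centred on the standard.
#'
#' @param pollutant `"pm25"` or `"ozone"`.
#' @param threshold daily standard; defaults to 35 (pm25) or 75 (ozone).
#' @param class_width width of the equal-length map classes (default 10).
#' @param n_classes number of map classes (only 5 is supported).
#' @return object of class `standard_config`.
#' @export
standard_config <- function(pollutant = c("pm25", "ozone"), threshold = NULL,
                            class_width = 10, n_classes = 5L) {
  pollutant <- match.arg(pollutant)
  if (is.null(threshold)) {
    threshold <- if (pollutant == "pm25") 35 else 75
  }
  stopifnot(threshold > 0, class_width > 0)
  if (n_classes != 5L) stop("only n_classes = 5 is supported")
  structure(list(pollutant = pollutant, threshold = threshold,
                 class_width = class_width, n_classes = 5L),
            class = "standard_config")
}

#' k-th-highest day of a daily series
#'
#' The pipeline reads "the p-tail percentile of a D-day series" as a day
#' rank: k = max(1, round(p * D)) with half-away-from-zero rounding, and
#' returns the k-th largest value. For a full year (D = 365) and p = 0.02
#' this is the 7th-highest day; for p = 0.10 it is the 37th
#' (0.10 * 365 = 36.5 rounds away from zero). The applied rank `k` is always
#' returned alongside the value so downstream tables can show which day-rank
#' convention was used.
#'
#' @param values non-empty numeric daily series.
#' @param p tail fraction in (0, 1).
#' @return list with elements `value` (the k-th largest) and `k`.
#' @export
kth_highest <- function(values, p) {
  if (length(values) == 0L) stop("empty series")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must be a single value in (0, 1)")
  }
  D <- length(values)
  k <- max(1L, as.integer(floor(p * D + 0.5)))  # half away from zero (p*D > 0)
  list(value = sort(values, decreasing = TRUE)[k], k = k)
}

#' Count days exceeding the daily standard
#'
#' A day counts as an exceedance when its value is strictly greater than the
#' threshold (`strict = FALSE` switches to `>=` for sensitivity analyses).
#'
#' @param values numeric daily series.
#' @param cfg a [standard_config()] (or a bare numeric threshold).
#' @param strict strict inequality (default `TRUE`).
#' @return integer count in \[0, length(values)\].
#' @export
count_exceedance_days <- function(values, cfg, strict = TRUE) {
  if (any(!is.finite(values))) stop("series contains non-finite values")
  thr <- if (inherits(cfg, "standard_config")) cfg$threshold else cfg
  if (strict) sum(values > thr) else sum(values >= thr)
}

#' Map class breaks around the daily standard
#'
#' Five classes with the second-highest cut point pinned to the standard t
#' and the rest at equal widths w: breaks (t-2w, t-w, t, t+w) delimit the
#' classes (-Inf, t-2w], (t-2w, t-w], (t-w, t], (t, t+w], (t+w, Inf). For
#' PM2.5 (t = 35, w = 10) the breaks are 15/25/35/45; for ozone (t = 75)
#' they are 55/65/75/85.
#'
#' @param cfg a [standard_config()].
#' @return numeric vector of 4 interior break points, increasing.
#' @export
class_breaks <- function(cfg) {
  stopifnot(inherits(cfg, "standard_config"))
  t <- cfg$threshold; w <- cfg$class_width
  c(t - 2 * w, t - w, t, t + w)
}

#' Assign values to map classes
#'
#' Classes are left-open, right-closed on the interior breaks from
#' [class_breaks()], so every finite value maps to exactly one class index
#' in 1..5 (1 = lowest).
#'
#' @param values numeric vector.
#' @param cfg a [standard_config()].
#' @return integer class indices.
#' @export
classify_values <- function(values, cfg) {
  br <- class_breaks(cfg)
  findInterval(values, br, left.open = TRUE) + 1L
}

#' Population at risk by census unit
#'
#' Rolls block-group exceedance records up to a census level: per unit, the
#' at-risk population is the summed population of member block groups whose
#' exceedance-day count is at least `min_days`; the percentage is relative to
#' the unit's total population. Units with zero total population get a
#' missing percentage.
#'
#' @param exceedance data.frame/data.table with columns `geoid` (12-digit BG
#'   GEOID), `days_exceeding`, `population`.
#' @param min_days minimum exceedance days (>= 1) qualifying a BG as at risk;
#'   may be a vector (e.g. `c(7, 14, 28)`), giving one block of rows each.
#' @param level census level to report (`"tract"`, `"county"`, `"state"`,
#'   `"national"`).
#' @return data.table with columns `geoid`, `level`, `min_days`,
#'   `population_at_risk`, `total_population`, `percent`.
#' @export
population_at_risk <- function(exceedance, min_days = c(7L, 14L, 28L),
                               level = "state") {
  level <- match.arg(level, c("tract", "county", "state", "national"))
  exceedance <- data.table::as.data.table(exceedance)
  need <- c("geoid", "days_exceeding", "population")
  if (!all(need %in% names(exceedance))) {
    stop("exceedance table needs columns geoid, days_exceeding, population")
  }
  check_geoid(exceedance$geoid)
  if (any(min_days < 1)) stop("min_days must be >= 1")

  population <- days_exceeding <- NULL
  unit_vec <- if (level == "national") rep("US", nrow(exceedance))
              else substr(exceedance$geoid, 1L, .CGU_PREFIX[[level]])
  dt <- data.table::copy(exceedance)
  data.table::set(dt, j = "unit", value = unit_vec)
  out <- lapply(sort(as.integer(min_days)), function(md) {
    r <- dt[, list(
      min_days = md,
      population_at_risk = sum(population[days_exceeding >= md]),
      total_population = sum(population)), by = "unit"]
    r[, `:=`(percent = ifelse(total_population > 0,
                              100 * population_at_risk / total_population,
                              NA_real_))]
    r
  })
  res <- data.table::rbindlist(out)
  data.table::setnames(res, "unit", "geoid")
  res[, `:=`(level = level)]
  data.table::setcolorder(res, c("geoid", "level", "min_days",
                                 "population_at_risk", "total_population",
                                 "percent"))
  data.table::setkey(res, geoid, min_days)
  res[]
}

#' Percentile and exceedance summary per unit series
#'
#' Convenience wrapper producing, for each unit in a long series table, the
#' day-rank percentile values (98th and 90th by default), their applied day
#' ranks, map classes, and (for block-group concentration series) the
#' exceedance-day count.
#'
#' @param series data.table with columns `geoid`, `date`, and a value column.
#' @param cfg a [standard_config()].
#' @param value_col name of the value column (`"mu"` for BG concentrations,
#'   `"pe"` for aggregated exposures).
#' @param tails tail fractions (default `c(p98 = 0.02, p90 = 0.10)`).
#' @param count_exceedance also count exceedance days (meaningful for BG
#'   concentration series).
#' @return one row per unit with value, rank and class columns per tail.
#' @export
summarize_series <- function(series, cfg, value_col = "mu",
                             tails = c(p98 = 0.02, p90 = 0.10),
                             count_exceedance = TRUE) {
  stopifnot(inherits(cfg, "standard_config"))
  series <- data.table::as.data.table(series)
  if (!value_col %in% names(series)) {
    stop(sprintf("column '%s' not found in series", value_col))
  }
  res <- series[, {
    v <- .SD[[value_col]]
    row <- list()
    for (nm in names(tails)) {
      kh <- kth_highest(v, tails[[nm]])
      row[[paste0(nm, "_value")]] <- kh$value
      row[[paste0(nm, "_k")]] <- kh$k
      row[[paste0("class_", nm)]] <- classify_values(kh$value, cfg)
    }
    if (count_exceedance) {
      row$days_exceeding <- count_exceedance_days(v, cfg)
    }
    row
  }, by = "geoid"]
  res[]
}
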