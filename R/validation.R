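# Validation of block-group estimates against ground monitoring stations:
# pairing, MAD, Pearson correlation, absolute-deviation distribution, and
# stratified reports (year / season / urban-rural).

#' Pair station observations with block-group estimates
#'
#' One pair per (station, date) where both an observation and an estimate for
#' the station's block group exist. Block groups hosting several stations
#' contribute one pair per station per date. Stations referencing a block
#' group with no estimate series are excluded with a warning and counted in
#' the attribute `n_excluded_stations`.
#'
#' @param stations data.frame/data.table with columns `station_id`,
#'   `bg_geoid`, `date`, `observed` and optionally `urban_rural`.
#' @param bg_est data.table from [downscale_all()] (`geoid`, `date`, `mu`).
#' @return data.table of pairs: `station_id`, `bg_geoid`, `date`, `observed`,
#'   `estimated` (+ `urban_rural` if supplied).
#' @export
pair_observations <- function(stations, bg_est) {
  stations <- data.table::as.data.table(stations)
  bg_est <- data.table::as.data.table(bg_est)
  need <- c("station_id", "bg_geoid", "date", "observed")
  if (!all(need %in% names(stations))) {
    stop("stations must have columns station_id, bg_geoid, date, observed")
  }
  if (any(!is.finite(stations$observed))) stop("observed values must be finite")
  check_geoid(stations$bg_geoid)

  unknown <- setdiff(unique(stations$bg_geoid), unique(bg_est$geoid))
  n_excluded <- 0L
  if (length(unknown)) {
    excl <- stations$bg_geoid %in% unknown
    n_excluded <- length(unique(stations$station_id[excl]))
    warning(sprintf(
      "%d station(s) reference BG(s) with no estimates and were excluded",
      n_excluded))
    stations <- stations[!excl]
  }
  est <- bg_est[, c("geoid", "date", "mu")]
  data.table::setnames(est, c("geoid", "mu"), c("bg_geoid", "estimated"))
  est[, `:=`(date = as.character(date))]
  stations <- data.table::copy(stations)[, `:=`(date = as.character(date))]
  pairs <- merge(stations, est, by = c("bg_geoid", "date"))
  keep <- c("station_id", "bg_geoid", "date", "observed", "estimated",
            intersect("urban_rural", names(pairs)))
  pairs <- pairs[, keep, with = FALSE]
  data.table::setkey(pairs, station_id, date)
  data.table::setattr(pairs, "n_excluded_stations", n_excluded)
  pairs[]
}

#' Mean absolute deviation of estimates from observations
#'
#' @param pairs data.table with columns `observed`, `estimated` (>= 1 row).
#' @return mean of `|estimated - observed|`.
#' @export
mad_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no pairs: MAD undefined")
  mean(abs(pairs$estimated - pairs$observed))
}

#' Pooled Pearson correlation of estimates vs observations
#'
#' All pairs are pooled into a single correlation (rather than averaging
#' per-station correlations). Returns `NA` when fewer than two pairs exist or
#' either column is constant, for which the sample correlation is undefined.
#'
#' @param pairs data.table with columns `observed`, `estimated`.
#' @return Pearson r in \[-1, 1\], or `NA_real_` when undefined.
#' @export
pearson_pairs <- function(pairs) {
  if (nrow(pairs) < 2L) return(NA_real_)
  if (stats::sd(pairs$observed) == 0 || stats::sd(pairs$estimated) == 0) {
    return(NA_real_)
  }
  stats::cor(pairs$observed, pairs$estimated)
}

#' Distribution of absolute deviations
#'
#' Order statistics of `|estimated - observed|`: minimum, 5th, 10th, 50th,
#' 90th and 95th percentiles, and maximum. Quantiles use linear interpolation
#' between order statistics (R's default type 7 rule), the single convention
#' applied everywhere in the package.
#'
#' @param pairs data.table with columns `observed`, `estimated` (>= 1 row).
#' @return named numeric vector `min, p5, p10, median, p90, p95, max`.
#' @export
absdev_distribution <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no pairs: distribution undefined")
  d <- abs(pairs$estimated - pairs$observed)
  q <- stats::quantile(d, probs = c(0.05, 0.10, 0.50, 0.90, 0.95),
                       names = FALSE, type = 7)
  c(min = min(d), p5 = q[1], p10 = q[2], median = q[3],
    p90 = q[4], p95 = q[5], max = max(d))
}

#' Meteorological season of an ISO date
#'
#' DJF = winter, MAM = spring, JJA = summer, SON = fall.
#'
#' @param dates character or Date vector.
#' @return character vector of season codes.
#' @export
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

.report_row <- function(pairs, stratum) {
  stats <- absdev_distribution(pairs)
  data.table::data.table(
    stratum = stratum,
    n_stations = length(unique(pairs$station_id)),
    n_obs = nrow(pairs),
    mad = mad_pairs(pairs),
    r = pearson_pairs(pairs),
    absdev_min = stats[["min"]], absdev_p5 = stats[["p5"]],
    absdev_p10 = stats[["p10"]], absdev_median = stats[["median"]],
    absdev_p90 = stats[["p90"]], absdev_p95 = stats[["p95"]],
    absdev_max = stats[["max"]])
}

#' Stratified comparison report
#'
#' One report row overall plus one per level of each requested stratum
#' (`year`, `season` from the pair date; `urban_rural` from the station
#' metadata). `n_stations` counts distinct stations contributing at least one
#' pair in the stratum; `n_obs` counts pairs.
#'
#' @param pairs output of [pair_observations()].
#' @param strata character subset of `c("year", "season", "urban_rural")`.
#' @return data.table, one row per stratum level plus `"overall"`.
#' @export
stratified_report <- function(pairs, strata = character()) {
  if (length(strata)) {
    strata <- match.arg(strata, c("year", "season", "urban_rural"),
                        several.ok = TRUE)
  }
  if (nrow(pairs) == 0L) stop("no pairs to report on")
  if ("urban_rural" %in% strata && !"urban_rural" %in% names(pairs)) {
    stop("urban_rural stratification requested but the column is absent")
  }
  out <- list(.report_row(pairs, "overall"))
  for (s in strata) {
    lab <- switch(s,
      year = format(as.Date(pairs$date), "%Y"),
      season = season_of(pairs$date),
      urban_rural = as.character(pairs$urban_rural))
    for (lv in sort(unique(lab))) {
      out[[length(out) + 1L]] <-
        .report_row(pairs[lab == lv], paste(s, lv, sep = ":"))
    }
  }
  data.table::rbindlist(out)[]
}
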