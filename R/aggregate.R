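# Bottom-up population-weighted aggregation of block-group estimates to
# tract, county, state and national exposure series.

.CGU_LEVELS <- c("bg", "tract", "county", "state", "national")
.CGU_PREFIX <- c(bg = 12L, tract = 11L, county = 5L, state = 2L)

#' Validate 12-digit block-group GEOIDs
#'
#' A block-group GEOID is exactly 12 digits: state (2) + county (3) +
#' tract (6) + block group (1). Leading zeros are significant, so GEOIDs are
#' always handled as character strings.
#'
#' @param geoids character vector.
#' @return invisibly `TRUE`; error listing offenders otherwise.
#' @export
check_geoid <- function(geoids) {
  bad <- !grepl("^[0-9]{12}$", geoids)
  if (any(bad)) {
    stop(sprintf("malformed block-group GEOID(s): %s%s",
                 paste(utils::head(geoids[bad], 5), collapse = ", "),
                 if (sum(bad) > 5) sprintf(" (+%d more)", sum(bad) - 5) else ""))
  }
  invisible(TRUE)
}

#' Build the census-unit hierarchy from block-group GEOIDs
#'
#' Each aggregation level is a fixed-width prefix of the 12-digit GEOID:
#' tract = first 11 digits, county = first 5, state = first 2; the national
#' unit is the single id `"US"`. Every block group therefore belongs to
#' exactly one unit per level.
#'
#' @param geoids character vector of 12-digit block-group GEOIDs.
#' @param levels which levels to build (subset of
#'   `c("bg","tract","county","state","national")`).
#' @return named list: per level, a named list mapping unit geoid to the
#'   member block-group GEOIDs.
#' @export
build_hierarchy <- function(geoids, levels = .CGU_LEVELS) {
  check_geoid(geoids)
  levels <- match.arg(levels, .CGU_LEVELS, several.ok = TRUE)
  geoids <- unique(geoids)
  out <- list()
  for (lv in levels) {
    key <- if (lv == "national") rep("US", length(geoids))
           else substr(geoids, 1L, .CGU_PREFIX[[lv]])
    out[[lv]] <- split(geoids, key)
  }
  out
}

#' Population-weighted exposure for one census unit
#'
#' With member weights a_i = pop_i / sum(pop): PE = sum(a_i * mu_i) per day,
#' and psi = sqrt(sum(a_i^2 * delta_i^2)) — the standard error of PE under
#' independence of the member block-group estimates. Zero-population members
#' carry weight zero and contribute nothing.
#'
#' @param est data.frame/data.table of member estimates with columns `geoid`,
#'   `date`, `mu`, `delta` (all members on the same calendar).
#' @param pops named numeric vector: population per member geoid.
#' @return data.table with columns `date`, `pe`, `psi`.
#' @export
aggregate_exposure <- function(est, pops) {
  est <- data.table::as.data.table(est)
  if (nrow(est) == 0L) stop("no member estimates supplied")
  if (any(is.na(pops)) || any(pops < 0)) stop("populations must be >= 0")
  total <- sum(pops)
  if (total <= 0) {
    stop("unit has zero total population: exposure undefined (no population, no exposure)")
  }
  miss <- setdiff(unique(est$geoid), names(pops))
  if (length(miss)) {
    stop(sprintf("no population record for BG(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  ndates <- length(unique(est$date))
  if (nrow(est) != ndates * length(unique(est$geoid))) {
    stop("calendar mismatch: members do not share the same set of dates")
  }
  a <- pops[est$geoid] / total
  mu <- delta <- NULL
  est[, list(pe = sum(a[.I] * mu), psi = sqrt(sum(a[.I]^2 * delta^2))),
      by = "date"]
}

#' Aggregate block-group series to all requested census levels
#'
#' Bottom-up (fine to coarse) population-weighted aggregation. Because the
#' weights are population shares, aggregating directly from block groups or
#' through intermediate levels yields identical results; this implementation
#' always weights member block groups directly.
#'
#' Zero-population block groups cannot carry exposure and are dropped from
#' the weighting (their count is reported when `verbose`). A unit whose total
#' population is zero is an error.
#'
#' @param bg_est data.table from [downscale_all()]: `geoid`, `date`, `mu`,
#'   `delta`.
#' @param bgs data.table with `geoid`, `population` (and optionally more).
#' @param levels levels to produce, subset of
#'   `c("bg","tract","county","state","national")`.
#' @param verbose print summary counts.
#' @return data.table with columns `geoid`, `level`, `date`, `pe`, `psi`,
#'   `population`.
#' @export
aggregate_all <- function(bg_est, bgs,
                          levels = c("tract", "county", "state", "national"),
                          verbose = FALSE) {
  levels <- match.arg(levels, .CGU_LEVELS, several.ok = TRUE)
  bg_est <- data.table::as.data.table(bg_est)
  bgs <- data.table::as.data.table(bgs)
  if (!all(c("geoid", "population") %in% names(bgs))) {
    stop("bgs must have columns geoid, population")
  }
  check_geoid(bgs$geoid)
  miss <- setdiff(unique(bg_est$geoid), bgs$geoid)
  if (length(miss)) {
    stop(sprintf("BG estimate without population record: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  pops <- stats::setNames(as.numeric(bgs$population), bgs$geoid)
  nzero <- sum(pops[unique(bg_est$geoid)] == 0)
  if (verbose && nzero > 0) {
    message(sprintf("aggregate: dropping %d zero-population BG(s) from weighting", nzero))
  }

  geoid <- mu <- delta <- pop <- NULL
  dt <- data.table::copy(bg_est)
  dt[, `:=`(pop = pops[geoid])]

  out <- vector("list", length(levels))
  names(out) <- levels
  for (lv in levels) {
    unit_vec <- if (lv == "national") rep("US", nrow(dt))
                else substr(dt$geoid, 1L, .CGU_PREFIX[[lv]])
    data.table::set(dt, j = "unit", value = unit_vec)
    tot <- dt[, list(tp = sum(pop[!duplicated(geoid)])), by = "unit"]
    if (any(tot$tp <= 0)) {
      stop(sprintf("unit(s) with zero total population at level %s: %s",
                   lv, paste(utils::head(tot$unit[tot$tp <= 0], 5), collapse = ", ")))
    }
    agg <- dt[, {
      tp <- sum(pop[!duplicated(geoid)])
      a <- pop / tp
      list(pe = sum(a * mu), psi = sqrt(sum(a^2 * delta^2)),
           population = tp)
    }, by = c("unit", "date")]
    data.table::setnames(agg, "unit", "geoid")
    agg[, `:=`(level = lv)]
    out[[lv]] <- agg
  }
  dt[, `:=`(unit = NULL)]
  res <- data.table::rbindlist(out)[, c("geoid", "level", "date", "pe", "psi",
                                        "population")]
  data.table::setkey(res, level, geoid, date)
  if (verbose) {
    message(sprintf("aggregate: %d unit-series across levels %s",
                    nrow(unique(res[, c("geoid", "level")])),
                    paste(levels, collapse = ",")))
  }
  res[]
}
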