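# Deterministic synthetic-data generator: gridded daily surfaces with
# standard errors, a nested block-group geography with populations, and
# noisy monitoring stations. Everything is a pure function of (config, seed).

.KM_PER_DEG_LAT <- 111.3195  # mean meridional degree on WGS84, adequate here

#' Simulation configuration
#'
#' Describes the synthetic world the generator produces. Defaults emulate the
#' kind of surface the pipeline consumes in production: a 36 km regular
#' lattice; a smooth spatial field (baseline plus Gaussian bumps) with a
#' seasonal sinusoid and AR(1) day-to-day noise; strictly positive standard
#' errors; block-group populations between 600 and 3,000 people centred near
#' the census optimum of 1,500; and at most two monitoring stations per block
#' group.
#'
#' @param n_rows,n_cols lattice dimensions (each >= 2).
#' @param spacing_km nominal grid spacing in km (36 or 12 in production).
#' @param origin_lat,origin_lon lattice origin (south-west centroid), degrees.
#' @param n_days days in the simulated calendar, starting `start_date`.
#' @param start_date first day, ISO-8601.
#' @param n_states,counties_per_state,tracts_per_county shape of the FIPS
#'   hierarchy the block groups are nested into.
#' @param n_bgs number of block groups.
#' @param pop_low,pop_high population bounds per block group.
#' @param baseline field baseline level (units of the pollutant).
#' @param seasonal_amp amplitude of the annual sinusoid.
#' @param n_bumps number of spatial Gaussian bumps.
#' @param bump_amp,bump_scale_km bump height and spatial scale.
#' @param ar1_phi AR(1) coefficient of the temporal noise, in \[0, 1).
#' @param innovation_sd standard deviation of AR(1) innovations.
#' @param se_scale,se_floor scale and strictly positive floor of the per-cell
#'   standard errors (drawn as `se_floor + se_scale * |N(0,1)|`).
#' @param station_frac_1,station_frac_2 fraction of block groups hosting one
#'   (respectively two) monitoring stations.
#' @param station_noise_sd standard deviation of station observation noise.
#' @param seed integer seed; the entire dataset is reproducible from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_rows = 10L, n_cols = 10L, spacing_km = 36,
                       origin_lat = 35, origin_lon = -95,
                       n_days = 30L, start_date = "2006-01-01",
                       n_states = 3L, counties_per_state = 2L,
                       tracts_per_county = 3L, n_bgs = 90L,
                       pop_low = 600L, pop_high = 3000L,
                       baseline = 13, seasonal_amp = 4,
                       n_bumps = 3L, bump_amp = 8, bump_scale_km = 80,
                       ar1_phi = 0.6, innovation_sd = 2,
                       se_scale = 1, se_floor = 0.2,
                       station_frac_1 = 0.25, station_frac_2 = 0.05,
                       station_noise_sd = 2, seed = 1L) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              spacing_km = spacing_km, origin_lat = origin_lat,
              origin_lon = origin_lon, n_days = as.integer(n_days),
              start_date = start_date, n_states = as.integer(n_states),
              counties_per_state = as.integer(counties_per_state),
              tracts_per_county = as.integer(tracts_per_county),
              n_bgs = as.integer(n_bgs), pop_low = as.integer(pop_low),
              pop_high = as.integer(pop_high), baseline = baseline,
              seasonal_amp = seasonal_amp, n_bumps = as.integer(n_bumps),
              bump_amp = bump_amp, bump_scale_km = bump_scale_km,
              ar1_phi = ar1_phi, innovation_sd = innovation_sd,
              se_scale = se_scale, se_floor = se_floor,
              station_frac_1 = station_frac_1,
              station_frac_2 = station_frac_2,
              station_noise_sd = station_noise_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_rows >= 2, n_cols >= 2, spacing_km > 0, n_days >= 1,
              n_states >= 1, counties_per_state >= 1, tracts_per_county >= 1,
              n_bgs >= 1, pop_low > 0, pop_low <= pop_high,
              ar1_phi >= 0, ar1_phi < 1, innovation_sd >= 0,
              se_floor > 0, se_scale >= 0,
              station_frac_1 >= 0, station_frac_2 >= 0,
              station_frac_1 + station_frac_2 <= 1,
              station_noise_sd >= 0)
  })
  check_geopoint(cfg$origin_lat, cfg$origin_lon, "origin")
  structure(cfg, class = "sim_config")
}

# deterministic per-component seeds split off the global one, so e.g. adding
# stations never perturbs the field; kept well below 2^31
.component_seed <- function(cfg, component) {
  offs <- c(grid = 101L, field = 211L, bgs = 307L, stations = 401L)
  (cfg$seed %% 1000000L) * 1000L + offs[[component]]
}

#' Regular lattice of grid-cell centroids
#'
#' `n_rows x n_cols` centroids spaced approximately `spacing_km` apart.
#' The km-to-degree conversion uses the meridional degree length for
#' latitude and the origin latitude's parallel for longitude — adequate at
#' the test-extent lattices this generator targets.
#'
#' @param cfg a [sim_config()].
#' @return data.table with columns `cell_id` (encodes row/column, e.g.
#'   `"r03c07"`), `lat`, `lon`.
#' @export
make_grid <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dlat <- cfg$spacing_km / .KM_PER_DEG_LAT
  dlon <- cfg$spacing_km / (.KM_PER_DEG_LAT * cos(cfg$origin_lat * pi / 180))
  g <- data.table::CJ(row = seq_len(cfg$n_rows), col = seq_len(cfg$n_cols))
  data.table::data.table(
    cell_id = sprintf("r%02dc%02d", g$row, g$col),
    lat = cfg$origin_lat + (g$row - 1L) * dlat,
    lon = cfg$origin_lon + (g$col - 1L) * dlon)
}

# smooth spatial component: baseline + sum of Gaussian bumps; the bump
# centres/heights are drawn once from the field stream
.make_bumps <- function(cfg) {
  if (cfg$n_bumps == 0L) {
    return(data.table::data.table(lat = numeric(), lon = numeric(),
                                  amp = numeric()))
  }
  dlat_ext <- (cfg$n_rows - 1L) * cfg$spacing_km / .KM_PER_DEG_LAT
  dlon_ext <- (cfg$n_cols - 1L) * cfg$spacing_km /
    (.KM_PER_DEG_LAT * cos(cfg$origin_lat * pi / 180))
  data.table::data.table(
    lat = cfg$origin_lat + stats::runif(cfg$n_bumps) * dlat_ext,
    lon = cfg$origin_lon + stats::runif(cfg$n_bumps) * dlon_ext,
    amp = cfg$bump_amp * stats::runif(cfg$n_bumps, 0.5, 1))
}

.spatial_component <- function(lat, lon, cfg, bumps) {
  v <- rep(cfg$baseline, length(lat))
  if (nrow(bumps)) {
    coslat <- cos(cfg$origin_lat * pi / 180)
    for (j in seq_len(nrow(bumps))) {
      dk2 <- ((lat - bumps$lat[j]) * .KM_PER_DEG_LAT)^2 +
             ((lon - bumps$lon[j]) * .KM_PER_DEG_LAT * coslat)^2
      v <- v + bumps$amp[j] * exp(-dk2 / (2 * cfg$bump_scale_km^2))
    }
  }
  v
}

.seasonal_component <- function(day_index, cfg) {
  cfg$seasonal_amp * sin(2 * pi * (day_index - 1L) / 365)
}

#' Simulate the gridded daily surface
#'
#' Per cell and day: `value = baseline + seasonal sinusoid + Gaussian spatial
#' bumps + AR(1) temporal noise`; `se` is drawn strictly positive as
#' `se_floor + se_scale * |N(0,1)|`. The returned truth field is the same
#' expression *without* the AR(1) noise, so station-recovery tests have a
#' clean analytic target; the truth function can be evaluated at any point
#' (in particular at block-group centroids).
#'
#' @param cells lattice from [make_grid()].
#' @param cfg a [sim_config()].
#' @return list with `grid` (long data.table: `cell_id, lat, lon, date,
#'   value, se`), `truth_fun` (`function(lat, lon, day_index)` returning the
#'   noise-free value) and `bumps` (the drawn bump table).
#' @export
simulate_field <- function(cells, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.component_seed(cfg, "field"))
  bumps <- .make_bumps(cfg)
  n_cells <- nrow(cells)
  dates <- as.character(as.Date(cfg$start_date) + 0:(cfg$n_days - 1L))

  spat <- .spatial_component(cells$lat, cells$lon, cfg, bumps)
  seas <- .seasonal_component(seq_len(cfg$n_days), cfg)

  # AR(1) per cell, stationary start
  noise <- matrix(0, n_cells, cfg$n_days)
  if (cfg$innovation_sd > 0) {
    sd0 <- cfg$innovation_sd / sqrt(1 - cfg$ar1_phi^2)
    noise[, 1] <- stats::rnorm(n_cells, 0, sd0)
    if (cfg$n_days > 1L) {
      for (t in 2:cfg$n_days) {
        noise[, t] <- cfg$ar1_phi * noise[, t - 1] +
          stats::rnorm(n_cells, 0, cfg$innovation_sd)
      }
    }
  }
  ses <- cfg$se_floor + cfg$se_scale * abs(stats::rnorm(n_cells * cfg$n_days))

  grid <- data.table::data.table(
    cell_id = rep(cells$cell_id, times = cfg$n_days),
    lat = rep(cells$lat, times = cfg$n_days),
    lon = rep(cells$lon, times = cfg$n_days),
    date = rep(dates, each = n_cells),
    value = rep(spat, times = cfg$n_days) +
      rep(seas, each = n_cells) + as.vector(noise),
    se = ses)
  data.table::setkey(grid, cell_id, date)

  truth_fun <- function(lat, lon, day_index) {
    .spatial_component(lat, lon, cfg, bumps) +
      .seasonal_component(day_index, cfg)
  }
  list(grid = grid[], truth_fun = truth_fun, bumps = bumps)
}

#' Generate block groups with populations and a nested FIPS hierarchy
#'
#' Centroids are uniform over the lattice's bounding box. GEOIDs are built to
#' respect the configured state/county/tract nesting (synthetic state codes
#' start at "01"). Populations are drawn between `pop_low` and `pop_high`
#' from a scaled Beta(3, 5), whose mean sits at 600 + 0.375 * 2400 = 1500 for
#' the default bounds — the census optimum block-group size.
#'
#' @param cfg a [sim_config()].
#' @return data.table with columns `geoid`, `lat`, `lon`, `population`.
#' @export
make_block_groups <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_tracts <- cfg$n_states * cfg$counties_per_state * cfg$tracts_per_county
  if (cfg$n_bgs < n_tracts) {
    stop(sprintf(
      "n_bgs = %d cannot fill %d tracts (need at least one BG per tract)",
      cfg$n_bgs, n_tracts))
  }
  if (cfg$n_bgs > n_tracts * 9L) {
    stop("n_bgs exceeds capacity: at most 9 BGs per tract (single-digit BG code)")
  }
  set.seed(.component_seed(cfg, "bgs"))

  # round-robin BGs over tracts so every tract is populated
  tract_idx <- rep(seq_len(n_tracts), length.out = cfg$n_bgs)
  tract_idx <- sort(tract_idx)
  bg_within <- stats::ave(tract_idx, tract_idx, FUN = seq_along)
  st <- (tract_idx - 1L) %/% (cfg$counties_per_state * cfg$tracts_per_county)
  co <- ((tract_idx - 1L) %/% cfg$tracts_per_county) %% cfg$counties_per_state
  tr <- (tract_idx - 1L) %% cfg$tracts_per_county
  geoid <- sprintf("%02d%03d%06d%1d", st + 1L, co + 1L, tr + 1L, bg_within)

  dlat_ext <- (cfg$n_rows - 1L) * cfg$spacing_km / .KM_PER_DEG_LAT
  dlon_ext <- (cfg$n_cols - 1L) * cfg$spacing_km /
    (.KM_PER_DEG_LAT * cos(cfg$origin_lat * pi / 180))
  pop <- cfg$pop_low +
    round(stats::rbeta(cfg$n_bgs, 3, 5) * (cfg$pop_high - cfg$pop_low))
  data.table::data.table(
    geoid = geoid,
    lat = cfg$origin_lat + stats::runif(cfg$n_bgs) * dlat_ext,
    lon = cfg$origin_lon + stats::runif(cfg$n_bgs) * dlon_ext,
    population = as.integer(pop))
}

#' Generate monitoring stations observing the noise-free truth plus noise
#'
#' A configured fraction of block groups receive one station and a smaller
#' fraction two (block groups host at most two monitors). Each station
#' observes the block group's truth value (the smooth field evaluated at the
#' BG centroid) plus iid `N(0, station_noise_sd)` noise, every day of the
#' calendar.
#'
#' @param bgs block-group table from [make_block_groups()].
#' @param truth_fun truth function from [simulate_field()].
#' @param cfg a [sim_config()].
#' @return data.table with columns `station_id`, `bg_geoid`, `date`,
#'   `observed`, `urban_rural`.
#' @export
make_stations <- function(bgs, truth_fun, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.component_seed(cfg, "stations"))
  n <- nrow(bgs)
  n1 <- round(cfg$station_frac_1 * n)
  n2 <- round(cfg$station_frac_2 * n)
  pick <- sample.int(n, min(n, n1 + n2))
  counts <- integer(n)
  counts[pick] <- rep(c(1L, 2L), c(length(pick) - min(n2, length(pick)),
                                   min(n2, length(pick))))
  host <- rep(seq_len(n), counts)
  if (length(host) == 0L) {
    return(data.table::data.table(
      station_id = character(), bg_geoid = character(), date = character(),
      observed = numeric(), urban_rural = character()))
  }
  station_id <- sprintf("S%04d", seq_along(host))
  urban <- sample(c("urban", "rural"), length(host), replace = TRUE,
                  prob = c(0.7, 0.3))
  dates <- as.character(as.Date(cfg$start_date) + 0:(cfg$n_days - 1L))

  base <- data.table::data.table(
    station_id = rep(station_id, each = cfg$n_days),
    bg_geoid = rep(bgs$geoid[host], each = cfg$n_days),
    lat = rep(bgs$lat[host], each = cfg$n_days),
    lon = rep(bgs$lon[host], each = cfg$n_days),
    urban_rural = rep(urban, each = cfg$n_days),
    date = rep(dates, times = length(host)),
    day_index = rep(seq_len(cfg$n_days), times = length(host)))
  base[, `:=`(observed = truth_fun(lat, lon, day_index) +
                stats::rnorm(.N, 0, cfg$station_noise_sd))]
  base[, c("station_id", "bg_geoid", "date", "observed", "urban_rural")]
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [make_grid()], [simulate_field()],
#' [make_block_groups()] and [make_stations()] from one config. Also returns
#' the block-group truth table used by recovery tests.
#'
#' @param cfg a [sim_config()].
#' @return list with `grid`, `bgs`, `stations`, `bg_truth` (data.table
#'   `geoid, date, truth`), `truth_fun`, `cells`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  cells <- make_grid(cfg)
  field <- simulate_field(cells, cfg)
  bgs <- make_block_groups(cfg)
  stations <- make_stations(bgs, field$truth_fun, cfg)
  dates <- as.character(as.Date(cfg$start_date) + 0:(cfg$n_days - 1L))
  bg_truth <- data.table::data.table(
    geoid = rep(bgs$geoid, each = cfg$n_days),
    date = rep(dates, times = nrow(bgs)),
    truth = as.vector(outer(seq_len(cfg$n_days), seq_len(nrow(bgs)),
      function(d, b) field$truth_fun(bgs$lat[b], bgs$lon[b], d))))
  list(grid = field$grid, bgs = bgs, stations = stations,
       bg_truth = bg_truth, truth_fun = field$truth_fun,
       cells = cells, cfg = cfg)
}
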