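test_that("build_hierarchy slices GEOID prefixes into nested units", {
  h <- build_hierarchy("130890212001")
  expect_identical(names(h$tract), "13089021200")
  expect_identical(names(h$county), "13089")
  expect_identical(names(h$state), "13")
  expect_identical(names(h$national), "US")
  # two BGs differing only in the last digit share a tract
  h2 <- build_hierarchy(c("130890212001", "130890212002"))
  expect_length(h2$tract, 1)
  expect_setequal(h2$tract[[1]], c("130890212001", "130890212002"))
  expect_error(build_hierarchy("13089021200"), "malformed")
  expect_error(build_hierarchy("13089021200a"), "malformed")
})

test_that("every BG lands in exactly one unit per level", {
  cfg <- small_world()
  bgs <- make_block_groups(cfg)
  h <- build_hierarchy(bgs$geoid)
  for (lv in names(h)) {
    members <- unlist(h[[lv]], use.names = FALSE)
    expect_setequal(members, bgs$geoid)
    expect_identical(anyDuplicated(members), 0L)
  }
})

test_that("aggregate_exposure matches hand-computed weighted means", {
  dates <- iso_dates(3)
  one <- data.table::data.table(geoid = "130890212001", date = dates,
                                mu = c(10, 11, 12), delta = c(1, 1.5, 2))
  # single member: pe = mu, psi = delta
  r1 <- aggregate_exposure(one, c("130890212001" = 1200))
  expect_equal(r1$pe, one$mu)
  expect_equal(r1$psi, one$delta)
  # equal populations: midpoint
  two <- rbind(one,
               data.table::data.table(geoid = "130890212002", date = dates,
                                      mu = c(20, 21, 22), delta = c(2, 2, 2)))
  r2 <- aggregate_exposure(two, c("130890212001" = 500, "130890212002" = 500))
  expect_equal(r2$pe, c(15, 16, 17))
  # populations (3000, 1000), mu (10, 20), delta (1, 2):
  # pe = 0.75*10 + 0.25*20 = 12.5; psi = sqrt(0.5625*1 + 0.0625*4)
  r3 <- aggregate_exposure(two[two$date == dates[1]],
                           c("130890212001" = 3000, "130890212002" = 1000))
  expect_equal(r3$pe, 12.5)
  expect_equal(r3$psi, sqrt(0.8125))
  expect_error(aggregate_exposure(two, c("130890212001" = 0,
                                         "130890212002" = 0)),
               "zero total population")
  expect_error(
    aggregate_exposure(
      rbind(one, data.table::data.table(geoid = "130890212002",
                                        date = dates[1], mu = 20, delta = 2)),
      c("130890212001" = 10, "130890212002" = 10)),
    "calendar")
})

test_that("zero-population members contribute nothing", {
  dates <- iso_dates(2)
  two <- data.table::data.table(
    geoid = rep(c("130890212001", "130890212002"), each = 2),
    date = rep(dates, 2), mu = c(10, 10, 99, 99), delta = c(1, 1, 9, 9))
  r <- aggregate_exposure(two, c("130890212001" = 800, "130890212002" = 0))
  expect_equal(r$pe, c(10, 10))
  expect_equal(r$psi, c(1, 1))
})

test_that("a constant field aggregates to the constant at every level", {
  cfg <- small_world()
  bgs <- make_block_groups(cfg)
  dates <- iso_dates(4)
  est <- data.table::data.table(
    geoid = rep(bgs$geoid, each = length(dates)),
    date = rep(dates, nrow(bgs)), mu = 21.5, delta = 0.5)
  exp <- aggregate_all(est, bgs)
  expect_true(all(abs(exp$pe - 21.5) < 21.5 * 1e-9))
  expect_true(all(exp$psi <= 0.5 + 1e-12))
})

test_that("nested aggregation is consistent: direct vs chained paths", {
  # 3-state, 500-BG fixture; direct BG->national vs BG->state->national
  cfg <- gridshed::sim_config(n_rows = 8L, n_cols = 8L, n_days = 6L,
                              n_states = 3L, counties_per_state = 4L,
                              tracts_per_county = 7L, n_bgs = 500L, seed = 31L)
  ds <- simulate_dataset(cfg)
  est <- downscale_all(ds$grid, ds$bgs)
  exp <- aggregate_all(est, ds$bgs, levels = c("county", "state", "national"))

  # independent chained path: state PE from county PEs weighted by county pop
  cty <- exp[exp$level == "county"]
  st_direct <- exp[exp$level == "state"]
  cty$state <- substr(cty$geoid, 1, 2)
  chained <- cty[, list(pe = sum(population * pe) / sum(population),
                        psi = sqrt(sum((population / sum(population))^2 * psi^2))),
                 by = c("state", "date")]
  m <- merge(chained, st_direct, by.x = c("state", "date"),
             by.y = c("geoid", "date"))
  expect_equal(m$pe.x, m$pe.y, tolerance = 1e-9)
  expect_equal(m$psi.x, m$psi.y, tolerance = 1e-9)

  # and BG -> national directly, by hand
  pop <- stats::setNames(as.numeric(ds$bgs$population), ds$bgs$geoid)
  nat_hand <- est[, list(pe = sum(pop[geoid] * mu) / sum(pop[geoid])),
                  by = "date"]
  nat <- exp[exp$level == "national"]
  expect_equal(nat$pe[order(nat$date)], nat_hand$pe[order(nat_hand$date)],
               tolerance = 1e-9)
})

test_that("unit population equals the sum of member BG populations", {
  cfg <- small_world()
  ds <- simulate_dataset(cfg)
  est <- downscale_all(ds$grid, ds$bgs)
  exp <- aggregate_all(est, ds$bgs)
  nat <- unique(exp[exp$level == "national", "population"])
  expect_equal(nat$population, sum(ds$bgs$population))
  st <- unique(exp[exp$level == "state", c("geoid", "population")])
  byhand <- tapply(ds$bgs$population, substr(ds$bgs$geoid, 1, 2), sum)
  expect_equal(st$population[order(st$geoid)],
               as.numeric(byhand[order(names(byhand))]))
})

test_that("removing a zero-population BG changes nothing", {
  cfg <- small_world()
  ds <- simulate_dataset(cfg)
  bgs <- data.table::copy(ds$bgs)
  bgs$population[3] <- 0L
  est <- downscale_all(ds$grid, bgs)
  full <- aggregate_all(est, bgs, levels = c("state", "national"))
  trimmed <- aggregate_all(est[est$geoid != bgs$geoid[3]],
                           bgs[-3, ], levels = c("state", "national"))
  m <- merge(full, trimmed, by = c("geoid", "level", "date"))
  expect_equal(m$pe.x, m$pe.y, tolerance = 1e-12)
  expect_equal(m$psi.x, m$psi.y, tolerance = 1e-12)
})

test_that("estimates without population records are rejected", {
  est <- data.table::data.table(geoid = "999999999999",
                                date = "2006-01-01", mu = 1, delta = 0.1)
  bgs <- data.table::data.table(geoid = "130890212001", population = 100L)
  expect_error(aggregate_all(est, bgs), "without population")
})
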