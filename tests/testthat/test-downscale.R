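test_that("find_nearest_grids recovers the enclosing four lattice cells", {
  # 4x4 lattice; a point interior to the cell square bounded by rows 2-3,
  # cols 1-2 must pick exactly those four centroids (the classic geometry of
  # a BG sitting inside a grid cell)
  cells <- lattice_cells(4, 4)
  bg_lat <- cells$lat[1] + 0.40   # between row 2 (0.3) and row 3 (0.6)
  bg_lon <- cells$lon[1] + 0.20   # between col 1 (0.0) and col 2 (0.3)
  nb <- find_nearest_grids(bg_lat, bg_lon, cells, k = 4)
  expect_setequal(nb$cell_id, c("g0201", "g0202", "g0301", "g0302"))
  expect_true(all(diff(nb$distance_km) >= 0))
})

test_that("a BG coincident with a grid centroid is matched at distance zero", {
  cells <- lattice_cells(3, 3)
  nb <- find_nearest_grids(cells$lat[5], cells$lon[5], cells, k = 4)
  expect_identical(nb$cell_id[1], cells$cell_id[5])
  expect_identical(nb$distance_km[1], 0)
})

test_that("equidistant ties resolve to lexicographically smallest cell ids", {
  # exact ties on the ellipsoid: east-west mirror images about the target's
  # meridian are truly equidistant; b/a tie nearest, d/c tie behind them
  cells <- data.table::data.table(
    cell_id = c("e", "d", "c", "b", "a"),
    lat = c(42.0, 40.0, 40.0, 40.3, 40.3),
    lon = c(-100.0, -100.8, -99.2, -100.2, -99.8))
  nb <- find_nearest_grids(40, -100, cells, k = 4)
  expect_identical(nb$cell_id, c("a", "b", "c", "d"))
  expect_equal(nb$distance_km[1], nb$distance_km[2], tolerance = 1e-12)
  expect_equal(nb$distance_km[3], nb$distance_km[4], tolerance = 1e-12)
})

test_that("index and brute-force neighbour search agree exactly", {
  set.seed(21)
  for (rep in 1:100) {
    cells <- lattice_cells(10, 10,
                           origin_lat = runif(1, 30, 45),
                           origin_lon = runif(1, -120, -80),
                           dlat = runif(1, 0.1, 0.5), dlon = runif(1, 0.1, 0.5))
    bg_lat <- min(cells$lat) + runif(1) * diff(range(cells$lat))
    bg_lon <- min(cells$lon) + runif(1) * diff(range(cells$lon))
    a <- find_nearest_grids(bg_lat, bg_lon, cells, method = "index")
    b <- find_nearest_grids(bg_lat, bg_lon, cells, method = "brute")
    expect_identical(a, b)
  }
})

test_that("fewer grid cells than k is a hard error naming the shortfall", {
  cells <- lattice_cells(2, 2)[1:3]
  expect_error(find_nearest_grids(35, -95, cells, k = 4), "3 cells.*k = 4")
})

test_that("compute_weights implements inverse-squared-distance weighting", {
  expect_equal(compute_weights(c(10, 10, 10, 10)), rep(0.25, 4))
  expect_equal(compute_weights(c(1, 2, 2, 2)), c(4, 1, 1, 1) / 7)
  expect_equal(compute_weights(c(0, 5, 7, 9)), c(1, 0, 0, 0))
  expect_equal(compute_weights(c(0, 0, 7, 9)), c(0.5, 0.5, 0, 0))
  expect_error(compute_weights(c(-1, 2, 3, 4)), "negative")
  expect_error(compute_weights(c(0, 0, 0, 0)), "degenerate")
})

test_that("weights are scale-invariant and sum to one", {
  set.seed(22)
  for (i in 1:50) {
    d <- runif(4, 0.1, 100)
    w <- compute_weights(d)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(w, compute_weights(d * runif(1, 0.01, 1000)),
                 tolerance = 1e-12)
  }
})

test_that("estimate_bg_day is the weighted convex combination", {
  expect_equal(estimate_bg_day(rep(0.25, 4), c(10, 20, 30, 40)), 25)
  expect_equal(estimate_bg_day(c(0.1, 0.2, 0.3, 0.4), rep(7, 4)), 7)
  expect_equal(estimate_bg_day(c(1, 0, 0, 0), c(13, 99, 99, 99)), 13)
  expect_error(estimate_bg_day(rep(0.25, 4), c(1, 2, NA, 4)), "missing")
  expect_error(estimate_bg_day(c(0.5, 0.5, 0.5, 0.5), 1:4), "sum to 1")
})

test_that("estimate_bg_day_se propagates variance and is bounded", {
  expect_equal(estimate_bg_day_se(rep(0.25, 4), c(2, 2, 2, 2)), 1)
  expect_equal(estimate_bg_day_se(c(1, 0, 0, 0), c(3, 9, 9, 9)), 3)
  expect_equal(estimate_bg_day_se(rep(0.25, 4), rep(0, 4)), 0)
  expect_error(estimate_bg_day_se(rep(0.25, 4), c(-1, 1, 1, 1)), "non-negative")
  # delta <= max sigma, and monotone in each sigma
  set.seed(23)
  for (i in 1:50) {
    w <- compute_weights(runif(4, 0.1, 10))
    s <- runif(4, 0, 5)
    d0 <- estimate_bg_day_se(w, s)
    expect_lte(d0, max(s))
    s2 <- s; j <- sample(4, 1); s2[j] <- s2[j] + runif(1, 0, 3)
    expect_gte(estimate_bg_day_se(w, s2), d0)
  }
})

test_that("downscale_all propagates a constant field exactly", {
  cells <- lattice_cells(4, 4)
  grid <- constant_grid(cells, iso_dates(5), value = 17.5, se = 2)
  bgs <- data.table::data.table(
    geoid = sprintf("%012d", 1:10),
    lat = runif(10, min(cells$lat), max(cells$lat)),
    lon = runif(10, min(cells$lon), max(cells$lon)))
  est <- downscale_all(grid, bgs)
  expect_equal(nrow(est), 50)
  expect_true(all(abs(est$mu - 17.5) < 17.5 * 1e-9))
  expect_true(all(est$delta <= 2 + 1e-12))
})

test_that("a BG coincident with a cell reproduces that cell's series", {
  cells <- lattice_cells(3, 3)
  dates <- iso_dates(6)
  grid <- constant_grid(cells, dates)
  set.seed(24)
  grid$value <- runif(nrow(grid), 5, 50)
  grid$se <- runif(nrow(grid), 0.1, 3)
  bg <- data.table::data.table(geoid = "130890212001",
                               lat = cells$lat[4], lon = cells$lon[4])
  est <- downscale_all(grid, bg)
  ref <- grid[grid$cell_id == cells$cell_id[4], ]
  expect_equal(est$mu, ref$value[order(ref$date)])
  expect_equal(est$delta, ref$se[order(ref$date)])
})

test_that("downscale_all matches the brute-force all-pairs oracle", {
  set.seed(25)
  cells <- lattice_cells(10, 10)
  dates <- iso_dates(30)
  grid <- constant_grid(cells, dates)
  grid$value <- runif(nrow(grid), 0, 60)
  grid$se <- runif(nrow(grid), 0.1, 4)
  bgs <- data.table::data.table(
    geoid = sprintf("%012d", 1:50),
    lat = runif(50, min(cells$lat), max(cells$lat)),
    lon = runif(50, min(cells$lon), max(cells$lon)))
  est <- downscale_all(grid, bgs)

  g <- data.table::as.data.table(grid)
  for (b in sample(nrow(bgs), 10)) {          # spot-check 10 BGs in full
    nb <- brute_knn(bgs$lat[b], bgs$lon[b], cells)
    w <- compute_weights(nb$distance_km)
    sub <- g[g$cell_id %in% nb$cell_id]
    sub <- sub[order(match(sub$cell_id, nb$cell_id))]
    for (d in dates[c(1, 15, 30)]) {
      sd_ <- sub[sub$date == d]
      mu_oracle <- sum(w * sd_$value[match(nb$cell_id, sd_$cell_id)])
      row <- est[est$geoid == bgs$geoid[b] & est$date == d]
      expect_equal(row$mu, mu_oracle, tolerance = 1e-12)
    }
  }
  # convexity for every BG-day: mu within neighbour range
  for (b in seq_len(nrow(bgs))) {
    nb <- brute_knn(bgs$lat[b], bgs$lon[b], cells)
    sub <- g[g$cell_id %in% nb$cell_id,
             list(lo = min(value), hi = max(value)), by = "date"]
    m <- merge(est[est$geoid == bgs$geoid[b]], sub, by = "date")
    expect_true(all(m$mu >= m$lo - 1e-9 & m$mu <= m$hi + 1e-9))
  }
})

test_that("incomplete grid calendars are rejected, not imputed", {
  cells <- lattice_cells(3, 3)
  grid <- constant_grid(cells, iso_dates(4))
  grid <- grid[-5, ]  # drop one cell-day
  bg <- data.table::data.table(geoid = "130890212001", lat = 35.1, lon = -94.9)
  expect_error(downscale_all(grid, bg), "incomplete")
})
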