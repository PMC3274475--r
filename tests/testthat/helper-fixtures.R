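# Shared fixtures: tiny lattices and constant-field grids built in code.

# regular lattice of cells in degree space (planar spacing is fine for
# neighbour-geometry tests; geodesy has its own oracle fixture)
lattice_cells <- function(n_rows, n_cols, origin_lat = 35, origin_lon = -95,
                          dlat = 0.3, dlon = 0.3) {
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  data.table::data.table(
    cell_id = sprintf("g%02d%02d", g$row, g$col),
    lat = origin_lat + (g$row - 1) * dlat,
    lon = origin_lon + (g$col - 1) * dlon)
}

# long grid table with a constant field P = value, sigma = se
constant_grid <- function(cells, dates, value = 10, se = 1) {
  data.table::data.table(
    cell_id = rep(cells$cell_id, times = length(dates)),
    lat = rep(cells$lat, times = length(dates)),
    lon = rep(cells$lon, times = length(dates)),
    date = rep(dates, each = nrow(cells)),
    value = value, se = se)
}

iso_dates <- function(n, start = "2006-01-01") {
  as.character(as.Date(start) + seq_len(n) - 1)
}

# brute-force k-nearest oracle: all-pairs geodesic distances, plain order()
brute_knn <- function(bg_lat, bg_lon, cells, k = 4) {
  d <- gridshed::vincenty_distance(rep(bg_lat, nrow(cells)),
                                   rep(bg_lon, nrow(cells)),
                                   cells$lat, cells$lon)
  ord <- order(d, cells$cell_id)[seq_len(k)]
  data.table::data.table(cell_id = cells$cell_id[ord], distance_km = d[ord])
}

# small synthetic world reused by aggregate/summary tests
small_world <- function(seed = 7L, n_days = 10L) {
  gridshed::sim_config(n_rows = 6L, n_cols = 6L, n_days = n_days,
                       n_states = 3L, counties_per_state = 2L,
                       tracts_per_county = 2L, n_bgs = 60L, seed = seed)
}
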