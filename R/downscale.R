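# Block-group concentration estimation: nearest-grid search, inverse-squared
# distance weights, daily estimate and standard-error propagation.

#' Find the k nearest grid centroids to a block-group centroid
#'
#' Exact k-nearest-neighbour search by geodesic (Vincenty/WGS84) distance.
#' Ties in distance are broken by `cell_id` ascending so results are
#' deterministic across runs and platforms.
#'
#' Two search routes are available and must agree exactly: `"brute"` computes
#' the geodesic distance to every cell; `"index"` prefilters candidates with a
#' cheap equirectangular planar approximation (valid at the sub-degree
#' neighbour scales this pipeline works at), keeps every cell within a 10%
#' safety margin of the k-th approximate distance, and only then ranks the
#' survivors by exact geodesic distance. Both return the same neighbours; the
#' index route exists to keep national-scale runs affordable.
#'
#' @param bg_lat,bg_lon block-group centroid, decimal degrees.
#' @param cells data.frame/data.table with columns `cell_id`, `lat`, `lon`
#'   (one row per grid cell; `cell_id` unique).
#' @param k number of neighbours (default 4, the pipeline's convention).
#' @param method `"index"` (default) or `"brute"`.
#' @return data.table with columns `cell_id`, `distance_km`, sorted by
#'   `(distance_km, cell_id)` ascending, exactly `k` rows.
#' @export
find_nearest_grids <- function(bg_lat, bg_lon, cells, k = 4L,
                               method = c("index", "brute")) {
  method <- match.arg(method)
  check_geopoint(bg_lat, bg_lon, "BG centroid")
  stopifnot(length(bg_lat) == 1L)
  cells <- data.table::as.data.table(cells)
  need <- c("cell_id", "lat", "lon")
  if (!all(need %in% names(cells))) {
    stop("cells must have columns cell_id, lat, lon")
  }
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id in grid")
  k <- as.integer(k)
  if (nrow(cells) < k) {
    stop(sprintf("grid has %d cells but k = %d neighbours requested",
                 nrow(cells), k))
  }

  if (method == "index" && nrow(cells) > k) {
    # equirectangular approximation, exact enough for candidate screening:
    # neighbour distances are << 1 radian so the relative error is tiny,
    # and the 1.10 margin absorbs it with room to spare.
    coslat <- cos(bg_lat * pi / 180)
    approx <- sqrt((cells$lat - bg_lat)^2 + ((cells$lon - bg_lon) * coslat)^2)
    rk <- sort(approx, partial = k)[k]
    keep <- approx <= rk * 1.10 + 1e-9
    cand <- cells[keep]
  } else {
    cand <- cells
  }
  d <- vincenty_distance(rep(bg_lat, nrow(cand)), rep(bg_lon, nrow(cand)),
                         cand$lat, cand$lon)
  ord <- order(d, cand$cell_id)
  sel <- ord[seq_len(k)]
  data.table::data.table(cell_id = cand$cell_id[sel], distance_km = d[sel])
}

#' Inverse-squared-distance weights for a neighbour set
#'
#' Implements the weighting rule w_i = (1/d_i^2) / sum_j (1/d_j^2). The rule
#' is undefined at zero distance; we take its continuous limit: when one or
#' more neighbours coincide with the target point, the coincident neighbours
#' split all the weight equally and every other neighbour gets zero.
#'
#' @param distances numeric vector of non-negative distances (any unit;
#'   weights are scale-invariant). Length 4 in the pipeline but any length
#'   >= 1 is accepted.
#' @return weights summing to 1, each in \[0, 1\].
#' @export
compute_weights <- function(distances) {
  if (!is.numeric(distances) || length(distances) < 1L ||
      any(!is.finite(distances))) {
    stop("distances must be finite numerics")
  }
  if (any(distances < 0)) stop("negative distance supplied to compute_weights")
  zero <- distances == 0
  if (any(zero)) {
    if (all(zero) && length(distances) > 1L) {
      stop("all neighbour distances are zero for distinct cells: degenerate grid")
    }
    w <- as.numeric(zero) / sum(zero)
    return(w)
  }
  inv <- 1 / distances^2
  inv / sum(inv)
}

#' Single-day block-group concentration estimate
#'
#' mu = sum_i w_i * P_i: a convex combination of the neighbouring cells'
#' values, so mu always lies within their range.
#'
#' @param weights weights from [compute_weights()] (must sum to 1).
#' @param values neighbouring cells' concentrations, same length.
#' @return the weighted estimate.
#' @export
estimate_bg_day <- function(weights, values) {
  stopifnot(length(weights) == length(values))
  if (any(!is.finite(values))) stop("missing or non-finite neighbour value")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights do not sum to 1")
  sum(weights * values)
}

#' Single-day block-group standard error
#'
#' delta = sqrt(sum_i w_i^2 * sigma_i^2), the propagated standard error of the
#' weighted estimate under independence of the neighbouring cells. Always
#' <= max(sigma_i) since weights lie in \[0, 1\] and sum to 1.
#'
#' @param weights weights from [compute_weights()].
#' @param ses neighbouring cells' standard errors, each >= 0.
#' @return the propagated standard error (non-negative).
#' @export
estimate_bg_day_se <- function(weights, ses) {
  stopifnot(length(weights) == length(ses))
  if (any(!is.finite(ses)) || any(ses < 0)) {
    stop("standard errors must be finite and non-negative")
  }
  sqrt(sum(weights^2 * ses^2))
}

#' Downscale a gridded surface to block-group daily estimates
#'
#' For each block group: find its `k` nearest grid centroids (geometry is
#' time-invariant, so the neighbour set is computed once and reused across all
#' dates), form inverse-squared-distance weights, and produce a daily series
#' of estimates `mu` with propagated standard errors `delta`.
#'
#' The grid must be complete: every cell carries a value and a standard error
#' for every date in the grid's calendar. Gaps are an error, never silently
#' imputed — the upstream surfaces this pipeline is designed for are gap-free
#' by construction.
#'
#' @param grid data.frame/data.table with columns `cell_id`, `lat`, `lon`,
#'   `date` (ISO-8601 string or Date), `value`, `se`.
#' @param bgs data.frame/data.table with columns `geoid`, `lat`, `lon`
#'   (population column, if present, is ignored here).
#' @param k neighbours per block group (default 4).
#' @param method neighbour-search route, see [find_nearest_grids()].
#' @param verbose print a one-line summary of counts.
#' @return data.table with columns `geoid`, `date`, `mu`, `delta`, keyed by
#'   `(geoid, date)`.
#' @export
downscale_all <- function(grid, bgs, k = 4L, method = c("index", "brute"),
                          verbose = FALSE) {
  method <- match.arg(method)
  grid <- data.table::as.data.table(grid)
  bgs <- data.table::as.data.table(bgs)
  need_g <- c("cell_id", "lat", "lon", "date", "value", "se")
  if (!all(need_g %in% names(grid))) {
    stop("grid must have columns cell_id, lat, lon, date, value, se")
  }
  if (!all(c("geoid", "lat", "lon") %in% names(bgs))) {
    stop("bgs must have columns geoid, lat, lon")
  }
  if (any(!is.finite(grid$value)) || any(!is.finite(grid$se))) {
    stop("grid values and standard errors must be finite")
  }
  if (any(grid$se < 0)) stop("grid standard errors must be non-negative")

  cells <- unique(grid[, c("cell_id", "lat", "lon")])
  dates <- sort(unique(as.character(grid$date)))
  # completeness: every cell on every date, exactly once
  cnt <- grid[, .N, by = "cell_id"]
  if (any(cnt$N != length(dates)) || nrow(grid) != nrow(cells) * length(dates)) {
    bad <- cnt$cell_id[cnt$N != length(dates)]
    stop(sprintf("grid calendar incomplete: %d cell(s) missing dates (e.g. %s)",
                 length(bad), paste(utils::head(bad, 3), collapse = ", ")))
  }

  value <- se <- mu <- delta <- NULL  # NSE bindings
  series <- data.table::data.table(
    cell_id = as.character(grid$cell_id),
    date = as.character(grid$date),
    value = grid$value, se = grid$se)
  data.table::setkey(series, cell_id, date)

  out <- vector("list", nrow(bgs))
  for (b in seq_len(nrow(bgs))) {
    nb <- find_nearest_grids(bgs$lat[b], bgs$lon[b], cells, k = k,
                             method = method)
    w <- compute_weights(nb$distance_km)
    sub <- series[data.table::data.table(cell_id = nb$cell_id)]
    sub[, `:=`(w = w[match(cell_id, nb$cell_id)])]
    est <- sub[, list(mu = sum(w * value), delta = sqrt(sum(w^2 * se^2))),
               by = "date"]
    est[, `:=`(geoid = bgs$geoid[b])]
    out[[b]] <- est
  }
  res <- data.table::rbindlist(out)[, c("geoid", "date", "mu", "delta")]
  data.table::setkey(res, geoid, date)
  if (verbose) {
    message(sprintf("downscale: %d BGs x %d days from %d grid cells",
                    nrow(bgs), length(dates), nrow(cells)))
  }
  res[]
}
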