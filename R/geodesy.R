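# Geodetic distances on the WGS84 ellipsoid (Vincenty inverse method).

#' WGS84 ellipsoid constants
#'
#' Semi-major axis `a` (metres), semi-minor axis `b` (metres) and flattening
#' `f`. All geodesic distances in the package are computed on this ellipsoid;
#' the constant is exported so the choice is visible and auditable.
#'
#' @format Named numeric vector with elements `a`, `b`, `f`.
#' @export
WGS84 <- c(a = 6378137, b = 6356752.314245, f = 1 / 298.257223563)

#' Validate latitude/longitude coordinates
#'
#' Checks that coordinates are finite decimal degrees with latitude in
#' \[-90, 90\] and longitude in \[-180, 180\]. Used as a precondition by every
#' function that takes geographic points.
#'
#' @param lat,lon numeric vectors of equal length, decimal degrees.
#' @param what label used in error messages.
#' @return invisibly `TRUE`; aborts with an informative error otherwise.
#' @export
check_geopoint <- function(lat, lon, what = "point") {
  if (length(lat) != length(lon)) {
    stop(sprintf("%s: lat and lon lengths differ (%d vs %d)",
                 what, length(lat), length(lon)))
  }
  if (!is.numeric(lat) || !is.numeric(lon) ||
      any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop(sprintf("%s: coordinates must be finite numerics", what))
  }
  if (any(lat < -90 | lat > 90)) {
    stop(sprintf("%s: latitude outside [-90, 90]", what))
  }
  if (any(lon < -180 | lon > 180)) {
    stop(sprintf("%s: longitude outside [-180, 180]", what))
  }
  invisible(TRUE)
}

#' Vincenty inverse geodesic distance
#'
#' Distance between pairs of latitude/longitude points by the iterative
#' Vincenty inverse solution on the WGS84 ellipsoid. Inputs are decimal
#' degrees; the result is kilometres. Vectorised: the four arguments are
#' recycled to a common length and one distance is returned per pair.
#'
#' Iteration stops when the auxiliary longitude difference changes by less
#' than `tol` radians (default 1e-12) and is capped at `max_iter` rounds;
#' pairs still unconverged at the cap (possible only for nearly antipodal
#' points, far beyond the continental scales this package targets) raise an
#' error rather than looping or returning a silently wrong value.
#'
#' @param lat1,lon1 first point(s), decimal degrees.
#' @param lat2,lon2 second point(s), decimal degrees.
#' @param tol convergence tolerance on the longitude-difference update, radians.
#' @param max_iter iteration cap.
#' @return numeric vector of distances in kilometres.
#' @examples
#' vincenty_distance(0, 0, 0, 1)   # ~111.32 km along the equator
#' vincenty_distance(0, 0, 1, 0)   # ~110.57 km along a meridian
#' @export
vincenty_distance <- function(lat1, lon1, lat2, lon2,
                              tol = 1e-12, max_iter = 200L) {
  check_geopoint(lat1, lon1, "point a")
  check_geopoint(lat2, lon2, "point b")
  n <- max(length(lat1), length(lat2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)

  a <- WGS84[["a"]]; b <- WGS84[["b"]]; f <- WGS84[["f"]]
  rad <- pi / 180
  L <- (lon2 - lon1) * rad
  U1 <- atan((1 - f) * tan(lat1 * rad))
  U2 <- atan((1 - f) * tan(lat2 * rad))
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinU2 <- sin(U2); cosU2 <- cos(U2)

  lambda <- L
  out <- numeric(n)
  active <- rep(TRUE, n)          # pairs still iterating
  # coincident points: Vincenty's sinSigma is 0, handle up front
  same <- lat1 == lat2 & lon1 == lon2
  out[same] <- 0
  active[same] <- FALSE

  sigma <- sinSigma <- cosSigma <- cos2SigmaM <- cosSqAlpha <- numeric(n)
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    i <- active
    sinLambda <- sin(lambda[i]); cosLambda <- cos(lambda[i])
    ss <- sqrt((cosU2[i] * sinLambda)^2 +
               (cosU1[i] * sinU2[i] - sinU1[i] * cosU2[i] * cosLambda)^2)
    cs <- sinU1[i] * sinU2[i] + cosU1[i] * cosU2[i] * cosLambda
    sg <- atan2(ss, cs)
    sinAlpha <- ifelse(ss == 0, 0, cosU1[i] * cosU2[i] * sinLambda / ss)
    csa <- 1 - sinAlpha^2
    c2sm <- ifelse(csa == 0, 0, cs - 2 * sinU1[i] * sinU2[i] / csa)
    C <- f / 16 * csa * (4 + f * (4 - 3 * csa))
    lambdaNew <- L[i] + (1 - C) * f * sinAlpha *
      (sg + C * ss * (c2sm + C * cs * (-1 + 2 * c2sm^2)))

    sinSigma[i] <- ss; cosSigma[i] <- cs; sigma[i] <- sg
    cos2SigmaM[i] <- c2sm; cosSqAlpha[i] <- csa

    done <- abs(lambdaNew - lambda[i]) < tol
    lambda[i] <- lambdaNew
    idx <- which(i)
    active[idx[done]] <- FALSE
  }
  if (any(active)) {
    stop(sprintf(
      "vincenty_distance: %d point pair(s) failed to converge in %d iterations (nearly antipodal?)",
      sum(active), max_iter))
  }

  todo <- !same
  if (any(todo)) {
    uSq <- cosSqAlpha[todo] * (a^2 - b^2) / b^2
    A <- 1 + uSq / 16384 * (4096 + uSq * (-768 + uSq * (320 - 175 * uSq)))
    B <- uSq / 1024 * (256 + uSq * (-128 + uSq * (74 - 47 * uSq)))
    c2sm <- cos2SigmaM[todo]
    deltaSigma <- B * sinSigma[todo] *
      (c2sm + B / 4 * (cosSigma[todo] * (-1 + 2 * c2sm^2) -
        B / 6 * c2sm * (-3 + 4 * sinSigma[todo]^2) * (-3 + 4 * c2sm^2)))
    out[todo] <- b * A * (sigma[todo] - deltaSigma)
  }
  out / 1000
}
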