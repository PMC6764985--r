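# Spherical geodesy primitives shared by the simulator and the feature
# extraction. All distances in km on a sphere of radius EARTH_RADIUS_KM,
# all angles in radians unless noted.

#' Normalize longitudes to [-180, 180)
#'
#' @param lon Numeric vector of longitudes in decimal degrees.
#' @return Longitudes wrapped into `[-180, 180)`.
#' @export
wrap_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Wrap angles to (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped into `(-pi, pi]`.
#' @export
wrap_to_pi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorized over
#' coordinate pairs.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Non-negative distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)  # one degree of latitude, ~111.195 km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  .check_lonlat(lon1, lat1)
  .check_lonlat(lon2, lat2)
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dl <- .deg2rad(lon2 - lon1)
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial bearing (forward azimuth) between two points
#'
#' @inheritParams great_circle_km
#' @return Bearing in radians in `(-pi, pi]`, measured clockwise from north.
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dl <- .deg2rad(lon2 - lon1)
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  wrap_to_pi(atan2(y, x))
}

#' Destination point along a great circle
#'
#' Solves the direct geodesic problem on the sphere: the point reached from
#' `(lon, lat)` after travelling `distance_km` on initial bearing
#' `bearing_rad`.
#'
#' @param lon,lat Start coordinates, decimal degrees.
#' @param bearing_rad Initial bearing in radians, clockwise from north.
#' @param distance_km Distance travelled in km.
#' @return A list with components `lon` (wrapped to `[-180, 180)`) and `lat`.
#' @export
destination_point <- function(lon, lat, bearing_rad, distance_km) {
  .check_lonlat(lon, lat)
  d <- distance_km / EARTH_RADIUS_KM
  p1 <- .deg2rad(lat); l1 <- .deg2rad(lon)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(bearing_rad))
  l2 <- l1 + atan2(
    sin(bearing_rad) * sin(d) * cos(p1),
    cos(d) - sin(p1) * sin(p2)
  )
  list(lon = wrap_lon(.rad2deg(l2)), lat = .rad2deg(p2))
}

# Azimuthal equidistant projection about (lon0, lat0): x east, y north, km.
# Exact inverse via the direct geodesic problem. Used to keep the DCRW state
# equation linear on a locally planar chart.
.project_aeqd <- function(lon, lat, lon0, lat0) {
  d <- great_circle_km(lon0, lat0, lon, lat)
  az <- initial_bearing(lon0, lat0, lon, lat)
  az[d == 0] <- 0
  list(x = d * sin(az), y = d * cos(az))
}

.unproject_aeqd <- function(x, y, lon0, lat0) {
  d <- sqrt(x^2 + y^2)
  az <- atan2(x, y)
  out <- destination_point(rep(lon0, length(x)), rep(lat0, length(x)), az, d)
  out$lon[d == 0] <- lon0
  out$lat[d == 0] <- lat0
  out
}
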