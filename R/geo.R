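# Spherical geometry helpers. All distances in km on a sphere of radius
# 6371 km; angles in radians unless noted.

EARTH_RADIUS_KM <- 6371

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle distance between coordinate pairs
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorised over all
#' four arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS-84).
#' @return Distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Initial great-circle bearing from point 1 to point 2, radians in (-pi, pi].
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  atan2(y, x)
}

# Absolute angular difference wrapped to [0, pi].
wrap_angle_abs <- function(x) {
  x <- abs(((x + pi) %% (2 * pi)) - pi)
  x
}

#' Project lon/lat to a local planar system about an origin
#'
#' Equirectangular projection centred on `origin` (lon, lat in degrees):
#' x = R cos(lat0) dlon, y = R dlat, both in km. Adequate near the equator
#' at foraging-trip scales (distortion < 0.2% over a few hundred km).
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param origin Numeric length-2, `c(lon0, lat0)` in degrees.
#' @return A list with components `x` and `y` (km).
#' @export
project_local <- function(lon, lat, origin) {
  lat0 <- deg2rad(origin[2])
  list(x = EARTH_RADIUS_KM * cos(lat0) * deg2rad(lon - origin[1]),
       y = EARTH_RADIUS_KM * deg2rad(lat - origin[2]))
}

#' Inverse of [project_local()]
#' @param x,y Planar coordinates in km.
#' @param origin Numeric length-2, `c(lon0, lat0)` in degrees.
#' @return A list with components `lon` and `lat` (degrees).
#' @export
unproject_local <- function(x, y, origin) {
  lat0 <- deg2rad(origin[2])
  list(lon = origin[1] + rad2deg(x / (EARTH_RADIUS_KM * cos(lat0))),
       lat = origin[2] + rad2deg(y / EARTH_RADIUS_KM))
}
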