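# Solar position (NOAA/Spencer approximation) for daylight masking.
# Accuracy ~0.1-0.3 degrees of elevation, ample for a day/night flag.

# Fractional year in radians for POSIXct times (UTC).
.frac_year <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  2 * pi / 365 * (lt$yday + (lt$hour + lt$min / 60 + lt$sec / 3600 - 12) / 24)
}

#' Solar elevation angle
#'
#' Spencer-series solar declination and equation of time; elevation from the
#' hour angle at the given longitude. No atmospheric refraction.
#'
#' @param time POSIXct (UTC).
#' @param lon,lat Observer position, decimal degrees.
#' @return Elevation above the horizon in degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  g <- .frac_year(time)
  # equation of time (minutes) and declination (radians), Spencer (1971)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lt <- as.POSIXlt(time, tz = "UTC")
  minutes <- lt$hour * 60 + lt$min + lt$sec / 60
  tst <- (minutes + eqtime + 4 * lon) %% 1440           # true solar time, min
  ha <- deg2rad(tst / 4 - 180)                          # hour angle
  phi <- deg2rad(lat)
  sin_el <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  rad2deg(asin(pmax(-1, pmin(1, sin_el))))
}

#' Daylight flag for a vector of times at a location
#'
#' `method = "solar"` marks times with solar elevation > 0. The
#' `method = "fixed"` fallback marks 06:00-18:00 local time, where local time
#' is UTC shifted by `lon/15` hours.
#'
#' @param times POSIXct (UTC).
#' @param lon,lat Location, decimal degrees.
#' @param method `"solar"` (default) or `"fixed"`.
#' @return Logical vector, TRUE for daylight.
#' @export
daylight_mask <- function(times, lon, lat, method = c("solar", "fixed")) {
  method <- match.arg(method)
  if (method == "solar") {
    return(solar_elevation(times, lon, lat) > 0)
  }
  local_h <- (as.numeric(times) / 3600 + lon / 15) %% 24
  local_h >= 6 & local_h < 18
}
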