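# Regularisation of raw fix series, step geometry, and absence delimitation.

#' Interpolate a fix series onto a regular time grid
#'
#' Linear interpolation of longitude and latitude onto a grid of
#' `interval` minutes anchored at the first fix. Grid points falling inside
#' a gap longer than `max_gap` minutes are dropped rather than fabricated.
#' Linear interpolation in lon/lat is an adequate approximation at
#' foraging-trip scales far smaller than the Earth radius.
#'
#' @param fixes Data frame with `timestamp` (POSIXct), `lon`, `lat`
#'   (degrees), optionally `bird_id`.
#' @param interval Target interval in minutes (> 0).
#' @param max_gap Maximum gap (minutes) to interpolate across.
#' @return A data frame like `fixes` on the regular grid.
#' @export
interpolate_track <- function(fixes, interval = 5, max_gap = 30) {
  if (nrow(fixes) < 2) stop("need at least two fixes to interpolate")
  if (interval <= 0) stop("interval must be > 0")
  tt <- as.numeric(fixes$timestamp)
  if (is.unsorted(tt, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  step <- interval * 60
  grid <- seq(tt[1], tt[length(tt)], by = step)
  lon <- stats::approx(tt, fixes$lon, xout = grid)$y
  lat <- stats::approx(tt, fixes$lat, xout = grid)$y
  # drop grid points bridging a raw gap wider than max_gap
  idx <- findInterval(grid, tt)
  gap_ok <- c(diff(tt), 0)[idx] <= max_gap * 60 | grid %in% tt
  out <- data.frame(timestamp = as.POSIXct(grid[gap_ok], tz = "UTC",
                                           origin = "1970-01-01"),
                    lon = lon[gap_ok], lat = lat[gap_ok],
                    stringsAsFactors = FALSE)
  if (!is.null(fixes$bird_id)) out$bird_id <- fixes$bird_id[1]
  out
}

#' Step distances, speeds and turning angles along a track
#'
#' Distances are great-circle (haversine, R = 6371 km); speed is distance
#' over elapsed time; the turning angle at an interior point is the
#' absolute change in great-circle bearing between the incoming and
#' outgoing step, wrapped to `[0, pi]`. One row per step (n-1 rows for n
#' fixes); turning angle is `NA` for the first step.
#'
#' @param track Regularised fix data frame (`timestamp`, `lon`, `lat`).
#' @return A `StepSeries` data frame: `t_mid`, `lon`, `lat` (step end),
#'   `dist_km`, `dt_s`, `speed_ms`, `turn_rad`.
#' @export
compute_steps <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("need at least two fixes")
  tt <- as.numeric(track$timestamp)
  if (any(diff(tt) == 0)) stop("duplicate timestamps in track")
  i <- seq_len(n - 1)
  d <- haversine_km(track$lon[i], track$lat[i],
                    track$lon[i + 1], track$lat[i + 1])
  dt <- diff(tt)
  brg <- gc_bearing(track$lon[i], track$lat[i],
                    track$lon[i + 1], track$lat[i + 1])
  turn <- c(NA_real_, wrap_angle_abs(diff(brg)))
  data.frame(
    t_mid = as.POSIXct((tt[i] + tt[i + 1]) / 2, tz = "UTC",
                       origin = "1970-01-01"),
    lon = track$lon[i + 1], lat = track$lat[i + 1],
    dist_km = d, dt_s = dt, speed_ms = d * 1000 / dt,
    turn_rad = turn,
    stringsAsFactors = FALSE
  )
}

#' Delimit the first qualifying foraging absence
#'
#' Finds the first maximal run of fixes farther than `radius_km` from the
#' colony whose away time exceeds `min_duration_h` hours; shorter
#' excursions before it are skipped. The reported departure and return
#' are anchored at the colony fixes bracketing the away run when they
#' exist (the absence clock starts when the previous attendance ends),
#' falling back to the run ends at the edges of the record. The
#' colony-distance radius is a proxy for nest attendance records.
#'
#' @param fixes Fix data frame for one bird (`timestamp`, `lon`, `lat`).
#' @param colony `c(lon, lat)` degrees.
#' @param radius_km Colony radius (default 1 km).
#' @param min_duration_h Minimum qualifying duration (default 3 h).
#' @param min_attendance_h Inside-radius interludes shorter than this are
#'   bridged into the surrounding absence (a brief pass over the colony is
#'   not an incubation shift; absences may contain colony returns).
#' @return A list with `found` (logical); when found, `depart_time`,
#'   `return_time`, `duration_h` (between the reported bounds), and
#'   integer fix indices `start`, `end` spanning those bounds.
#' @export
detect_first_absence <- function(fixes, colony, radius_km = 1,
                                 min_duration_h = 3,
                                 min_attendance_h = 1) {
  d <- haversine_km(fixes$lon, fixes$lat, colony[1], colony[2])
  away <- d > radius_km
  if (!any(away)) return(list(found = FALSE))
  tt0 <- as.numeric(fixes$timestamp)
  r0 <- rle(away)
  e0 <- cumsum(r0$lengths); s0 <- e0 - r0$lengths + 1
  for (j in seq_along(r0$values)) {
    if (r0$values[j] || j == 1 || j == length(r0$values)) next
    if ((tt0[e0[j]] - tt0[s0[j]]) / 3600 < min_attendance_h)
      away[s0[j]:e0[j]] <- TRUE
  }
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tt <- as.numeric(fixes$timestamp)
  n <- length(tt)
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    dur <- (tt[ends[j]] - tt[starts[j]]) / 3600
    if (dur > min_duration_h) {
      i0 <- max(starts[j] - 1L, 1L)
      i1 <- min(ends[j] + 1L, n)
      return(list(found = TRUE,
                  depart_time = fixes$timestamp[i0],
                  return_time = fixes$timestamp[i1],
                  duration_h = (tt[i1] - tt[i0]) / 3600,
                  start = i0, end = i1))
    }
  }
  list(found = FALSE)
}

#' Step series for an absence, with daylight flags
#'
#' Convenience wrapper: subsets the fixes of a detected absence, computes
#' steps and flags each step's midpoint as daylight or night.
#'
#' @param fixes Full fix table for one bird.
#' @param absence Result of [detect_first_absence()] with `found = TRUE`.
#' @param colony `c(lon, lat)` used for the solar computation.
#' @param daylight_method Passed to [daylight_mask()].
#' @return A step data frame with an added logical `daylight` column and
#'   attributes `depart_time`, `return_time`.
#' @export
absence_steps <- function(fixes, absence, colony,
                          daylight_method = "solar") {
  if (!isTRUE(absence$found)) stop("absence was not found")
  sub <- fixes[absence$start:absence$end, , drop = FALSE]
  steps <- compute_steps(sub)
  steps$daylight <- daylight_mask(steps$t_mid, colony[1], colony[2],
                                  method = daylight_method)
  attr(steps, "depart_time") <- absence$depart_time
  attr(steps, "return_time") <- absence$return_time
  steps
}
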