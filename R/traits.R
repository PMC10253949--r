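# Per-absence foraging traits and structural covariates.

#' Departure mass from deployment mass and incubation loss
#'
#' Birds lose mass at a steady daily rate while incubating; departure mass
#' is deployment mass minus the accumulated loss.
#'
#' @param deploy_mass_g Mass at logger deployment (g).
#' @param days_since_deployment Days between deployment and departure.
#' @param daily_loss_g_per_day Incubation mass-loss rate (g/day).
#' @return Departure mass in grams.
#' @export
departure_mass <- function(deploy_mass_g, days_since_deployment,
                           daily_loss_g_per_day) {
  if (any(c(deploy_mass_g, days_since_deployment,
            daily_loss_g_per_day) < 0))
    stop("all inputs must be >= 0")
  m <- deploy_mass_g - days_since_deployment * daily_loss_g_per_day
  if (any(m <= 0)) stop("implausible departure mass <= 0")
  m
}

#' Wing loading
#'
#' Departure body weight (N) divided by wing area (m^2), with wing area
#' approximated from wing chord: `9.8 * mass / (0.04 + 0.95 * chord)^2`.
#' Mass in kg and chord in m (convention; the area term is then m^2).
#'
#' @param mass_kg Body mass, kg.
#' @param wing_chord_m Flattened stretched wing chord, m.
#' @return Wing loading in N/m^2.
#' @export
wing_loading <- function(mass_kg, wing_chord_m) {
  if (any(mass_kg <= 0)) stop("mass must be > 0")
  if (any(wing_chord_m < 0)) stop("wing chord must be >= 0")
  9.8 * mass_kg / (0.04 + 0.95 * wing_chord_m)^2
}

#' Compute the five foraging traits for one absence
#'
#' Absence duration, total distance and time searching are summed over
#' daylight steps only; mass gain is return minus departure mass; the mass
#' gain rate divides by the wall-clock (day + night) duration.
#'
#' @param steps Step data frame for the absence, with `dist_km`, `dt_s`,
#'   `daylight`, and a `state` column (factor/character; `"SEARCH"` counts
#'   as searching). Typically [absence_steps()] plus [classify_states()].
#' @param depart_mass_g,return_mass_g Masses (g); `return_mass_g` may be
#'   `NA`, in which case mass fields are `NA` and the record is flagged.
#' @param metadata Optional list/row with `bird_id`, `season`, `sex`,
#'   `age`, `logger` copied onto the record.
#' @return A one-row `TraitRecord` data frame.
#' @export
compute_traits <- function(steps, depart_mass_g, return_mass_g,
                           metadata = NULL) {
  if (is.null(steps$state)) stop("steps must carry a state column")
  if (is.null(steps$daylight)) stop("steps must carry a daylight flag")
  dt_h <- steps$dt_s / 3600
  total_h <- sum(dt_h)
  day <- steps$daylight
  rec <- data.frame(
    absence_duration_h = sum(dt_h[day]),
    total_duration_h = total_h,
    total_distance_km = sum(steps$dist_km[day]),
    time_searching_h = sum(dt_h[day & steps$state == "SEARCH"]),
    mass_gain_g = NA_real_,
    mass_gain_per_h = NA_real_,
    mass_missing = is.na(return_mass_g),
    all_night = !any(day)
  )
  if (!is.na(return_mass_g)) {
    rec$mass_gain_g <- return_mass_g - depart_mass_g
    rec$mass_gain_per_h <- rec$mass_gain_g / total_h
  }
  if (!is.null(metadata)) {
    for (f in c("bird_id", "season", "sex", "age", "logger"))
      if (!is.null(metadata[[f]])) rec[[f]] <- metadata[[f]]
  }
  rec
}

#' Transform a response trait for modelling
#'
#' Square root for the three effort traits (absence duration, total
#' distance, time searching), natural log for the mass gain rate (with
#' non-positive values excluded and counted), identity for mass gain.
#'
#' @param trait_name One of `absence_duration_h`, `total_distance_km`,
#'   `time_searching_h`, `mass_gain_per_h`, `mass_gain_g`.
#' @param values Numeric vector.
#' @return A list: `values` (transformed, excluded entries dropped),
#'   `keep` (logical row mask), `n_excluded`, and `inverse` (function
#'   mapping back to the original scale).
#' @export
transform_response <- function(trait_name, values) {
  sqrt_traits <- c("absence_duration_h", "total_distance_km",
                   "time_searching_h")
  if (trait_name %in% sqrt_traits) {
    keep <- !is.na(values)
    return(list(values = sqrt(values[keep]), keep = keep,
                n_excluded = 0L, inverse = function(y) y^2))
  }
  if (trait_name == "mass_gain_per_h") {
    keep <- !is.na(values) & values > 0
    n_exc <- sum(!is.na(values) & values <= 0)
    return(list(values = log(values[keep]), keep = keep,
                n_excluded = n_exc, inverse = exp))
  }
  if (trait_name == "mass_gain_g") {
    keep <- !is.na(values)
    return(list(values = values[keep], keep = keep,
                n_excluded = 0L, inverse = identity))
  }
  stop("unknown trait: ", trait_name)
}

#' Trait table for a whole simulated or observed dataset
#'
#' Runs absence detection, step computation, state classification and
#' trait extraction for every bird-season in a fix table, producing one
#' `TraitRecord` row per absence.
#'
#' @param fixes Fix table (`bird_id`, `timestamp`, `lon`, `lat`) holding
#'   one deployment per bird-season; a `season` column on `birds` links
#'   records.
#' @param birds Metadata table (`bird_id`, `season`, `sex`, `age`,
#'   `logger`, `deploy_mass_g`, `days_since_deployment`, `wing_chord_m`,
#'   `return_mass_g`).
#' @param delims_by_sex Named list of `delimiters` (`male`, `female`).
#' @param colony `c(lon, lat)`.
#' @param daily_loss_g_per_day Incubation mass-loss rate.
#' @param radius_km,min_duration_h Absence detection parameters.
#' @param daylight_method Passed to [daylight_mask()].
#' @return A data frame of trait records with `depart_time`, `depart_day`
#'   attributes needed downstream; birds with no qualifying absence are
#'   skipped with a count in attribute `n_no_absence`.
#' @export
build_trait_table <- function(fixes, birds, delims_by_sex, colony,
                              daily_loss_g_per_day = 20,
                              radius_km = 1, min_duration_h = 3,
                              daylight_method = "solar") {
  out <- list(); dropped <- 0L
  for (i in seq_len(nrow(birds))) {
    b <- birds[i, ]
    sel <- fixes$bird_id == b$bird_id
    if (!is.null(fixes$season) && !is.null(b$season)) {
      sel <- sel & fixes$season == b$season
    } else if (!is.null(b$deploy_date)) {
      # one deployment per bird-season: window around the deployment date
      t0 <- as.POSIXct(as.Date(b$deploy_date), tz = "UTC")
      sel <- sel & fixes$timestamp >= t0 &
        fixes$timestamp <= t0 + 30 * 86400
    }
    fx <- fixes[sel, , drop = FALSE]
    if (nrow(fx) < 2) { dropped <- dropped + 1L; next }
    abs_ <- detect_first_absence(fx, colony, radius_km, min_duration_h)
    if (!isTRUE(abs_$found)) { dropped <- dropped + 1L; next }
    st <- absence_steps(fx, abs_, colony, daylight_method)
    cls <- classify_states(st, delims_by_sex[[b$sex]])
    st$state <- cls$state
    dm <- departure_mass(b$deploy_mass_g, b$days_since_deployment,
                         daily_loss_g_per_day)
    rec <- compute_traits(st, dm, b$return_mass_g, metadata = b)
    rec$wing_loading <- wing_loading(dm / 1000, b$wing_chord_m)
    rec$depart_time <- abs_$depart_time
    out[[length(out) + 1L]] <- rec
  }
  res <- do.call(rbind, out)
  attr(res, "n_no_absence") <- dropped
  res
}
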