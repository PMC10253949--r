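# Configuration for the synthetic central-place-forager generator.

#' Movement state labels
#'
#' Four activity states defined by the speed/turn dichotomy: REST (low
#' speed, low turn), COMMUTE (high, low), RELOCATE (high, high), SEARCH
#' (low, high).
#' @export
STATE_LEVELS <- c("REST", "COMMUTE", "RELOCATE", "SEARCH")

#' Default per-state movement parameters
#'
#' Gaussian speeds truncated at zero (m/s) and wrapped-Cauchy turning-angle
#' concentration rho (0 = uniform turns, 1 = straight). The defaults place
#' the slow states (rest 0.3, search 3 m/s) and fast states (commute and
#' relocate 10 m/s) on opposite sides of published speed delimiters near
#' 6-7 m/s. Turn concentrations are 0.98 for the low-turn states (nearly
#' straight flight or quiescent drift) and 0.05 for the high-turn states
#' (near-uniform headings during area-restricted search): the wrapped
#' Cauchy is heavy-tailed, and this contrast bounds the analytic
#' misclassification mass of the turn dichotomy at about 7% at the
#' equal-density crossing.
#' @export
default_state_params <- function() {
  data.frame(
    state = STATE_LEVELS,
    speed_mean = c(0.3, 10, 10, 3),
    speed_sd   = c(0.2, 1.2, 1.5, 0.8),
    turn_rho   = c(0.98, 0.98, 0.05, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Default state transition matrix
#'
#' Row-stochastic 4x4 over (REST, COMMUTE, RELOCATE, SEARCH). Dwell times
#' are long enough (diagonal 0.80-0.90) that bouts span several fixes.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    0.90, 0.06, 0.01, 0.03,   # REST
    0.04, 0.80, 0.06, 0.10,   # COMMUTE
    0.02, 0.28, 0.50, 0.20,   # RELOCATE
    0.06, 0.10, 0.04, 0.80    # SEARCH
  ), nrow = 4, byrow = TRUE, dimnames = list(STATE_LEVELS, STATE_LEVELS))
  m
}

#' Default season table
#'
#' Five breeding seasons emulating a cool-to-warm SST spectrum: two cool
#' (La Nina-like) seasons, two near-neutral, and one strongly warm
#' (El Nino-like, +2 degC). `mbd` is the population median breeding date in
#' days since the season start (1 November), spanning about three weeks.
#' @export
default_seasons <- function() {
  data.frame(
    season = c("S1", "S2", "S3", "S4", "S5"),
    year = c(2011, 2012, 2014, 2015, 2016),
    sst_offset = c(-1.0, 0.0, 0.3, 2.0, -0.5),
    mbd = c(24, 30, 36, 43, 28),
    stringsAsFactors = FALSE
  )
}

#' Build and validate a simulation configuration
#'
#' The configuration is the generator's statement of the world it emulates:
#' a cohort of known-age central-place foragers tracked over several
#' breeding seasons with contrasting SST regimes, one multi-day foraging
#' absence per bird-season driven by a four-state movement model, a
#' U-shaped (quadratic) age effect on target absence duration, and a mass
#' gain rate per search hour carrying an age-by-SST interaction.
#'
#' @param n_birds Number of birds in the cohort.
#' @param seasons Data frame with columns `season`, `year`, `sst_offset`
#'   (degC), `mbd` (median breeding date, day of season).
#' @param age_range Integer range of ages sampled, within `[4, 25]`.
#' @param sex_ratio Fraction of males.
#' @param fix_interval Fix interval in minutes, 3 or 5.
#' @param colony Colony position `c(lon, lat)` in degrees.
#' @param colony_radius_km Radius defining "at the colony".
#' @param state_params Data frame as [default_state_params()].
#' @param transition_matrix Row-stochastic 4x4 matrix.
#' @param trip_model Coefficients (hours scale) of the target absence
#'   duration: `intercept + age*A + age2*A^2 + sst*SSTc + sex_male*I(male)`
#'   plus bird and departure-window random intercepts and residual noise.
#'   `SSTc` is SST centred on `sst_base`.
#' @param mass_model Mass bookkeeping: `daily_loss` (g/day incubation mass
#'   loss), `gain_base` (g per search hour), `gain_age_sst` (age-by-SST
#'   interaction on the gain rate, g/h per year*degC; ages centred at 12),
#'   `gain_age` (g/h per year), `gain_sd` (bird-level noise on the rate).
#' @param sigma_id,sigma_departgroup,sigma_resid Random-effect SDs (hours,
#'   on target absence duration).
#' @param sst_base Mean SST (degC) about which seasonal offsets apply.
#' @param sst_trend Within-season SST slope (degC/day).
#' @param sst_noise Daily SST noise SD (degC).
#' @param daylight_method Passed to [daylight_mask()].
#' @param seed Integer seed recorded in the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_birds = 40,
                       seasons = default_seasons(),
                       age_range = c(4, 25),
                       sex_ratio = 0.5,
                       fix_interval = 5,
                       colony = c(-89.6167, -1.3833),
                       colony_radius_km = 1,
                       state_params = default_state_params(),
                       transition_matrix = default_transition_matrix(),
                       trip_model = list(intercept = 46.6, age = -3.6,
                                         age2 = 0.15, sst = -2.0,
                                         sex_male = -2.0),
                       mass_model = list(daily_loss = 20, gain_base = 30,
                                         gain_age = -0.3, gain_age_sst = 0.4,
                                         gain_sd = 3),
                       sigma_id = 2.0,
                       sigma_departgroup = 1.5,
                       sigma_resid = 3.0,
                       sst_base = 25,
                       sst_trend = 0.02,
                       sst_noise = 0.3,
                       daylight_method = "solar",
                       seed = 1L) {
  cfg <- list(n_birds = n_birds, seasons = seasons, age_range = age_range,
              sex_ratio = sex_ratio, fix_interval = fix_interval,
              colony = colony, colony_radius_km = colony_radius_km,
              state_params = state_params,
              transition_matrix = transition_matrix,
              trip_model = trip_model, mass_model = mass_model,
              sigma_id = sigma_id, sigma_departgroup = sigma_departgroup,
              sigma_resid = sigma_resid,
              sst_base = sst_base, sst_trend = sst_trend,
              sst_noise = sst_noise, daylight_method = daylight_method,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants (row-stochastic transitions,
#' non-negative SDs, fix interval in {3, 5}, ages within `[4, 25]`) and
#' errors on the first violation.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  if (!is.data.frame(cfg$seasons) || nrow(cfg$seasons) < 1)
    stop("configuration error: at least one season must be defined")
  need <- c("season", "sst_offset", "mbd")
  if (!all(need %in% names(cfg$seasons)))
    stop("configuration error: seasons table needs columns ",
         paste(need, collapse = ", "))
  if (cfg$n_birds < 1) stop("configuration error: n_birds must be >= 1")
  if (!cfg$fix_interval %in% c(3, 5))
    stop("configuration error: fix_interval must be 3 or 5 minutes")
  if (cfg$age_range[1] < 4 || cfg$age_range[2] > 25 ||
      cfg$age_range[1] > cfg$age_range[2])
    stop("configuration error: age_range must lie within [4, 25]")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1)
    stop("configuration error: sex_ratio must be in [0, 1]")
  tm <- cfg$transition_matrix
  if (!is.matrix(tm) || any(dim(tm) != c(4, 4)))
    stop("configuration error: transition_matrix must be 4x4")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-12))
    stop("configuration error: transition_matrix rows must sum to 1")
  sds <- c(cfg$sigma_id, cfg$sigma_departgroup, cfg$sigma_resid,
           cfg$sst_noise, cfg$state_params$speed_sd)
  if (any(sds < 0)) stop("configuration error: all SDs must be >= 0")
  if (any(cfg$state_params$turn_rho < 0 | cfg$state_params$turn_rho > 1))
    stop("configuration error: turn_rho must be in [0, 1]")
  if (is.null(cfg$seed)) stop("configuration error: seed is required")
  invisible(cfg)
}

# Season start instant (1 November of the season's year, UTC).
season_start <- function(seasons) {
  as.POSIXct(paste0(seasons$year, "-11-01 00:00:00"), tz = "UTC")
}
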