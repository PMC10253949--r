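# Synthetic GPS tracks: a discrete-time four-state correlated random walk
# from the colony, with forced nocturnal rest, a homeward turn once the
# target absence duration is reached, and mass accrual during search.

# Gaussian truncated at zero by rejection (means here sit >= 1.5 sd above 0).
rtnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

# Wrapped-Cauchy turning angles, mu = 0, concentration rho in [0, 1].
rwrapped_cauchy <- function(n, rho) {
  if (rho >= 1) return(rep(0, n))
  u <- stats::runif(n)
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
}

# One transition of the four-state chain (shared by the track loop).
.step_state <- function(state, tm) {
  sample.int(4L, 1L, prob = tm[state, ])
}

#' Simulate the four-state Markov chain in isolation
#'
#' The bare state-switching process of the track generator, without night
#' forcing or homeward phases; used to check empirical dwell frequencies
#' against the transition matrix's stationary distribution.
#'
#' @param n_steps Chain length.
#' @param transition_matrix Row-stochastic 4x4 matrix.
#' @param init Initial state index (1-4).
#' @param seed Integer seed.
#' @return Integer vector of state indices.
#' @export
simulate_state_chain <- function(n_steps, transition_matrix, init = 2L,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  s <- integer(n_steps)
  cur <- as.integer(init)
  for (i in seq_len(n_steps)) {
    cur <- .step_state(cur, transition_matrix)
    s[i] <- cur
  }
  s
}

#' Simulate one foraging absence track
#'
#' State-switching correlated random walk at the configured fix interval.
#' The bird leaves the colony in a forced commuting bout, then switches
#' among the four states by the transition matrix; all night-time steps are
#' forced to rest; once wall-clock time exceeds the bird's target absence
#' duration the bird commutes straight back to the colony (by daylight) and
#' the track ends inside the colony radius. Mass accrues linearly during
#' daylight search at the bird's gain rate.
#'
#' @param bird A list or one-row data frame with `bird_id`, `sex`, `age`,
#'   `season`, `depart_time` (POSIXct UTC), `depart_mass_g`,
#'   `target_duration_h` (> 0), `gain_rate_g_h`.
#' @param config A [sim_config()].
#' @param seed Integer seed; required (reproducibility contract).
#' @return A list with `fixes` (bird_id, timestamp, lon, lat), and `truth`:
#'   the latent `states` per step plus departure/return time and mass and
#'   the five true trait values.
#' @export
simulate_absence_track <- function(bird, config, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is required to simulate a track")
  if (bird$age < config$age_range[1] || bird$age > config$age_range[2])
    stop("bird age ", bird$age, " outside configured age range")
  if (is.null(bird$target_duration_h) || bird$target_duration_h <= 0)
    stop("target absence duration must be > 0")
  set.seed(as.integer(seed))

  sp <- config$state_params
  tm <- config$transition_matrix
  dt_s <- config$fix_interval * 60
  dt_h <- dt_s / 3600
  colony <- config$colony
  target_h <- bird$target_duration_h

  max_steps <- ceiling((target_h + 96) / dt_h)
  xs <- ys <- numeric(max_steps)
  states <- integer(max_steps)
  day_flag <- logical(max_steps)
  x <- 0; y <- 0
  heading <- stats::runif(1, -pi, pi)
  state <- 2L                      # COMMUTE out of the colony
  t0 <- as.POSIXct(bird$depart_time, tz = "UTC")
  tt <- t0
  mass <- bird$depart_mass_g
  search_h_day <- 0
  phase <- "out"
  n <- 0L

  for (i in seq_len(max_steps)) {
    # a step is a daylight step if its midpoint is in daylight (the same
    # convention the processing pipeline applies to observed steps)
    day <- daylight_mask(tt + dt_s / 2, colony[1], colony[2],
                         method = config$daylight_method)
    if (!day) {
      state <- 1L                  # forced rest at night
    } else if (phase == "home") {
      state <- 2L
    } else if (i <= 30 / config$fix_interval) {
      state <- 2L                  # initial outbound commute (~30 min)
    } else {
      state <- .step_state(state, tm)
    }
    speed <- rtnorm_pos(1, sp$speed_mean[state], sp$speed_sd[state])
    if (phase == "home" && day) {
      heading <- atan2(-y, -x)     # straight back to the colony
      d_col <- sqrt(x^2 + y^2)
      step_km <- min(speed * dt_s / 1000, max(d_col - 0.2, 0))
    } else {
      heading <- heading + rwrapped_cauchy(1, sp$turn_rho[state])
      step_km <- speed * dt_s / 1000
      # keep the outbound walk from drifting back inside the colony radius
      if (phase == "out" && sqrt(x^2 + y^2) < 2 * config$colony_radius_km &&
          i > 3) {
        heading <- atan2(y, x)
      }
    }
    x <- x + step_km * cos(heading)
    y <- y + step_km * sin(heading)
    if (state == 4L && day) {
      mass <- mass + bird$gain_rate_g_h * dt_h
      search_h_day <- search_h_day + dt_h
    }
    tt <- tt + dt_s
    n <- n + 1L
    xs[n] <- x; ys[n] <- y; states[n] <- state; day_flag[n] <- day
    elapsed_h <- as.numeric(difftime(tt, t0, units = "hours"))
    if (phase == "out" && elapsed_h >= target_h) phase <- "home"
    if (phase == "home" && sqrt(x^2 + y^2) <= config$colony_radius_km) break
  }

  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  states <- states[seq_len(n)]; day_flag <- day_flag[seq_len(n)]
  ll <- unproject_local(xs, ys, colony)
  times <- t0 + dt_s * seq_len(n)
  steps_km <- sqrt(diff(c(0, xs))^2 + diff(c(0, ys))^2)

  total_h <- as.numeric(difftime(times[n], t0, units = "hours"))
  truth <- list(
    bird_id = bird$bird_id,
    season = bird$season,
    states = STATE_LEVELS[states],
    depart_time = t0,
    return_time = times[n],
    depart_mass_g = bird$depart_mass_g,
    return_mass_g = mass,
    total_duration_h = total_h,
    absence_duration_h = sum(day_flag) * dt_h,
    total_distance_km = sum(steps_km[day_flag]),
    time_searching_h = search_h_day,
    mass_gain_g = mass - bird$depart_mass_g,
    mass_gain_per_h = (mass - bird$depart_mass_g) / total_h
  )
  fixes <- data.frame(
    bird_id = bird$bird_id,
    timestamp = times,
    lon = ll$lon, lat = ll$lat,
    stringsAsFactors = FALSE
  )
  list(fixes = fixes, truth = truth)
}

# Age-group ranges used when sampling the cohort (age 10 is deliberately
# absent, mirroring its absence from the study population's groups).
.age_group_ranges <- list(Young = 4:9, MiddleAge = 11:16,
                          Old = 17:20, Oldest = 21:25)

# Sample cohort ages cycling over the four age groups, restricted to range.
sample_cohort_ages <- function(n, age_range) {
  pools <- lapply(.age_group_ranges, function(r)
    r[r >= age_range[1] & r <= age_range[2]])
  pools <- pools[vapply(pools, length, 1L) > 0]
  grp <- rep(seq_along(pools), length.out = n)
  vapply(seq_len(n), function(i) {
    p <- pools[[grp[i]]]
    p[sample.int(length(p), 1L)]
  }, numeric(1))
}

# Linear predictor of target absence duration (hours), before random effects.
trip_target_mean <- function(trip_model, age, sst_c, sex) {
  trip_model$intercept + trip_model$age * age + trip_model$age2 * age^2 +
    trip_model$sst * sst_c + trip_model$sex_male * (sex == "male")
}

# Mass gain rate (g per search hour) for a bird; ages centred at 12.
mass_gain_rate <- function(mass_model, age, sst_c, noise = 0) {
  mass_model$gain_base + mass_model$gain_age * (age - 12) +
    mass_model$gain_age_sst * (age - 12) * sst_c + noise
}

#' Simulate a complete tracking dataset
#'
#' Generates the environment, a cohort of birds with ages cycling over the
#' four age groups and sexes at the configured ratio, and one foraging
#' absence per bird-season. Deployment groups of four same-sex birds share
#' a departure window; departure-window (10-day bin) and bird random
#' intercepts plus residual noise perturb each absence's target duration.
#' Colony-resting fixes (2 h) are added before and after each absence so
#' absence delimitation can be exercised on the output.
#'
#' @param config A [sim_config()].
#' @param output_dir Optional directory; when given, writes `fixes.csv`,
#'   `birds.csv`, `env_sst.csv`, `env_cloud.csv`, `truth.csv` and a
#'   `manifest.json` recording the seed.
#' @return A list: `fixes`, `birds`, `env` (list of tables), `truth`
#'   (data frame), `truth_states` (list of latent state vectors keyed by
#'   `bird_id.season`).
#' @export
simulate_dataset <- function(config, output_dir = NULL) {
  validate_sim_config(config)
  if (config$n_birds < 1) stop("n_birds must be >= 1")
  env <- generate_environment(config)
  set.seed(config$seed)

  n <- config$n_birds
  n_male <- round(n * config$sex_ratio)
  birds <- data.frame(
    bird_id = sprintf("B%04d", seq_len(n)),
    sex = rep(c("male", "female"), c(n_male, n - n_male)),
    age = sample_cohort_ages(n, config$age_range),
    wing_chord_m = NA_real_,
    stringsAsFactors = FALSE
  )
  birds$wing_chord_m <- stats::rnorm(n, ifelse(birds$sex == "male",
                                               0.43, 0.45), 0.012)
  re_id <- stats::rnorm(n, 0, config$sigma_id)

  seasons <- config$seasons
  starts <- season_start(seasons)
  fixes_list <- list(); truth_list <- list(); meta_list <- list()
  truth_states <- list()
  k <- 0L
  for (s in seq_len(nrow(seasons))) {
    # same-sex deployment groups of 4 share a departure day
    ord <- order(birds$sex)
    grp <- (seq_len(n) - 1) %/% 4
    grp_day <- sample(10:60, max(grp) + 1, replace = TRUE)
    day_of <- integer(n)
    day_of[ord] <- grp_day[grp + 1]
    re_dg_tab <- new.env()
    for (b in seq_len(n)) {
      k <- k + 1L
      day <- day_of[b]
      bin <- day %/% 10
      key <- paste(seasons$season[s], bin, sep = ".")
      if (is.null(re_dg_tab[[key]]))
        re_dg_tab[[key]] <- stats::rnorm(1, 0, config$sigma_departgroup)
      sst <- sst_window_mean(env$sst, seasons$season[s], day)
      sst_c <- sst - config$sst_base
      target <- trip_target_mean(config$trip_model, birds$age[b], sst_c,
                                 birds$sex[b]) +
        re_id[b] + re_dg_tab[[key]] + stats::rnorm(1, 0, config$sigma_resid)
      target <- max(target, 6)
      days_dep <- sample(1:3, 1)
      deploy_mass <- stats::rnorm(1, ifelse(birds$sex[b] == "male",
                                            1700, 1990), 80)
      depart_mass <- deploy_mass - days_dep * config$mass_model$daily_loss
      gain <- mass_gain_rate(config$mass_model, birds$age[b], sst_c,
                             stats::rnorm(1, 0, config$mass_model$gain_sd))
      gain <- max(gain, 1)
      # local morning departures (colony sits near UTC-6)
      depart_time <- starts[s] + day * 86400 +
        round(stats::runif(1, 13, 17)) * 3600
      bird <- list(bird_id = birds$bird_id[b], sex = birds$sex[b],
                   age = birds$age[b], season = seasons$season[s],
                   depart_time = depart_time, depart_mass_g = depart_mass,
                   target_duration_h = target, gain_rate_g_h = gain)
      sim <- simulate_absence_track(bird, config, seed = config$seed + 17L * k)
      tr <- sim$truth

      # colony-resting fixes before departure and after return
      dt_s <- config$fix_interval * 60
      n_pad <- ceiling(2 * 3600 / dt_s)
      jit <- config$colony_radius_km * 0.1
      pre_t <- depart_time - dt_s * rev(seq_len(n_pad) - 1)
      post_t <- tr$return_time + dt_s * seq_len(n_pad)
      pad <- function(times) {
        p <- unproject_local(stats::rnorm(length(times), 0, jit),
                             stats::rnorm(length(times), 0, jit),
                             config$colony)
        data.frame(bird_id = birds$bird_id[b], timestamp = times,
                   lon = p$lon, lat = p$lat, stringsAsFactors = FALSE)
      }
      fixes_list[[k]] <- rbind(pad(pre_t), sim$fixes, pad(post_t))
      truth_states[[paste(birds$bird_id[b], seasons$season[s], sep = ".")]] <-
        tr$states
      truth_list[[k]] <- data.frame(
        bird_id = tr$bird_id, season = tr$season,
        age = birds$age[b], sex = birds$sex[b],
        depart_day = day, depart_group = bin,
        sst_matched = sst,
        depart_time = tr$depart_time, return_time = tr$return_time,
        depart_mass_g = tr$depart_mass_g, return_mass_g = tr$return_mass_g,
        total_duration_h = tr$total_duration_h,
        absence_duration_h = tr$absence_duration_h,
        total_distance_km = tr$total_distance_km,
        time_searching_h = tr$time_searching_h,
        mass_gain_g = tr$mass_gain_g,
        mass_gain_per_h = tr$mass_gain_per_h,
        target_duration_h = target,
        stringsAsFactors = FALSE
      )
      meta_list[[k]] <- data.frame(
        bird_id = birds$bird_id[b], sex = birds$sex[b], age = birds$age[b],
        season = seasons$season[s], logger = sample(c("GT120", "GT600"), 1),
        deploy_mass_g = deploy_mass,
        deploy_date = as.Date(depart_time) - days_dep,
        days_since_deployment = days_dep,
        wing_chord_m = birds$wing_chord_m[b],
        return_mass_g = tr$return_mass_g,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(fixes = do.call(rbind, fixes_list),
              birds = do.call(rbind, meta_list),
              env = env,
              truth = do.call(rbind, truth_list),
              truth_states = truth_states,
              config = config)
  if (!is.null(output_dir)) write_sim_dataset(out, output_dir)
  out
}

#' Write a simulated dataset to CSV files
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- dataset$fixes
  fx$timestamp <- format(fx$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(fx, file.path(dir, "fixes.csv"), row.names = FALSE)
  utils::write.csv(dataset$birds, file.path(dir, "birds.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$env$sst, file.path(dir, "env_sst.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$env$cloud, file.path(dir, "env_cloud.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$env$mbd, file.path(dir, "env_mbd.csv"),
                   row.names = FALSE)
  tr <- dataset$truth
  tr$depart_time <- format(tr$depart_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tr$return_time <- format(tr$return_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = dataset$config$seed,
                            n_birds = dataset$config$n_birds,
                            fix_interval = dataset$config$fix_interval),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate per-absence trait records directly from the trait model
#'
#' Draws trait values from the generator's trait layer (fixed effects of
#' age, SST, sex plus crossed bird and departure-window random intercepts
#' and residual noise) without simulating GPS tracks. Used for mixed-model
#' calibration at sample sizes where track simulation would be wasteful;
#' the distributional assumptions are exactly those the track generator
#' embeds in its target absence duration.
#'
#' @param config A [sim_config()].
#' @param n_absences Total number of absence records.
#' @param n_seasons_per_bird Repeat measures per bird (default 2).
#' @param seed Integer seed.
#' @return A data frame with `bird_id`, `depart_group`, `season`, `age`,
#'   `sex`, `sst_c`, `duration_h` (the trait), and the generator's linear
#'   predictor `mu`.
#' @export
simulate_trait_table <- function(config, n_absences = 500,
                                 n_seasons_per_bird = 2, seed = 1L) {
  set.seed(as.integer(seed))
  n_birds <- ceiling(n_absences / n_seasons_per_bird)
  ages <- sample_cohort_ages(n_birds, config$age_range)
  n_male <- round(n_birds * config$sex_ratio)
  sexes <- rep(c("male", "female"), c(n_male, n_birds - n_male))
  re_id <- stats::rnorm(n_birds, 0, config$sigma_id)
  seasons <- config$seasons
  rows <- list()
  k <- 0L
  for (s in seq_len(n_seasons_per_bird)) {
    season <- seasons$season[(s - 1) %% nrow(seasons) + 1]
    off <- seasons$sst_offset[(s - 1) %% nrow(seasons) + 1]
    day <- sample(10:60, n_birds, replace = TRUE)
    bin <- day %/% 10
    dg_key <- paste(season, bin)
    dg_levels <- unique(dg_key)
    re_dg <- stats::rnorm(length(dg_levels), 0, config$sigma_departgroup)
    names(re_dg) <- dg_levels
    sst_c <- off + stats::rnorm(n_birds, 0, config$sst_noise)
    mu <- trip_target_mean(config$trip_model, ages, sst_c, sexes)
    k <- k + 1L
    rows[[k]] <- data.frame(
      bird_id = sprintf("B%04d", seq_len(n_birds)),
      depart_group = dg_key, season = season,
      age = ages, sex = sexes, sst_c = sst_c, mu = mu,
      duration_h = mu + re_id + re_dg[dg_key] +
        stats::rnorm(n_birds, 0, config$sigma_resid),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out[seq_len(min(nrow(out), n_absences)), , drop = FALSE]
}
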