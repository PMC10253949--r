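# Shared fixtures, generated once per test run and memoised.

# Two-season cohort with one cool and one warm (El Nino-like) season.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_birds = 20,
                        seasons = default_seasons()[c(1, 4), ],
                        seed = 402L)
      cache <<- list(cfg = cfg, ds = simulate_dataset(cfg))
    }
    cache
  }
})

# Detected absence steps for record i of the shared dataset, aligned
# 1:1 with the generator's latent state sequence.
aligned_absence_steps <- function(ds, cfg, i) {
  b <- ds$birds[i, ]
  t0 <- as.POSIXct(as.Date(b$deploy_date), tz = "UTC")
  fx <- ds$fixes[ds$fixes$bird_id == b$bird_id &
                   ds$fixes$timestamp >= t0 &
                   ds$fixes$timestamp <= t0 + 30 * 86400, ]
  ab <- detect_first_absence(fx, cfg$colony)
  st <- absence_steps(fx, ab, cfg$colony)
  list(steps = st, absence = ab, bird = b,
       truth = ds$truth[i, ],
       truth_states = ds$truth_states[[paste(b$bird_id, b$season,
                                             sep = ".")]])
}

# Trait-layer dataset (no tracks) with modelling covariate columns.
trait_layer_data <- function(cfg, n = 400, seed = 1L) {
  tt <- simulate_trait_table(cfg, n_absences = n, seed = seed)
  set.seed(seed + 5000L)
  tt$absence_duration_h <- tt$duration_h
  tt$logger <- sample(c("GT120", "GT600"), nrow(tt), TRUE)
  tt$date_z <- stats::rnorm(nrow(tt))
  tt$wing_loading_z <- stats::rnorm(nrow(tt))
  tt$sst_resid <- tt$sst_c
  tt$mbd_z <- 0
  tt$cloud_mean <- stats::runif(nrow(tt))
  tt
}

# Synthetic track bundles for the spatial randomization tests.
make_point_tracks <- function(k, n_pts = 25, center = c(0, 0),
                              track_sd = 2, point_sd = 1.5) {
  lapply(seq_len(k), function(i) {
    cx <- stats::rnorm(1, center[1], track_sd)
    cy <- stats::rnorm(1, center[2], track_sd)
    list(x = cx + stats::rnorm(n_pts, 0, point_sd),
         y = cy + stats::rnorm(n_pts, 0, point_sd))
  })
}
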