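# Synthetic environmental series: SST, cloud cover, median breeding date.

#' Generate synthetic environment tables
#'
#' Produces daily SST for each season (seasonal linear trend + season
#' regime offset + Gaussian noise), cloud-cover fractions in 6-hour blocks
#' (Beta-distributed with mild day-to-day persistence), and the per-season
#' median breeding date.
#'
#' @param config A [sim_config()].
#' @param n_days Days simulated per season (from the 1 November start).
#' @return A list of data frames: `sst` (season, day, date, sst), `cloud`
#'   (season, day, block, cloud), `mbd` (season, mbd).
#' @export
generate_environment <- function(config, n_days = 90) {
  validate_sim_config(config)
  set.seed(config$seed + 1003L)
  seasons <- config$seasons
  starts <- season_start(seasons)
  sst <- do.call(rbind, lapply(seq_len(nrow(seasons)), function(i) {
    day <- 0:(n_days - 1)
    data.frame(
      season = seasons$season[i],
      day = day,
      date = as.Date(starts[i]) + day,
      sst = config$sst_base + seasons$sst_offset[i] +
        config$sst_trend * day +
        stats::rnorm(n_days, 0, config$sst_noise),
      stringsAsFactors = FALSE
    )
  }))
  cloud <- do.call(rbind, lapply(seq_len(nrow(seasons)), function(i) {
    grid <- expand.grid(day = 0:(n_days - 1), block = 0:3)
    # persistent daily regime, Beta noise within the day
    regime <- stats::filter(stats::rnorm(n_days), 0.7, method = "recursive")
    p <- stats::pnorm(as.numeric(regime) / 1.4)
    val <- stats::rbeta(nrow(grid), 1 + 3 * p[grid$day + 1],
                        1 + 3 * (1 - p[grid$day + 1]))
    data.frame(season = seasons$season[i], day = grid$day,
               block = grid$block, cloud = pmin(1, pmax(0, val)),
               stringsAsFactors = FALSE)
  }))
  mbd <- data.frame(season = seasons$season, mbd = seasons$mbd,
                    stringsAsFactors = FALSE)
  list(sst = sst, cloud = cloud, mbd = mbd)
}

# Mean SST over the 8-day compositing window containing `day` (matching the
# temporal resolution of satellite SST products).
sst_window_mean <- function(sst_table, season, day) {
  w <- day %/% 8
  rows <- sst_table$season == season & sst_table$day %/% 8 == w
  if (!any(rows)) {
    stop("absence on season ", season, " day ", day,
         " is outside environment coverage")
  }
  mean(sst_table$sst[rows])
}
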