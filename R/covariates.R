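# Assembly of the analysis table: standardized covariates, matched and
# detrended SST, daylight cloud averages, departure-date bins.

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Prepare the modelling covariates for a trait table
#'
#' Adds to each absence record: day-of-season and its global z-score
#' (`date_z`), the 10-day departure bin (`depart_group`), standardized
#' wing loading (`wing_loading_z`), standardized per-season median
#' breeding date (`mbd_z`), SST matched by the 8-day window containing
#' the departure day and detrended by a pooled linear regression on
#' day-of-season (`sst_resid`, plus raw `sst_matched`), and cloud cover
#' averaged over the daylight blocks of the absence's day span
#' (`cloud_mean`).
#'
#' @param traits Trait table from [build_trait_table()] (needs
#'   `depart_time`, `season`, `wing_loading`, `total_duration_h`).
#' @param env Environment tables from [generate_environment()].
#' @param seasons Season table (`season`, `year`, `mbd`).
#' @return The trait table with covariate columns appended.
#' @export
prepare_covariates <- function(traits, env, seasons) {
  starts <- season_start(seasons)
  names(starts) <- seasons$season
  t0 <- starts[traits$season]
  day <- floor(as.numeric(difftime(traits$depart_time, t0,
                                   units = "days")))
  if (any(is.na(day)))
    stop("absence with unknown season: ",
         traits$bird_id[which(is.na(day))[1]])
  traits$depart_day <- day
  traits$depart_group <- day %/% 10
  traits$date_z <- zscore(day)
  traits$wing_loading_z <- zscore(traits$wing_loading)
  mbd <- seasons$mbd[match(traits$season, seasons$season)]
  traits$mbd_z <- zscore(mbd)

  sst <- mapply(function(s, d) {
    sst_window_mean(env$sst, s, d)
  }, traits$season, day)
  traits$sst_matched <- sst
  # detrend on the centre of the matched 8-day window (pooled across
  # seasons): "relatively warm or cool for the time of year"
  wday <- (day %/% 8) * 8 + 3.5
  fit <- stats::lm(sst ~ wday)
  traits$sst_resid <- unname(stats::resid(fit))

  # daylight blocks (06-12, 12-18 local) over the days spanned by the
  # absence, averaged; block resolution stands in for per-fix matching
  end_day <- floor(as.numeric(difftime(
    traits$depart_time + traits$total_duration_h * 3600, t0,
    units = "days")))
  cl <- env$cloud
  traits$cloud_mean <- vapply(seq_len(nrow(traits)), function(i) {
    rows <- cl$season == traits$season[i] &
      cl$day >= day[i] & cl$day <= end_day[i] & cl$block %in% c(1, 2)
    if (!any(rows))
      stop("absence of ", traits$bird_id[i],
           " outside cloud-cover coverage")
    mean(cl$cloud[rows])
  }, numeric(1))
  traits
}
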