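# Pipeline orchestration: simulate -> process -> behavior -> traits ->
# model -> spatial -> report, file-based between stages, with a manifest
# recording seeds, checksums and exclusion counts.

PIPELINE_STAGES <- c("simulate", "process", "behavior", "traits",
                     "model", "spatial", "report")

# Artifacts each stage needs before it can run (stage named in errors).
.stage_requires <- list(
  simulate = character(0),
  process = c("fixes.csv", "birds.csv"),
  behavior = c("steps.csv", "birds.csv"),
  traits = c("steps.csv", "states.csv", "birds.csv"),
  model = c("traits.csv", "env_sst.csv", "env_mbd.csv", "env_cloud.csv"),
  spatial = c("steps.csv", "states.csv", "birds.csv"),
  report = c("traits.csv")
)
.stage_producing <- c(
  fixes.csv = "simulate", birds.csv = "simulate",
  env_sst.csv = "simulate", env_mbd.csv = "simulate",
  env_cloud.csv = "simulate",
  steps.csv = "process", absences.csv = "process",
  states.csv = "behavior", traits.csv = "traits")

#' Default pipeline configuration
#'
#' Defaults mirror published analysis constants where they exist: 5-min
#' fix interval, 3-h minimum absence, 1-km colony radius, 500-m UD grid,
#' 1000 permutations, AICc top-set cutoff of 2, FDR q = 0.05.
#'
#' @param ... Named overrides merged (shallow per block) into the
#'   defaults.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    sim = list(),                       # passed to sim_config()
    process = list(interval = 5, max_gap = 30, radius_km = 1,
                   min_absence_h = 3),
    behavior = list(fit = TRUE, min_steps = 200),
    traits = list(daily_loss = 20),
    model = list(trait = "absence_duration_h", sexes = c("female", "male"),
                 delta_max = 2),
    spatial = list(n_perm = 1000, cell_m = 500, q = 0.05,
                   sexes = c("female", "male"))
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  cfg
}

read_csv_ <- function(dir, name, time_cols = character(0)) {
  x <- utils::read.csv(file.path(dir, name), stringsAsFactors = FALSE)
  for (tc in intersect(time_cols, names(x)))
    x[[tc]] <- as.POSIXct(x[[tc]], tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%OSZ")
  x
}

write_csv_ <- function(x, dir, name, time_cols = character(0)) {
  for (tc in intersect(time_cols, names(x)))
    x[[tc]] <- format(x[[tc]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, reading each stage's inputs
#' from files written by earlier stages under `out_dir`, and writes a
#' manifest (seed, per-file MD5 checksums, exclusion counts). Rerunning
#' with an identical configuration and seed reproduces identical CSVs.
#'
#' @param config Configuration list from [default_pipeline_config()].
#' @param stages Character vector of stages (subset of
#'   simulate, process, behavior, traits, model, spatial, report).
#' @param out_dir Run directory.
#' @param seed Integer master seed; overrides `config$sim$seed`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = PIPELINE_STAGES, out_dir, seed = 1L) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  config$sim$seed <- as.integer(seed)
  sim_cfg <- do.call(sim_config, config$sim)   # validates before any stage
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exclusions <- list()

  for (st in stages) {
    need <- .stage_requires[[st]]
    missing_ <- need[!file.exists(file.path(out_dir, need))]
    if (length(missing_)) {
      stop("stage '", st, "' is missing artifact ", missing_[1],
           "; run stage '", .stage_producing[[missing_[1]]], "' first")
    }
    switch(st,
      simulate = {
        ds <- simulate_dataset(sim_cfg, output_dir = out_dir)
      },
      process = {
        fixes <- read_csv_(out_dir, "fixes.csv", "timestamp")
        birds <- read_csv_(out_dir, "birds.csv")
        res <- stage_process(fixes, birds, sim_cfg, config$process)
        write_csv_(res$steps, out_dir, "steps.csv", "t_mid")
        write_csv_(res$absences, out_dir, "absences.csv",
                   c("depart_time", "return_time"))
        exclusions$no_absence <- res$n_no_absence
      },
      behavior = {
        steps <- read_csv_(out_dir, "steps.csv", "t_mid")
        birds <- read_csv_(out_dir, "birds.csv")
        res <- stage_behavior(steps, birds, config$behavior,
                              seed = seed + 101L)
        write_csv_(res$states, out_dir, "states.csv")
        jsonlite::write_json(res$delims, file.path(out_dir,
                                                   "delimiters.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      traits = {
        steps <- read_csv_(out_dir, "steps.csv", "t_mid")
        states <- read_csv_(out_dir, "states.csv")
        birds <- read_csv_(out_dir, "birds.csv")
        absences <- read_csv_(out_dir, "absences.csv",
                              c("depart_time", "return_time"))
        tr <- stage_traits(steps, states, birds, absences,
                           config$traits)
        write_csv_(tr, out_dir, "traits.csv", "depart_time")
      },
      model = {
        traits <- read_csv_(out_dir, "traits.csv", "depart_time")
        env <- list(sst = read_csv_(out_dir, "env_sst.csv"),
                    cloud = read_csv_(out_dir, "env_cloud.csv"),
                    mbd = read_csv_(out_dir, "env_mbd.csv"))
        res <- stage_model(traits, env, sim_cfg$seasons, config$model)
        write_csv_(res$stage1, out_dir, "stage1_ranking.csv")
        write_csv_(res$stage2, out_dir, "stage2_ranking.csv")
        write_csv_(res$coefficients, out_dir, "coefficients.csv")
        exclusions$log_transform_drops <- res$n_excluded
      },
      spatial = {
        steps <- read_csv_(out_dir, "steps.csv", "t_mid")
        states <- read_csv_(out_dir, "states.csv")
        birds <- read_csv_(out_dir, "birds.csv")
        res <- stage_spatial(steps, states, birds, sim_cfg$colony,
                             config$spatial, seed = seed + 202L,
                             out_dir = out_dir)
        write_csv_(res$overlaps, out_dir, "overlap_results.csv")
        exclusions$age10_birds <- res$n_age10
      },
      report = {
        stage_report(out_dir)
      })
  }

  files <- list.files(out_dir, pattern = "\\.(csv|json|asc|md)$")
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    seed = as.integer(seed),
    stages = stages,
    config = config[setdiff(names(config), "sim")],
    sim = list(n_birds = sim_cfg$n_birds, seed = sim_cfg$seed,
               fix_interval = sim_cfg$fix_interval),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))),
    exclusions = exclusions)
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# process stage: interpolate, delimit the first absence, compute steps.
stage_process <- function(fixes, birds, sim_cfg, pcfg) {
  steps_list <- list(); abs_list <- list(); dropped <- 0L
  for (i in seq_len(nrow(birds))) {
    b <- birds[i, ]
    sel <- fixes$bird_id == b$bird_id
    if (!is.null(b$deploy_date)) {
      t0 <- as.POSIXct(as.Date(b$deploy_date), tz = "UTC")
      sel <- sel & fixes$timestamp >= t0 & fixes$timestamp <= t0 + 30 * 86400
    }
    fx <- fixes[sel, , drop = FALSE]
    if (nrow(fx) < 2) { dropped <- dropped + 1L; next }
    fx <- interpolate_track(fx, pcfg$interval, pcfg$max_gap)
    ab <- detect_first_absence(fx, sim_cfg$colony, pcfg$radius_km,
                               pcfg$min_absence_h)
    if (!isTRUE(ab$found)) { dropped <- dropped + 1L; next }
    st <- absence_steps(fx, ab, sim_cfg$colony, sim_cfg$daylight_method)
    aid <- paste(b$bird_id, b$season, sep = ".")
    st <- cbind(absence_id = aid, st, idx = seq_len(nrow(st)))
    steps_list[[length(steps_list) + 1L]] <- st
    abs_list[[length(abs_list) + 1L]] <- data.frame(
      absence_id = aid, bird_id = b$bird_id, season = b$season,
      depart_time = ab$depart_time, return_time = ab$return_time,
      duration_h = ab$duration_h, stringsAsFactors = FALSE)
  }
  list(steps = do.call(rbind, steps_list),
       absences = do.call(rbind, abs_list),
       n_no_absence = dropped)
}

# behavior stage: delimiters per sex (fitted when enough steps), labels.
stage_behavior <- function(steps, birds, bcfg, seed = 1L) {
  sex_of <- birds$sex[match(sub("\\..*$", "", steps$absence_id),
                            birds$bird_id)]
  delims <- list(); states_list <- list()
  for (sx in unique(sex_of)) {
    sub <- steps[sex_of == sx, , drop = FALSE]
    d <- if (isTRUE(bcfg$fit) &&
             sum(is.finite(sub$speed_ms)) >= bcfg$min_steps) {
      fit_delimiters(sub, sex = sx, seed = seed)
    } else {
      reference_delimiters(paste0(sx, "_paper"))
    }
    delims[[sx]] <- list(speed_split = d$speed_split,
                         turn_split = d$turn_split,
                         provenance = d$provenance)
    cls <- classify_states(sub, d)
    states_list[[sx]] <- data.frame(
      absence_id = sub$absence_id, idx = sub$idx,
      state = as.character(cls$state),
      turn_missing = cls$turn_missing, stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, states_list)
  states <- states[order(states$absence_id, states$idx), ]
  rownames(states) <- NULL
  list(states = states, delims = delims)
}

# traits stage: five responses plus structural covariates per absence.
stage_traits <- function(steps, states, birds, absences, tcfg) {
  steps$state <- states$state[match(paste(steps$absence_id, steps$idx),
                                    paste(states$absence_id, states$idx))]
  out <- list()
  for (i in seq_len(nrow(absences))) {
    a <- absences[i, ]
    b <- birds[birds$bird_id == a$bird_id & birds$season == a$season, ][1, ]
    st <- steps[steps$absence_id == a$absence_id, , drop = FALSE]
    dm <- departure_mass(b$deploy_mass_g, b$days_since_deployment,
                         tcfg$daily_loss)
    rec <- compute_traits(st, dm, b$return_mass_g, metadata = b)
    rec$wing_loading <- wing_loading(dm / 1000, b$wing_chord_m)
    rec$depart_time <- a$depart_time
    rec$absence_id <- a$absence_id
    out[[i]] <- rec
  }
  do.call(rbind, out)
}

# model stage: stage-1 age-function selection then stage-2 environment
# models for the configured trait, per sex.
stage_model <- function(traits, env, seasons, mcfg) {
  data <- prepare_covariates(traits, env, seasons)
  s1_rows <- list(); s2_rows <- list(); coef_rows <- list()
  n_excluded <- 0L
  for (sx in mcfg$sexes) {
    d <- data[data$sex == sx, , drop = FALSE]
    if (nrow(d) < 20) next
    specs1 <- enumerate_stage1_models(sx, trait = mcfg$trait)
    fits1 <- lapply(specs1, fit_lmm, data = d)
    rk1 <- rank_models(fits1, mcfg$delta_max)
    tab1 <- rk1$table; tab1$sex <- sx
    s1_rows[[sx]] <- tab1
    best_basis <- fits1[[rk1$best]]$spec$age_basis
    specs2 <- enumerate_stage2_models(best_basis, sex = sx,
                                      trait = mcfg$trait)
    fits2 <- lapply(specs2, fit_lmm, data = d)
    rk2 <- rank_models(fits2, mcfg$delta_max)
    tab2 <- rk2$table; tab2$sex <- sx
    s2_rows[[sx]] <- tab2
    bf <- fits2[[rk2$best]]
    cf <- bf$coefficients; cf$sex <- sx; cf$model <- format(bf$spec)
    cf$r2m <- bf$r2m; cf$r2c <- bf$r2c
    coef_rows[[sx]] <- cf
    n_excluded <- n_excluded + bf$n_excluded
  }
  empty_rank <- data.frame(model = character(0), k = numeric(0),
                           logLik = numeric(0), AICc = numeric(0),
                           delta = numeric(0), weight = numeric(0),
                           top = logical(0), sex = character(0))
  list(stage1 = if (length(s1_rows)) do.call(rbind, s1_rows) else empty_rank,
       stage2 = if (length(s2_rows)) do.call(rbind, s2_rows) else empty_rank,
       coefficients = if (length(coef_rows)) do.call(rbind, coef_rows) else
         data.frame(term = character(0), estimate = numeric(0)),
       n_excluded = n_excluded)
}

# spatial stage: searching locations by age group, pairwise BA +
# randomization, BH-FDR over the pairs, per sex.
stage_spatial <- function(steps, states, birds, colony, scfg, seed = 1L,
                          out_dir = NULL) {
  steps$state <- states$state[match(paste(steps$absence_id, steps$idx),
                                    paste(states$absence_id, states$idx))]
  bird_of <- sub("\\..*$", "", steps$absence_id)
  meta <- birds[match(bird_of, birds$bird_id), ]
  grp <- age_group(meta$age)
  n_age10 <- length(unique(bird_of[is.na(grp)]))
  rows <- list(); k <- 0L
  for (sx in scfg$sexes) {
    sel <- meta$sex == sx & !is.na(grp) & steps$state == "SEARCH"
    sub <- steps[sel, , drop = FALSE]
    if (!nrow(sub)) next
    pj <- project_local(sub$lon, sub$lat, colony)
    sub$x <- pj$x; sub$y <- pj$y
    gsub <- droplevels(grp[sel])
    tracks_by_group <- lapply(split(seq_len(nrow(sub)), gsub[drop = TRUE]),
                              function(ix) {
      lapply(split(ix, sub$absence_id[ix]), function(jx)
        list(x = sub$x[jx], y = sub$y[jx]))
    })
    sizes <- vapply(tracks_by_group, length, 1L)
    groups <- names(sizes)[sizes >= 2]
    npts <- vapply(tracks_by_group, function(g)
      sum(lengths(lapply(g, `[[`, "x"))), 1L)
    groups <- groups[npts[groups] >= 5]
    if (length(groups) < 2) next
    pairs <- t(utils::combn(groups, 2))
    pvals <- numeric(nrow(pairs)); bas <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      rt <- randomization_test(tracks_by_group, pairs[i, ],
                               n_perm = scfg$n_perm,
                               seed = seed + 7L * i, cell_m = scfg$cell_m)
      pvals[i] <- rt$p; bas[i] <- rt$ba_obs
    }
    rej <- bh_fdr(pvals, scfg$q)
    for (i in seq_len(nrow(pairs))) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        sex = sx, group1 = pairs[i, 1], group2 = pairs[i, 2],
        ba = bas[i], p = pvals[i], fdr_reject = rej[i],
        n_perm = scfg$n_perm, seed = seed + 7L * i,
        stringsAsFactors = FALSE)
    }
    if (!is.null(out_dir)) {
      for (g in groups) {
        ix <- which(gsub == g)
        ud <- estimate_ud(sub$x[ix], sub$y[ix], scfg$cell_m)
        write_ud_asc(ud, file.path(out_dir,
                                   sprintf("ud_%s_%s.asc", sx, g)))
      }
    }
  }
  list(overlaps = if (k) do.call(rbind, rows) else
    data.frame(sex = character(0), group1 = character(0),
               group2 = character(0), ba = numeric(0), p = numeric(0),
               fdr_reject = logical(0), n_perm = integer(0),
               seed = integer(0)),
    n_age10 = n_age10)
}

# report stage: short markdown summary of rankings and overlaps.
stage_report <- function(out_dir) {
  lines <- c("# Pipeline report", "")
  add_tab <- function(lines, title, file, n = 5) {
    path <- file.path(out_dir, file)
    if (!file.exists(path)) return(lines)
    x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(x) || !nrow(x)) return(lines)
    lines <- c(lines, paste("##", title), "", "```",
               utils::capture.output(print(utils::head(x, n))), "```", "")
    lines
  }
  lines <- add_tab(lines, "Stage 1 model ranking (head)",
                   "stage1_ranking.csv", 8)
  lines <- add_tab(lines, "Stage 2 model ranking (head)",
                   "stage2_ranking.csv", 8)
  lines <- add_tab(lines, "Top-model coefficients", "coefficients.csv", 12)
  lines <- add_tab(lines, "Spatial overlap", "overlap_results.csv", 12)
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(NULL)
}
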