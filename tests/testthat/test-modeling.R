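# Age bases, model enumeration, covariate prep, mixed-model fitting,
# AICc ranking.

test_that("age design columns follow the piecewise definitions", {
  expect_equal(unname(build_age_design(c(10, 17),
                                       age_basis("one_threshold", 12))),
               matrix(c(10, 12, 0, 5), 2), tolerance = 1e-12)
  expect_equal(unname(build_age_design(c(20, 6),
                                       age_basis("two_threshold", 7, 15))),
               matrix(c(7, 6, 8, 0, 5, 0), 2), tolerance = 1e-12)
  expect_equal(ncol(build_age_design(1:10, age_basis("null"))), 0L)
  expect_equal(unname(build_age_design(c(4, 9), age_basis("linear"))),
               matrix(c(4, 9), 2))
  # quadratic is centred; predictions span the uncentred polynomial
  q <- build_age_design(c(4, 12, 20), age_basis("quadratic"))
  expect_equal(q[, "age"], c(4, 12, 20) - 12)
  expect_equal(q[, "age2"], (c(4, 12, 20) - 12)^2)
  # continuity at thresholds: left and right limits agree
  eps <- 1e-8
  for (b in list(age_basis("one_threshold", 12),
                 age_basis("two_threshold", 7, 15))) {
    for (tt in c(b$t1, b$t2)) {
      lim <- build_age_design(c(4, tt - eps, tt + eps, 25), b,
                              center = 12)
      expect_equal(lim[2, ], lim[3, ], tolerance = 1e-6)
    }
  }
  expect_error(build_age_design(5:10, age_basis("one_threshold", 25)),
               "outside")
  expect_error(age_basis("two_threshold", 15, 7), "t1 < t2")
})

test_that("stage-1 enumeration matches the published candidate counts", {
  m <- enumerate_stage1_models("male")
  f <- enumerate_stage1_models("female")
  expect_length(m, 29)
  expect_length(f, 24)
  forms <- vapply(m, function(s) s$age_basis$form, character(1))
  expect_equal(sum(forms == "two_threshold"), 16)   # 4 early x 4 late
  expect_equal(sum(forms == "one_threshold"), 10)
  f_forms <- vapply(f, function(s) s$age_basis$form, character(1))
  expect_equal(sum(f_forms == "two_threshold"), 12)  # 3 early x 4 late
  expect_true(all(vapply(m, function(s) s$season && s$wing_loading,
                         logical(1))))
})

test_that("stage-2 enumeration: 14 with age, 8 without, Date+Logger always", {
  s_age <- enumerate_stage2_models(age_basis("quadratic"))
  s_null <- enumerate_stage2_models(age_basis("null"))
  expect_length(s_age, 14)
  expect_length(s_null, 8)
  expect_true(all(!vapply(s_null, function(s) s$interaction, logical(1))))
  expect_true(all(vapply(s_age, function(s) s$stage == 2 && !s$season,
                         logical(1))))
  expect_error(enumerate_stage2_models(age_basis("null"),
                                       predictors = character(0)),
               "empty")
})

test_that("AICc, weights, and the asymptotic correction", {
  expect_equal(aicc(-100, 5, 50), 210 + 60 / 44, tolerance = 1e-9)
  expect_equal(akaike_weights(c(0, 2)), c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(sum(akaike_weights(runif(7, 0, 10))), 1, tolerance = 1e-9)
  expect_lt(aicc(-100, 5, 1e6) - (-2 * -100 + 2 * 5), 1e-3)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("covariate preparation: z-scores, residual SST, bins", {
  sh <- shared_sim()
  delims <- list(male = reference_delimiters("male_paper"),
                 female = reference_delimiters("female_paper"))
  tt <- build_trait_table(sh$ds$fixes, sh$ds$birds, delims, sh$cfg$colony)
  pc <- prepare_covariates(tt, sh$ds$env, sh$cfg$seasons)
  expect_equal(mean(pc$date_z), 0, tolerance = 1e-9)
  expect_equal(sd(pc$date_z), 1, tolerance = 1e-9)
  expect_equal(mean(pc$wing_loading_z), 0, tolerance = 1e-9)
  expect_equal(pc$depart_group, pc$depart_day %/% 10)
  expect_true(all(pc$cloud_mean >= 0 & pc$cloud_mean <= 1))
  # matched SST reflects the season regimes (warm season > cool season)
  warm <- sh$cfg$seasons$season[which.max(sh$cfg$seasons$sst_offset)]
  expect_gt(mean(pc$sst_matched[pc$season == warm]),
            mean(pc$sst_matched[pc$season != warm]))

  # SST exactly linear in day: residual SST is identically zero
  env_lin <- sh$ds$env
  env_lin$sst$sst <- 20 + 0.05 * env_lin$sst$day
  pc_lin <- prepare_covariates(tt, env_lin, sh$cfg$seasons)
  expect_lt(max(abs(pc_lin$sst_resid)), 1e-9)

  # bin rule on raw days
  expect_equal(c(3, 12) %/% 10, c(0, 1))
})

test_that("profiled ML reduces to OLS when random variances vanish", {
  set.seed(91)
  n <- 120
  d <- data.frame(
    bird_id = rep(sprintf("b%02d", 1:30), 4),
    depart_group = rep(1:6, 20),
    season = "S1", logger = rep(c("GT120", "GT600"), n / 2),
    age = sample(c(4:9, 11:25), n, TRUE),
    date_z = rnorm(n), wing_loading_z = rnorm(n),
    sst_resid = rnorm(n), mbd_z = rnorm(n), cloud_mean = runif(n))
  d$mass_gain_g <- 100 + 5 * d$date_z - 3 * d$wing_loading_z + rnorm(n, 0, 4)
  spec <- model_spec(1, "female", "mass_gain_g", age_basis("null"))
  fit <- fit_lmm(spec, d)
  ols <- lm(mass_gain_g ~ logger + date_z + wing_loading_z, data = d)
  expect_equal(unname(fit$coefficients$estimate[
    match(c("date_z", "wing_loading_z"), fit$coefficients$term)]),
    unname(coef(ols)[c("date_z", "wing_loading_z")]), tolerance = 1e-5)
  expect_true(fit$boundary)
  expect_equal(fit$k, 4 + 3)      # intercept + logger + 2 slopes, + 3
})

test_that("profiled ML agrees with the lme4 oracle", {
  skip_if_not_installed("lme4")
  cfg <- sim_config()
  d <- trait_layer_data(cfg, n = 300, seed = 17)
  d <- d[d$sex == "female", ]
  specs <- list(
    model_spec(1, "female", "absence_duration_h", age_basis("quadratic")),
    model_spec(1, "female", "absence_duration_h",
               age_basis("two_threshold", 7, 15)),
    model_spec(2, "female", "absence_duration_h", age_basis("linear"),
               season = FALSE, env = "sst", interaction = TRUE))
  for (sp in specs) {
    f1 <- fit_lmm(sp, d)
    f2 <- fit_lmm(sp, d, engine = "lmer")
    expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
    expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
                 tolerance = 1e-4)
    expect_equal(f1$coefficients$se, f2$coefficients$se,
                 tolerance = 1e-3)
    expect_equal(unname(f1$varcomp), unname(f2$varcomp), tolerance = 1e-3)
  }
})

test_that("stage-2 age restriction and interaction columns", {
  cfg <- sim_config()
  d <- trait_layer_data(cfg, n = 300, seed = 23)
  d <- d[d$sex == "female", ]
  sp <- model_spec(2, "female", "absence_duration_h",
                   age_basis("one_threshold", 12),
                   season = FALSE, env = "sst", interaction = TRUE)
  fit <- fit_lmm(sp, d)
  expect_equal(fit$n, sum(d$age >= 5 & d$age <= 22))
  expect_true(all(c("age_seg1_x_sst", "age_seg2_x_sst") %in%
                    fit$coefficients$term))
})

test_that("singular designs are rejected with the aliased columns named", {
  cfg <- sim_config()
  d <- trait_layer_data(cfg, n = 200, seed = 29)
  d$sst_resid <- d$date_z    # duplicate predictor
  sp <- model_spec(2, "female", "absence_duration_h", age_basis("null"),
                   season = FALSE, env = "sst")
  expect_warning(
    expect_error(fit_lmm(sp, d[d$sex == "female", ]), "aliased.*sst"),
    "collinear")
  expect_error(suppressWarnings(fit_lmm(sp, d[1:5, ])), "at least 10")

  # collinearity screen warns short of singularity
  d2 <- d
  set.seed(30)
  d2$sst_resid <- d2$date_z + rnorm(nrow(d2), 0, 0.3)
  expect_warning(fit_lmm(sp, d2[d2$sex == "female", ]), "collinear")
})

test_that("ranking: weights, nested-model pruning, comparability guard", {
  # synthetic fit results with controlled AICc and nesting structure
  mk_fit <- function(ll, p, X) {
    n <- nrow(X)
    k <- p + 3
    structure(list(spec = model_spec(1, "m", "t", age_basis("null")),
                   logLik = ll, k = k, n = n, aicc = aicc(ll, k, n),
                   X = X), class = "fit_result")
  }
  set.seed(3)
  X1 <- cbind(1, rnorm(100))
  X2 <- cbind(X1, rnorm(100))
  # choose logLiks so AICc(simple) = lower, complex within delta 2
  f_simple <- mk_fit(-50, 2, X1)
  gain <- (f_simple$aicc + 1.5 - 2 * (2 + 3 + 1) -
             2 * (2 + 3 + 1) * (2 + 3 + 2) / (100 - 2 - 3 - 2)) / -2
  f_complex <- mk_fit(gain, 3, X2)
  expect_equal(f_complex$aicc - f_simple$aicc, 1.5, tolerance = 1e-9)
  rk <- rank_models(list(f_simple, f_complex))
  expect_identical(rk$top, c(TRUE, FALSE))   # pruned despite delta < 2
  expect_equal(sum(rk$table$weight), 1, tolerance = 1e-9)

  # non-nested model with delta < 2 stays in the top set
  X3 <- cbind(1, rnorm(100))
  f_other <- mk_fit(f_simple$logLik - 0.5, 2, X3)
  rk3 <- rank_models(list(f_simple, f_other))
  expect_identical(rk3$top, c(TRUE, TRUE))

  f_bad_n <- mk_fit(-50, 2, X1[1:50, ])
  expect_error(rank_models(list(f_simple, f_bad_n)), "differing n")
})

test_that("marginal and conditional R-squared", {
  fake <- structure(list(var_fixed = 0,
                         varcomp = c(id = 1, depart_group = 0,
                                     residual = 1)),
                    class = "fit_result")
  r2 <- r2_nakagawa(fake)
  expect_equal(unname(r2), c(0, 0.5))
  fake0 <- fake; fake0$varcomp[] <- 0
  expect_error(r2_nakagawa(fake0), "zero total variance")
  # on a real fit: R2m <= R2c always
  cfg <- sim_config()
  d <- trait_layer_data(cfg, n = 200, seed = 31)
  fit <- fit_lmm(model_spec(1, "female", "absence_duration_h",
                            age_basis("linear")),
                 d[d$sex == "female", ])
  expect_lte(fit$r2m, fit$r2c)
  expect_equal(unname(r2_nakagawa(fit)), c(fit$r2m, fit$r2c),
               tolerance = 1e-12)
})

test_that("age-by-SST interaction is recoverable at realistic effect size", {
  # trait on the log scale with a positive late-segment interaction of
  # the order of the published 0.009; 10 replicates at n = 300
  hits <- 0
  for (r in 1:10) {
    set.seed(400 + r)
    n <- 300
    d <- data.frame(
      bird_id = rep(sprintf("b%03d", 1:150), 2),
      depart_group = sample(0:5, n, TRUE),
      season = "S1", logger = sample(c("A", "B"), n, TRUE),
      age = sample(c(5:9, 11:22), n, TRUE),
      date_z = rnorm(n), wing_loading_z = rnorm(n),
      sst_resid = rnorm(n, 0, 1.2), mbd_z = 0, cloud_mean = 0.5)
    seg2 <- pmax(d$age - 12, 0)
    eta <- 2.3 - 0.013 * seg2 + 0.02 * d$sst_resid +
      0.025 * seg2 * d$sst_resid +
      rep(rnorm(150, 0, 0.05), 2) + rnorm(n, 0, 0.08)
    d$mass_gain_per_h <- exp(eta)
    sp <- model_spec(2, "female", "mass_gain_per_h",
                     age_basis("one_threshold", 12),
                     season = FALSE, env = "sst", interaction = TRUE)
    fit <- fit_lmm(sp, d)
    co <- fit$coefficients
    row <- co[co$term == "age_seg2_x_sst", ]
    hits <- hits + (row$ci_lo > 0)
  }
  expect_gte(hits, 8)
})
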