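# Mixed-model fitting: crossed random intercepts (bird identity and
# 10-day departure window), maximum likelihood (fixed-effect structures
# are compared, so ML rather than REML), Wald confidence intervals.
#
# The default engine profiles the ML deviance over the two relative
# random-effect SDs (gamma_id, gamma_dg), solving the penalized normal
# equations by dense Cholesky with crossproducts precomputed once per
# design; an lme4 engine is retained for cross-checking.

# Profiled ML deviance machinery ------------------------------------------

# Precompute crossproducts for a design (y, X, Z1, Z2).
.pml_setup <- function(y, X, id, dg) {
  Z1 <- stats::model.matrix(~ 0 + id)
  Z2 <- stats::model.matrix(~ 0 + dg)
  Z <- cbind(Z1, Z2)
  q1 <- ncol(Z1); q2 <- ncol(Z2)
  list(y = y, X = X, q1 = q1, q2 = q2, n = length(y), p = ncol(X),
       CZZ = crossprod(Z), CZX = crossprod(Z, X), CXX = crossprod(X),
       czy = crossprod(Z, y), cxy = crossprod(X, y), yy = sum(y^2))
}

# Deviance (-2 logLik) profiled over beta and sigma^2 at relative SDs g.
.pml_dev <- function(g, S, details = FALSE) {
  d <- c(rep(g[1], S$q1), rep(g[2], S$q2))
  q <- S$q1 + S$q2
  M <- rbind(cbind(S$CZZ * outer(d, d) + diag(q), d * S$CZX),
             cbind(t(d * S$CZX), S$CXX))
  cc <- c(d * S$czy, S$cxy)
  L <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(L)) return(if (details) NULL else 1e10)
  w <- backsolve(L, forwardsolve(t(L), cc))
  rss <- max(S$yy - sum(cc * w), 1e-12)
  logdet <- 2 * sum(log(diag(L)[seq_len(q)]))
  dev <- logdet + S$n * (1 + log(2 * pi * rss / S$n))
  if (!details) return(dev)
  Minv <- chol2inv(L)
  sigma2 <- rss / S$n
  bidx <- q + seq_len(S$p)
  list(dev = dev, beta = w[bidx], sigma2 = sigma2,
       vcov_beta = sigma2 * Minv[bidx, bidx, drop = FALSE],
       v_id = g[1]^2 * sigma2, v_dg = g[2]^2 * sigma2)
}

# Fit by profiled ML: optimize the two relative SDs (bounded at 0).
.pml_fit <- function(y, X, id, dg) {
  S <- .pml_setup(y, X, id, dg)
  obj <- function(g) .pml_dev(g, S)
  best <- stats::optim(c(1, 1), obj, method = "L-BFGS-B",
                       lower = c(0, 0), upper = c(1e3, 1e3))
  det <- .pml_dev(best$par, S, details = TRUE)
  names(det$beta) <- colnames(X)
  det$logLik <- -best$value / 2
  det$gamma <- best$par
  det$boundary <- any(best$par < 1e-4)
  det
}

# Build response, fixed design matrix and grouping factors for a spec.
# Returns NULL-able list; stage-2 specs with an age basis restrict ages
# to 5-22 (edge ages are sparsely sampled across seasons).
build_model_frame <- function(spec, data) {
  tr <- transform_response(spec$trait, data[[spec$trait]])
  rows <- data[tr$keep, , drop = FALSE]
  y <- tr$values
  if (spec$stage == 2 && spec$age_basis$form != "null") {
    ok <- rows$age >= 5 & rows$age <= 22
    rows <- rows[ok, , drop = FALSE]
    y <- y[ok]
  }
  parts <- list()
  if (spec$season && length(unique(rows$season)) > 1)
    parts$season <- factor(rows$season)
  parts$date_z <- rows$date_z
  if (length(unique(rows$logger)) > 1)   # single-logger data: no contrast
    parts$logger <- factor(rows$logger)
  if (spec$wing_loading) parts$wing_loading_z <- rows$wing_loading_z
  age_X <- build_age_design(rows$age, spec$age_basis)
  for (j in seq_len(ncol(age_X))) parts[[colnames(age_X)[j]]] <- age_X[, j]
  env_col <- switch(spec$env, none = NULL, sst = rows$sst_resid,
                    mbd = rows$mbd_z, cloud = rows$cloud_mean)
  # collinearity screen over the base predictors (derived age columns of
  # one basis are intentionally correlated and excluded from the screen)
  base_cols <- Filter(Negate(is.null),
                      list(date = rows$date_z,
                           wing_loading = if (spec$wing_loading)
                             rows$wing_loading_z,
                           env = env_col))
  if (length(base_cols) > 1) {
    cm <- stats::cor(do.call(cbind, base_cols))
    cm[upper.tri(cm, diag = TRUE)] <- 0
    if (any(abs(cm) > 0.7)) {
      bad <- which(abs(cm) > 0.7, arr.ind = TRUE)[1, ]
      warning("collinear fixed predictors (|r| > 0.7): ",
              names(base_cols)[bad[2]], " and ", names(base_cols)[bad[1]])
    }
  }
  if (!is.null(env_col)) {
    parts[[spec$env]] <- env_col
    if (spec$interaction) {
      for (j in seq_len(ncol(age_X))) {
        parts[[paste0(colnames(age_X)[j], "_x_", spec$env)]] <-
          age_X[, j] * env_col
      }
    }
  }
  df <- as.data.frame(parts, optional = TRUE)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(names(parts), collapse = " + "))),
    df)
  list(y = y, X = X,
       id = factor(rows$bird_id), dg = factor(rows$depart_group),
       n_excluded = tr$n_excluded)
}

#' Fit a linear mixed model for one model specification
#'
#' Fits `response ~ fixed effects + (1 | bird) + (1 | departure window)`
#' by maximum likelihood with `lme4`, returning log-likelihood, AICc
#' bookkeeping inputs, coefficient estimates with Wald 95% CIs, variance
#' components, and marginal/conditional R-squared inputs. The parameter
#' count is structural: number of fixed-effect columns plus three (two
#' random-intercept variances and the residual). Variance components
#' estimated at the boundary (zero) are retained and flagged.
#'
#' @param spec A [model_spec()].
#' @param data Analysis table from [prepare_covariates()], with `bird_id`
#'   and `depart_group` columns.
#' @param engine `"profile"` (built-in profiled ML, default) or `"lmer"`
#'   (fit via lme4; used for cross-validation of the profiled fitter).
#' @return A `fit_result` list: `spec`, `logLik`, `k`, `n`, `aicc`,
#'   `coefficients` (data frame: term, estimate, se, ci_lo, ci_hi),
#'   `varcomp` (id, depart_group, residual variances), `var_fixed`,
#'   `r2m`, `r2c`, `boundary`, `n_excluded`, `X` (fixed design matrix).
#' @export
fit_lmm <- function(spec, data, engine = c("profile", "lmer")) {
  engine <- match.arg(engine)
  mf <- build_model_frame(spec, data)
  n <- length(mf$y)
  if (n < 10) stop("need at least 10 observations, got ", n)
  qrX <- qr(mf$X)
  if (qrX$rank < ncol(mf$X)) {
    aliased <- colnames(mf$X)[qrX$pivot[(qrX$rank + 1):ncol(mf$X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  if (engine == "profile") {
    pf <- .pml_fit(mf$y, mf$X, mf$id, mf$dg)
    beta <- pf$beta
    se <- sqrt(diag(pf$vcov_beta))
    v_id <- pf$v_id; v_dg <- pf$v_dg; v_res <- pf$sigma2
    ll <- pf$logLik
    boundary <- pf$boundary
  } else {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("engine 'lmer' requires the lme4 package")
    df <- as.data.frame(mf$X[, -1, drop = FALSE])
    names(df) <- make.names(colnames(mf$X)[-1], unique = TRUE)
    fixed_terms <- names(df)
    df$.y <- mf$y; df$.id <- mf$id; df$.dg <- mf$dg
    form <- stats::as.formula(paste(
      ".y ~", paste(c("1", fixed_terms), collapse = " + "),
      "+ (1 | .id) + (1 | .dg)"))
    ctrl <- lme4::lmerControl(
      check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
      check.conv.singular = "ignore", calc.derivs = FALSE)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df, REML = FALSE, control = ctrl)))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_id <- vc$vcov[vc$grp == ".id"]
    v_dg <- vc$vcov[vc$grp == ".dg"]
    v_res <- vc$vcov[vc$grp == "Residual"]
    ll <- as.numeric(stats::logLik(fit))
    boundary <- lme4::isSingular(fit)
  }
  k <- length(beta) + 3L
  var_f <- stats::var(as.numeric(mf$X %*% beta))
  denom <- var_f + v_id + v_dg + v_res
  res <- list(
    spec = spec, logLik = ll, k = k, n = n,
    aicc = aicc(ll, k, n),
    coefficients = data.frame(
      term = names(beta), estimate = unname(beta), se = se,
      ci_lo = unname(beta) - 1.96 * se, ci_hi = unname(beta) + 1.96 * se,
      stringsAsFactors = FALSE),
    varcomp = c(id = v_id, depart_group = v_dg, residual = v_res),
    var_fixed = var_f,
    r2m = var_f / denom,
    r2c = (var_f + v_id + v_dg) / denom,
    boundary = boundary,
    n_excluded = mf$n_excluded,
    X = mf$X)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s\n  logLik %.2f, k %d, n %d, AICc %.2f, R2m %.3f, R2c %.3f%s\n",
              format(x$spec), x$logLik, x$k, x$n, x$aicc, x$r2m, x$r2c,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param logLik Maximised log-likelihood.
#' @param k Parameter count.
#' @param n Sample size (must exceed `k + 1`).
#' @return AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc differences
#'
#' @param delta Vector of AICc differences from the minimum.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Nakagawa marginal and conditional R-squared
#'
#' `R2m` is the fixed-effect variance over the total (fixed + both random
#' intercepts + residual); `R2c` additionally credits the random
#' intercepts.
#'
#' @param fit A `fit_result`.
#' @return Named vector `c(r2m, r2c)`.
#' @export
r2_nakagawa <- function(fit) {
  v <- fit$varcomp
  denom <- fit$var_fixed + sum(v)
  if (denom <= 0) stop("zero total variance")
  c(r2m = fit$var_fixed / denom,
    r2c = (fit$var_fixed + v[["id"]] + v[["depart_group"]]) / denom)
}

# Is fit `a` (fixed part) nested in fit `b`? True when every column of
# a's design lies in the span of b's design (numeric projection test).
is_nested_fit <- function(a, b) {
  if (a$k >= b$k) return(FALSE)
  if (nrow(a$X) != nrow(b$X)) return(FALSE)
  proj <- stats::lm.fit(b$X, a$X)
  scale <- pmax(colSums(a$X^2), 1e-12)
  all(colSums(as.matrix(proj$residuals)^2) / scale < 1e-8)
}

#' Rank fitted models by AICc with the top-model-set rule
#'
#' Computes AICc differences and Akaike weights over the candidate set,
#' then marks the top model set: models within `delta_max` (default 2) of
#' the best, excluding any model that merely adds parameters to a nested
#' model with a lower AICc. Coefficients are never averaged across
#' models.
#'
#' @param fits List of `fit_result` objects fitted to the same rows.
#' @param delta_max Top-set cutoff (AICc units).
#' @return A list: `table` (data frame: model, k, logLik, AICc, delta,
#'   weight, top), `order` (indices into `fits`, best first), `top`
#'   (logical, aligned with `fits`), `best` (index of the top model).
#' @export
rank_models <- function(fits, delta_max = 2) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("fits have differing n; likelihoods are not comparable")
  ac <- vapply(fits, function(f) f$aicc, numeric(1))
  delta <- ac - min(ac)
  w <- akaike_weights(delta)
  top <- delta <= delta_max
  for (i in which(top)) {
    for (j in seq_along(fits)) {
      if (i == j || ac[j] >= ac[i]) next
      if (is_nested_fit(fits[[j]], fits[[i]])) { top[i] <- FALSE; break }
    }
  }
  tab <- data.frame(
    model = vapply(fits, function(f) format(f$spec), character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = ac, delta = delta, weight = w, top = top,
    stringsAsFactors = FALSE)
  ord <- order(ac)
  list(table = tab[ord, ], order = ord, top = top, best = ord[1])
}
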