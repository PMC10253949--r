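# Four-state behavioural annotation from speed and turning angle.
#
# Each variable is split into "low" and "high" by a two-component 1-D
# Gaussian mixture fitted by EM; the delimiter is the point between the
# component means where posterior membership is 0.5. The four states are
# the Cartesian product of the two dichotomies. This is a deliberate
# univariate simplification of bivariate binary clustering; published
# delimiters can be supplied directly instead of fitting.

#' Reference delimiters
#'
#' Named delimiter sets shipped with the package so classification can run
#' without fitting: published splits of 5.8 m/s and 0.74 rad for males and
#' 7.12 m/s and 0.34 rad for females.
#'
#' @param name `"male_paper"` or `"female_paper"`.
#' @return A `delimiters` object (see [fit_delimiters()]).
#' @export
reference_delimiters <- function(name = c("male_paper", "female_paper")) {
  name <- match.arg(name)
  val <- switch(name,
                male_paper = c(speed = 5.8, turn = 0.74),
                female_paper = c(speed = 7.12, turn = 0.34))
  structure(list(speed_split = unname(val["speed"]),
                 turn_split = unname(val["turn"]),
                 sex = sub("_paper$", "", name),
                 provenance = "configured"),
            class = "delimiters")
}

#' Construct a delimiters object
#' @param speed_split Speed split, m/s (> 0).
#' @param turn_split Turn split, rad (> 0, <= pi).
#' @param sex Sex label the delimiters apply to.
#' @param provenance `"fitted"` or `"configured"`.
#' @return A `delimiters` object.
#' @export
delimiters <- function(speed_split, turn_split, sex = NA_character_,
                       provenance = "configured") {
  if (speed_split <= 0) stop("speed_split must be > 0")
  if (turn_split <= 0 || turn_split > pi)
    stop("turn_split must be in (0, pi]")
  structure(list(speed_split = speed_split, turn_split = turn_split,
                 sex = sex, provenance = provenance),
            class = "delimiters")
}

#' @export
print.delimiters <- function(x, ...) {
  cat(sprintf("delimiters (%s, %s): speed %.3f m/s, turn %.3f rad\n",
              x$sex, x$provenance, x$speed_split, x$turn_split))
  invisible(x)
}

# One EM run for a two-component 1-D Gaussian mixture from given start.
.em_1d_run <- function(x, mu, sigma, lambda, tol = 1e-8, max_iter = 500) {
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- lambda * stats::dnorm(x, mu[1], sigma[1])
    d2 <- (1 - lambda) * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      return(list(mu = mu, sigma = sigma, lambda = lambda, loglik = ll,
                  converged = TRUE, iter = it))
    }
    ll_old <- ll
    n1 <- sum(g)
    lambda <- n1 / length(x)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / (length(x) - n1))
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                    sum((1 - g) * (x - mu[2])^2) / (length(x) - n1)))
    sigma <- pmax(sigma, 1e-6)
  }
  list(mu = mu, sigma = sigma, lambda = lambda, loglik = ll_old,
       converged = FALSE, iter = max_iter)
}

# Posterior-0.5 crossing of a fitted two-component mixture, searched
# between the component means by 1-D root finding.
mixture_crossing <- function(mu, sigma, lambda) {
  o <- order(mu)
  mu <- mu[o]; sigma <- sigma[o]
  lam <- if (o[1] == 1) lambda else 1 - lambda
  f <- function(x) lam * stats::dnorm(x, mu[1], sigma[1]) -
    (1 - lam) * stats::dnorm(x, mu[2], sigma[2])
  lo <- mu[1]; hi <- mu[2]
  if (f(lo) * f(hi) > 0) return(mean(mu))  # no sign change: fall back
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Two-component EM split of one variable: returns the 0.5-posterior
# delimiter. k-means initialisation with restarts.
fit_binary_split <- function(x, seed = 1L, restarts = 10, tol = 1e-8,
                             max_iter = 500, var_name = "variable") {
  x <- x[is.finite(x)]
  if (length(x) < 200)
    stop("need at least 200 ", var_name, " values to fit a split")
  if (stats::sd(x) < 1e-8)
    stop("degenerate ", var_name, " data: no variance to split")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- suppressWarnings(stats::kmeans(x, centers = 2, nstart = 1))
    mu <- as.numeric(km$centers)
    sigma <- vapply(1:2, function(k) {
      s <- stats::sd(x[km$cluster == k])
      if (!is.finite(s) || s < 1e-6) stats::sd(x) / 10 else s
    }, numeric(1))
    lambda <- mean(km$cluster == 1)
    fit <- .em_1d_run(x, mu, sigma, lambda, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # degenerate single-cluster data: the two-component fit must beat a
  # single Gaussian by its BIC penalty (3 extra parameters), otherwise
  # there is no second cluster to delimit
  ll1 <- sum(stats::dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)),
                          log = TRUE))
  if (2 * (best$loglik - ll1) < 3 * log(length(x)) ||
      abs(diff(best$mu)) < 0.05 * stats::sd(x))
    stop("degenerate ", var_name,
         " clustering: no support for two components")
  if (!best$converged)
    stop("EM did not converge for ", var_name, " after ", max_iter,
         " iterations")
  mixture_crossing(best$mu, best$sigma, best$lambda)
}

#' Fit speed and turning-angle delimiters by binary EM clustering
#'
#' Fits, per variable, a two-component Gaussian mixture (EM, k-means
#' initialisation, 10 restarts, tolerance 1e-8 on the log-likelihood, 500
#' iteration cap) and takes the point between the component means where
#' posterior membership is 0.5 as the delimiter.
#'
#' @param steps Step data frame with `speed_ms` and `turn_rad`, pooled
#'   within one sex.
#' @param sex Sex label carried on the result.
#' @param seed Integer seed (k-means restarts).
#' @return A `delimiters` object with provenance `"fitted"`.
#' @export
fit_delimiters <- function(steps, sex = NA_character_, seed = 1L) {
  sp <- fit_binary_split(steps$speed_ms, seed = seed, var_name = "speed")
  tu <- fit_binary_split(steps$turn_rad, seed = seed + 1L,
                         var_name = "turning angle")
  delimiters(speed_split = sp, turn_split = tu, sex = sex,
             provenance = "fitted")
}

#' Classify steps into the four behavioural states
#'
#' A step below the speed split is "low speed", at or above the turn split
#' "high turn"; values exactly equal to a split fall on the low side. The
#' four combinations map to REST (low/low), COMMUTE (high/low), RELOCATE
#' (high/high) and SEARCH (low/high). Steps with missing turning angle
#' (track endpoints) are labelled by speed alone into REST or COMMUTE and
#' flagged.
#'
#' @param steps Step data frame with `speed_ms`, `turn_rad`.
#' @param delims A `delimiters` object.
#' @return A data frame with `state` (factor over the four labels) and
#'   `turn_missing` (logical).
#' @export
classify_states <- function(steps, delims) {
  if (!inherits(delims, "delimiters")) stop("delims must be delimiters")
  low_speed <- steps$speed_ms <= delims$speed_split
  high_turn <- steps$turn_rad > delims$turn_split
  miss <- is.na(steps$turn_rad)
  high_turn[miss] <- FALSE
  state <- ifelse(low_speed,
                  ifelse(high_turn, "SEARCH", "REST"),
                  ifelse(high_turn, "RELOCATE", "COMMUTE"))
  data.frame(state = factor(state, levels = STATE_LEVELS),
             turn_missing = miss)
}
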