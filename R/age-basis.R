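# Age-function bases: null, linear, quadratic, and continuous piecewise
# (segment-slope) threshold parameterizations.

#' Construct an age basis
#'
#' @param form One of `"null"`, `"linear"`, `"quadratic"`,
#'   `"one_threshold"`, `"two_threshold"`.
#' @param t1,t2 Threshold ages (years); `t1 < t2` for two thresholds.
#' @return An `age_basis` object.
#' @export
age_basis <- function(form = c("null", "linear", "quadratic",
                               "one_threshold", "two_threshold"),
                      t1 = NULL, t2 = NULL) {
  form <- match.arg(form)
  if (form == "one_threshold" && is.null(t1))
    stop("one_threshold needs t1")
  if (form == "two_threshold") {
    if (is.null(t1) || is.null(t2)) stop("two_threshold needs t1 and t2")
    if (t1 >= t2) stop("thresholds must satisfy t1 < t2")
  }
  structure(list(form = form, t1 = t1, t2 = t2), class = "age_basis")
}

#' @export
format.age_basis <- function(x, ...) {
  switch(x$form,
         null = "null",
         linear = "linear",
         quadratic = "quadratic",
         one_threshold = sprintf("one_threshold(%g)", x$t1),
         two_threshold = sprintf("two_threshold(%g,%g)", x$t1, x$t2))
}

#' @export
print.age_basis <- function(x, ...) {
  cat("age basis:", format(x), "\n"); invisible(x)
}

#' Build design columns for an age basis
#'
#' Segment-slope parameterization for thresholds: one threshold T gives
#' columns `(min(Age, T), max(Age - T, 0))`; two thresholds (T1, T2) give
#' `(min(Age, T1), min(max(Age - T1, 0), T2 - T1), max(Age - T2, 0))`.
#' Each column's coefficient is then the within-segment slope and the
#' fitted curve is continuous at each threshold. The quadratic basis is
#' built on centred age to limit collinearity; threshold and linear
#' columns are returned raw (centring changes only the intercept).
#'
#' @param ages Numeric vector of ages.
#' @param basis An [age_basis()].
#' @param center Centre used for the quadratic basis (default mean of
#'   `ages`).
#' @return A numeric matrix with zero or more named columns.
#' @export
build_age_design <- function(ages, basis, center = NULL) {
  stopifnot(inherits(basis, "age_basis"))
  thr <- c(basis$t1, basis$t2)
  if (length(thr) && length(ages) > 1 &&
      (any(thr <= min(ages)) || any(thr >= max(ages))))
    stop("threshold outside the observed age range")
  switch(basis$form,
    null = matrix(numeric(0), nrow = length(ages), ncol = 0),
    linear = cbind(age = ages),
    quadratic = {
      ctr <- if (is.null(center)) mean(ages) else center
      a <- ages - ctr
      cbind(age = a, age2 = a^2)
    },
    one_threshold = cbind(age_seg1 = pmin(ages, basis$t1),
                          age_seg2 = pmax(ages - basis$t1, 0)),
    two_threshold = cbind(
      age_seg1 = pmin(ages, basis$t1),
      age_seg2 = pmin(pmax(ages - basis$t1, 0), basis$t2 - basis$t1),
      age_seg3 = pmax(ages - basis$t2, 0))
  )
}
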