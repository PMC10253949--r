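# Enumeration of the Stage-1 (age function) and Stage-2 (age-by-
# environment) candidate model sets.

# Sex-specific threshold grids: early-life thresholds at ages 6-8 for
# females and 7-10 for males, late-life thresholds at 14-17 for both;
# single-threshold models additionally consider ages 12 and 13.
stage1_threshold_grids <- function(sex) {
  early <- if (sex == "male") 7:10 else 6:8
  list(early = early, late = 14:17, single_extra = c(12, 13))
}

#' Enumerate Stage-1 age-function models
#'
#' Null, linear, quadratic, every two-threshold (early grid x late grid)
#' combination, and every single-threshold model (early grid, late grid,
#' plus ages 12 and 13). All specs carry the Stage-1 fixed covariates
#' (Season, Date, Logger, Wing Loading) and the two crossed random
#' intercepts. Yields 29 specs for males and 24 for females.
#'
#' @param sex `"male"` or `"female"`.
#' @param trait Response trait name carried on each spec.
#' @return A list of `model_spec` objects.
#' @export
enumerate_stage1_models <- function(sex = c("male", "female"),
                                    trait = "absence_duration_h") {
  sex <- match.arg(sex)
  g <- stage1_threshold_grids(sex)
  bases <- c(
    list(age_basis("null"), age_basis("linear"), age_basis("quadratic")),
    unlist(lapply(g$early, function(t1)
      lapply(g$late, function(t2) age_basis("two_threshold", t1, t2))),
      recursive = FALSE),
    lapply(sort(unique(c(g$early, g$late, g$single_extra))),
           function(t1) age_basis("one_threshold", t1))
  )
  lapply(bases, function(b)
    model_spec(stage = 1, sex = sex, trait = trait, age_basis = b,
               wing_loading = TRUE, season = TRUE,
               env = "none", interaction = FALSE))
}

#' Enumerate Stage-2 environmental models
#'
#' Each environmental predictor (SST, median breeding date, cloud cover)
#' is evaluated in separate models. The set crosses a shared base (Date +
#' Logger + the Stage-1 age basis) with presence/absence of Wing Loading,
#' then adds, per predictor E: E alone and E interacting with every age
#' column, each with and without Wing Loading. Season is dropped (the
#' environmental predictor replaces it). With a non-null age basis this
#' yields 2 + 3 x 4 = 14 specs; with a null basis interactions are
#' impossible and the set has 2 + 3 x 2 = 8.
#'
#' @param age_basis_from_stage1 The winning [age_basis()] from Stage 1.
#' @param sex,trait Carried onto each spec.
#' @param predictors Environmental predictors to evaluate.
#' @return A list of `model_spec` objects.
#' @export
enumerate_stage2_models <- function(age_basis_from_stage1,
                                    sex = "female",
                                    trait = "absence_duration_h",
                                    predictors = c("sst", "mbd", "cloud")) {
  if (length(predictors) == 0) stop("empty predictor set")
  has_age <- age_basis_from_stage1$form != "null"
  specs <- list()
  for (wl in c(FALSE, TRUE)) {
    specs[[length(specs) + 1L]] <-
      model_spec(stage = 2, sex = sex, trait = trait,
                 age_basis = age_basis_from_stage1, wing_loading = wl,
                 season = FALSE, env = "none", interaction = FALSE)
    for (e in predictors) {
      specs[[length(specs) + 1L]] <-
        model_spec(stage = 2, sex = sex, trait = trait,
                   age_basis = age_basis_from_stage1, wing_loading = wl,
                   season = FALSE, env = e, interaction = FALSE)
      if (has_age) {
        specs[[length(specs) + 1L]] <-
          model_spec(stage = 2, sex = sex, trait = trait,
                     age_basis = age_basis_from_stage1, wing_loading = wl,
                     season = FALSE, env = e, interaction = TRUE)
      }
    }
  }
  specs
}

#' Construct a model specification
#'
#' @param stage 1 or 2.
#' @param sex,trait Labels.
#' @param age_basis An [age_basis()].
#' @param wing_loading Include standardized wing loading?
#' @param season Include the breeding-season factor (Stage 1 only)?
#' @param env `"none"`, `"sst"`, `"mbd"` or `"cloud"`.
#' @param interaction Interact the environmental predictor with every age
#'   column?
#' @return A `model_spec` object.
#' @export
model_spec <- function(stage, sex, trait, age_basis, wing_loading = TRUE,
                       season = stage == 1, env = "none",
                       interaction = FALSE) {
  if (stage == 1 && env != "none")
    stop("Stage 1 models carry no environmental predictor")
  if (stage == 2 && season)
    stop("Stage 2 models replace Season with an environmental predictor")
  if (interaction && (env == "none" || age_basis$form == "null"))
    stop("interaction requires an environmental predictor and age columns")
  structure(list(stage = stage, sex = sex, trait = trait,
                 age_basis = age_basis, wing_loading = wing_loading,
                 season = season, env = env, interaction = interaction),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  parts <- c(sprintf("age=%s", format(x$age_basis)),
             if (x$season) "Season",
             "Date", "Logger",
             if (x$wing_loading) "WL",
             if (x$env != "none")
               paste0(toupper(x$env), if (x$interaction) "*Age"))
  sprintf("[stage %d, %s, %s] %s", x$stage, x$sex, x$trait,
          paste(parts, collapse = " + "))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}
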