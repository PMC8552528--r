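#' Convert gestational weeks + days to days
#'
#' Gestational age is handled in days throughout the package; the obstetric
#' notation w+d (w completed weeks plus d days) maps to `7 * w + d`, so week
#' 14+0 is day 98.
#'
#' @param weeks Completed gestational weeks.
#' @param days Additional days (0-6). Default 0.
#' @return Gestational age in days.
#' @examples
#' ga_days(14)      # 98
#' ga_days(40, 3)   # 283, the term / late-term boundary
#' @export
ga_days <- function(weeks, days = 0) {
  stopifnot(all(days >= 0 & days <= 6))
  as.numeric(7 * weeks + days)
}

# Boundaries used by the trimester labeller (days).
.GA_T2_START <- 98    # 14+0
.GA_T3_START <- 196   # 28+0
.GA_LATE_START <- 284 # first day beyond 40+3 (day 283)

#' Label gestational ages with trimester / late-term strata
#'
#' First trimester is below week 14+0 (day 98), second trimester covers weeks
#' 14+0 to 27+6 (days 98-195), third trimester weeks 28+0 to 40+3 (days
#' 196-283) and everything beyond day 283 is late term.
#'
#' @param ga Gestational age(s) in days.
#' @return Factor with levels `T1`, `T2`, `T3`, `late`.
#' @examples
#' ga_trimester(c(97, 98, 195, 196, 283, 284))
#' @export
ga_trimester <- function(ga) {
  stopifnot(is.numeric(ga))
  out <- rep(NA_character_, length(ga))
  out[ga < .GA_T2_START] <- "T1"
  out[ga >= .GA_T2_START & ga < .GA_T3_START] <- "T2"
  out[ga >= .GA_T3_START & ga < .GA_LATE_START] <- "T3"
  out[ga >= .GA_LATE_START] <- "late"
  factor(out, levels = c("T1", "T2", "T3", "late"))
}

#' Classify body mass index per WHO adult cut-offs
#'
#' Left-closed classes: normal weight 18.5-24.9, overweight 25.0-29.9,
#' obese >= 30.0 kg/m2. Values outside the study eligibility window
#' [18.5, 40) are still classified; eligibility is enforced by the cohort
#' accounting, not here.
#'
#' @param bmi Numeric BMI values (kg/m2).
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @export
bmi_class <- function(bmi) {
  stopifnot(is.numeric(bmi))
  out <- rep(NA_character_, length(bmi))
  out[bmi < 25] <- "normal"
  out[bmi >= 25 & bmi < 30] <- "overweight"
  out[bmi >= 30] <- "obese"
  factor(out, levels = c("normal", "overweight", "obese"))
}

# Derive stage-specific RNG seeds from a master seed so each sub-generator
# (cohort, concentrations, assay, outcomes) has its own reproducible stream.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(cohort = 101L, concentrations = 211L, assay = 307L,
               outcomes = 401L, analysis = 503L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Evaluate with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Small checked accessor for named lists used as configs.
cfg_get <- function(cfg, name, default) {
  if (!is.null(cfg[[name]])) cfg[[name]] else default
}
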