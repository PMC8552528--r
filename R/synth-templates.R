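# Trajectory templates: smooth per-cytokine gestational profiles on the
# natural-log concentration scale, realised as cubic B-spline curves with 4
# interior knots over gestational days 40-290. The four canonical shapes are
# parameterised by their control-point (knot-height) vectors; the B-spline
# variation-diminishing property guarantees the qualitative shape (monotone
# up / monotone down / interior peak / interior dip).

.TEMPLATE_GA_RANGE <- c(40, 290)
.TEMPLATE_INNER_KNOTS <- c(90, 140, 190, 240)

.SHAPE_COEFS <- list(
  increase = seq(0, 1, length.out = 8),
  decrease = seq(1, 0, length.out = 8),
  peak_mid = c(0, 0.40, 0.85, 1, 1, 0.85, 0.40, 0),
  dip_mid  = 1 - c(0, 0.40, 0.85, 1, 1, 0.85, 0.40, 0)
)

#' Default serum analyte panel
#'
#' The 22 cytokines retained by the quantification filter plus CRP. CRP is
#' carried in ug/mL, all cytokines in pg/mL; units are metadata and are never
#' converted.
#'
#' @return Data frame with columns `cytokine` and `unit`.
#' @export
default_panel <- function() {
  cyt <- c("eotaxin", "FGF-b", "G-CSF", "GM-CSF", "IP-10", "IL-1b", "IL-1Ra",
           "IL-2", "IL-4", "IL-6", "IL-7", "IL-8", "IL-9", "IL-12", "IL-13",
           "IL-15", "IL-17", "MCP-1", "MIP-1a", "MIP-1b", "PDGF-BB", "TNF-a")
  data.frame(
    cytokine = c(cyt, "CRP"),
    unit = c(rep("pg/mL", length(cyt)), "ug/mL"),
    stringsAsFactors = FALSE
  )
}

# Default shape assignment mirrors the four observed gestational patterns:
# chemokines and most regulatory analytes fall steadily, G-CSF/IL-13/FGF-b
# rise, CRP and IL-7 peak mid-pregnancy, and the classical inflammatory
# interleukins show a mid-pregnancy dip with a late surge.
.DEFAULT_SHAPES <- c(
  "eotaxin" = "decrease", "MCP-1" = "decrease", "MIP-1a" = "decrease",
  "MIP-1b" = "decrease", "PDGF-BB" = "decrease", "IL-1Ra" = "decrease",
  "IL-9" = "decrease", "IP-10" = "decrease", "IL-15" = "decrease",
  "TNF-a" = "decrease", "IL-12" = "decrease", "IL-4" = "decrease",
  "GM-CSF" = "decrease",
  "G-CSF" = "increase", "IL-13" = "increase", "FGF-b" = "increase",
  "CRP" = "peak_mid", "IL-7" = "peak_mid",
  "IL-1b" = "dip_mid", "IL-2" = "dip_mid", "IL-6" = "dip_mid",
  "IL-8" = "dip_mid", "IL-17" = "dip_mid"
)

#' Generate per-cytokine trajectory templates
#'
#' Assigns each analyte one of the four canonical gestational shapes
#' (documented defaults; eotaxin always decreases) with baseline level,
#' amplitude and variance components on the natural-log scale. Unknown
#' analytes receive a shape drawn reproducibly from the four.
#'
#' @param panel Character vector of analyte names (default: full panel).
#' @param seed Integer seed; templates are deterministic given the seed.
#' @param covariate_effects Optional covariate-effect table
#'   (see [default_covariate_effects()]); attached to the template set.
#' @return Object of class `trajectory_templates`: a data frame with one row
#'   per analyte (`cytokine`, `shape`, `baseline_log`, `amplitude_log`,
#'   `subject_sd`, `residual_sd`) plus a `covariate_effects` attribute.
#' @export
generate_trajectory_params <- function(panel = default_panel()$cytokine,
                                       seed = 1L,
                                       covariate_effects = default_covariate_effects()) {
  if (length(panel) < 1) stop("panel must be non-empty")
  if (anyDuplicated(panel)) stop("panel names must be unique")
  with_seed(derive_seed(seed, "concentrations"), {
    shape <- .DEFAULT_SHAPES[panel]
    miss <- is.na(shape)
    shape[miss] <- sample(names(.SHAPE_COEFS), sum(miss), replace = TRUE)
    # Baselines spread over a realistic serum range (~5-500 pg/mL);
    # eotaxin gets the largest amplitude, matching its pronounced decline.
    baseline <- stats::runif(length(panel), log(5), log(500))
    amplitude <- stats::runif(length(panel), 0.5, 1.0)
    amplitude[panel == "eotaxin"] <- 1.5
    out <- data.frame(
      cytokine = panel,
      shape = unname(shape),
      baseline_log = baseline,
      amplitude_log = amplitude,
      subject_sd = 0.40,
      residual_sd = 0.30,
      stringsAsFactors = FALSE
    )
  })
  attr(out, "covariate_effects") <- covariate_effects
  class(out) <- c("trajectory_templates", class(out))
  out
}

#' Evaluate a template shape curve
#'
#' Returns the noiseless mean log-concentration of a template at given
#' gestational ages: `baseline_log + amplitude_log * s(ga)` where `s` is the
#' shape's B-spline curve scaled to [0, 1]. Gestational ages are clamped to
#' the template support (days 40-290).
#'
#' @param template One row of a `trajectory_templates` frame (or a list with
#'   the same fields).
#' @param ga Gestational ages in days.
#' @return Numeric vector of mean log concentrations.
#' @export
evaluate_template <- function(template, ga) {
  shape_curve(template$shape, ga) * template$amplitude_log + template$baseline_log
}

#' Canonical shape curve on [0, 1]
#'
#' @param shape One of `"increase"`, `"decrease"`, `"peak_mid"`, `"dip_mid"`.
#' @param ga Gestational ages in days (clamped to 40-290).
#' @return Numeric vector in [0, 1].
#' @export
shape_curve <- function(shape, ga) {
  coefs <- .SHAPE_COEFS[[match.arg(shape, names(.SHAPE_COEFS))]]
  ga <- pmin(pmax(ga, .TEMPLATE_GA_RANGE[1]), .TEMPLATE_GA_RANGE[2])
  knots <- c(rep(.TEMPLATE_GA_RANGE[1], 4), .TEMPLATE_INNER_KNOTS,
             rep(.TEMPLATE_GA_RANGE[2], 4))
  basis <- splines::splineDesign(knots, ga, ord = 4)
  drop(basis %*% coefs)
}

#' Default covariate effect table
#'
#' Log-scale additive effects of maternal and fetal covariates on specific
#' analytes, each active over a gestational profile: `all` (every trimester),
#' `t1`, `t3`, or `t2t3`. The defaults encode the qualitative group
#' signatures the analysis is designed to detect: obesity raises most
#' acute-phase analytes in all trimesters (strongest CRP and IL-1Ra, with
#' overweight showing the same pattern at half strength), smoking raises
#' IL-12/IL-17/CRP, multiparity raises CRP and IL-6 in the first trimester
#' and lowers them in the third, a female fetus raises IL-9 in the first
#' trimester, and high birth weight raises IL-2 and FGF-b throughout while
#' low birth weight raises them from the second trimester.
#'
#' @return Data frame with columns `covariate`, `level`, `cytokine`,
#'   `effect_log`, `profile`.
#' @export
default_covariate_effects <- function() {
  rbind(
    data.frame(covariate = "bmi_class", level = "obese",
               cytokine = c("CRP", "IL-1Ra", "IL-6", "MCP-1"),
               effect_log = c(0.40, 0.35, 0.15, 0.15), profile = "all"),
    data.frame(covariate = "bmi_class", level = "overweight",
               cytokine = c("CRP", "IL-1Ra", "IL-6", "MCP-1"),
               effect_log = c(0.20, 0.18, 0.08, 0.08), profile = "all"),
    data.frame(covariate = "smoking", level = "TRUE",
               cytokine = c("IL-12", "IL-17", "CRP"),
               effect_log = c(0.25, 0.25, 0.20), profile = "all"),
    data.frame(covariate = "parous", level = "TRUE",
               cytokine = c("CRP", "IL-6"),
               effect_log = c(0.25, 0.20), profile = "t1"),
    data.frame(covariate = "parous", level = "TRUE",
               cytokine = c("CRP", "IL-6"),
               effect_log = c(-0.20, -0.15), profile = "t3"),
    data.frame(covariate = "fetal_sex", level = "female",
               cytokine = "IL-9", effect_log = 0.20, profile = "t1"),
    data.frame(covariate = "bw_group", level = "high",
               cytokine = c("IL-2", "FGF-b"),
               effect_log = c(0.20, 0.20), profile = "all"),
    data.frame(covariate = "bw_group", level = "low",
               cytokine = c("IL-2", "FGF-b"),
               effect_log = c(0.15, 0.15), profile = "t2t3")
  )
}

# Multiplier of an effect profile at a given gestational age.
.profile_weight <- function(profile, ga) {
  tri <- as.character(ga_trimester(ga))
  switch(profile,
    all = rep(1, length(ga)),
    t1 = as.numeric(tri == "T1"),
    t2 = as.numeric(tri == "T2"),
    t3 = as.numeric(tri %in% c("T3", "late")),
    t2t3 = as.numeric(tri %in% c("T2", "T3", "late")),
    stop("unknown effect profile: ", profile)
  )
}

#' Simulate true serum concentrations
#'
#' Draws per-sample, per-analyte true concentrations from the generative
#' model: log concentration = template mean at GA + covariate effects +
#' subject random intercept + residual, all on the natural-log scale.
#'
#' @param participants Participant table from [generate_cohort()].
#' @param samples Sample table from [generate_cohort()].
#' @param templates A `trajectory_templates` object.
#' @param seed Integer seed.
#' @return Long data frame: `sample_id`, `participant_id`, `cytokine`, `ga`,
#'   `true_conc`, `true_log_conc`.
#' @export
simulate_concentrations <- function(participants, samples, templates, seed = 1L) {
  stopifnot(all(samples$ga >= 30 & samples$ga <= 302))
  eff <- attr(templates, "covariate_effects")
  if (!is.null(eff)) {
    unknown <- setdiff(eff$cytokine, templates$cytokine)
    if (length(unknown) > 0) {
      stop("covariate effects reference unknown cytokine(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  cov_level <- function(p, covariate) {
    switch(covariate,
      bmi_class = as.character(p$bmi_class),
      smoking = as.character(p$smoking),
      parous = as.character(p$parity > 0),
      fetal_sex = as.character(p$fetal_sex),
      bw_group = as.character(p$bw_group),
      stop("unknown covariate in effect table: ", covariate)
    )
  }
  with_seed(derive_seed(seed, "concentrations") + 13L, {
    n_cyt <- nrow(templates)
    pid <- participants$id
    # subject random intercepts, one per participant per cytokine
    subj <- matrix(stats::rnorm(length(pid) * n_cyt), length(pid), n_cyt)
    rownames(subj) <- pid
    rows <- vector("list", n_cyt)
    p_of_sample <- participants[match(samples$participant_id, participants$id), ]
    for (k in seq_len(n_cyt)) {
      tmpl <- templates[k, ]
      mu <- evaluate_template(tmpl, samples$ga)
      if (!is.null(eff)) {
        eff_k <- eff[eff$cytokine == tmpl$cytokine, , drop = FALSE]
        for (r in seq_len(nrow(eff_k))) {
          lev <- cov_level(p_of_sample, eff_k$covariate[r])
          hit <- !is.na(lev) & lev == eff_k$level[r]
          if (any(hit)) {
            w <- .profile_weight(eff_k$profile[r], samples$ga[hit])
            mu[hit] <- mu[hit] + eff_k$effect_log[r] * w
          }
        }
      }
      log_conc <- mu +
        tmpl$subject_sd * subj[samples$participant_id, k] +
        tmpl$residual_sd * stats::rnorm(nrow(samples))
      rows[[k]] <- data.frame(
        sample_id = samples$sample_id,
        participant_id = samples$participant_id,
        cytokine = tmpl$cytokine,
        ga = samples$ga,
        true_log_conc = log_conc,
        true_conc = exp(log_conc),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
}
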