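# Synthetic multi-cohort pregnancy study: participants and serum samples.
# Five cohorts, four contributing the term study group (1-4 samples per woman
# spread over gestation on cohort-specific visit schedules) and one late-term
# cohort sampled once around gestational week 41+2 (day 289).

#' Default study design
#'
#' Marginal covariate prevalences follow the study population: 10% smokers,
#' 46% nulliparous, 42% female fetuses; 56% of women belong to the late-term
#' group (396/707). Term cohorts carry fixed visit schedules (gestational
#' days) used both for sampling-time generation and for the missing-GA
#' donor-group structure.
#'
#' @return Named list of design parameters, overridable entry-wise via
#'   [generate_cohort()]'s `config` argument.
#' @export
default_study_design <- function() {
  list(
    cohorts = c("C1", "C2", "C3", "C4", "C5"),
    late_cohort = "C5",
    prop_late = 396 / 707,
    term_cohort_shares = c(C1 = 0.30, C2 = 0.30, C3 = 0.25, C4 = 0.15),
    visit_schedule = list(
      C1 = c(77, 161, 245),
      C2 = c(91, 175, 259),
      C3 = c(70, 140, 210, 266),
      C4 = c(105, 189, 252)
    ),
    visit_jitter_sd = 7,
    visit_attend_prob = 0.8,
    smoking_prev = 0.10,
    nulliparous_prev = 0.46,
    female_prev = 0.42,
    age_mean = 30, age_sd = 4.5,
    bmi_mean = 24.6, bmi_sd = 3.8,
    ga_delivery_term_mean = 280.2, ga_delivery_term_sd = 8.8,
    late_sample_day = 289, late_sample_spread = 2,
    cesarean_prev_term = 0.08
  )
}

#' Synthetic birth-weight reference table
#'
#' A smooth population reference (synthetic, loosely shaped like Scandinavian
#' term birth-weight references) giving mean and SD of birth weight in grams
#' by gestational age at delivery and fetal sex. Used to convert weights to
#' z-scores and to generate weights in the simulator. The real national
#' reference values are deliberately not bundled; any table with the same
#' columns can be supplied wherever a `reference` argument is accepted.
#'
#' @return Data frame with columns `ga`, `sex`, `mean`, `sd`.
#' @export
synthetic_bw_reference <- function() {
  ga <- seq(259, 302, by = 7)
  # ~140 g/week growth flattening toward post-term; boys ~120 g heavier
  base <- 3250 + 20 * (ga - 259) - 0.12 * (ga - 259)^2
  rbind(
    data.frame(ga = ga, sex = "female", mean = base - 60, sd = 420),
    data.frame(ga = ga, sex = "male", mean = base + 60, sd = 440)
  )
}

#' Generate a synthetic study cohort
#'
#' Draws participants with covariates and their serum sampling times. Term
#' women receive 1-4 samples on their cohort's visit schedule (with jitter);
#' late-term women receive exactly one sample near gestational day 289
#' (week 41+2). Birth weights are drawn from the supplied reference given
#' gestational age at delivery and fetal sex; birth-weight percentile groups
#' (<25th, 25-75th, >75th) are derived from the implied z-scores.
#'
#' @param n_women Number of women (>= 2).
#' @param config Study design list; entries override [default_study_design()].
#' @param seed Integer seed.
#' @param bw_reference Birth-weight reference table
#'   (default [synthetic_bw_reference()]).
#' @return List with `participants` and `samples` data frames.
#' @export
generate_cohort <- function(n_women, config = list(), seed = 1L,
                            bw_reference = synthetic_bw_reference()) {
  if (n_women < 2) stop("n_women must be >= 2")
  cfg <- utils::modifyList(default_study_design(), config)
  for (p in c("smoking_prev", "nulliparous_prev", "female_prev", "prop_late",
              "visit_attend_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("prevalence out of [0, 1]: ", p)
    }
  }
  if (length(cfg$cohorts) == 0) stop("empty cohort list")
  with_seed(derive_seed(seed, "cohort"), {
    id <- sprintf("P%04d", seq_len(n_women))
    late <- stats::runif(n_women) < cfg$prop_late
    term_cohorts <- setdiff(cfg$cohorts, cfg$late_cohort)
    shares <- cfg$term_cohort_shares[term_cohorts]
    shares <- shares / sum(shares)
    cohort <- ifelse(
      late, cfg$late_cohort,
      sample(term_cohorts, n_women, replace = TRUE, prob = shares)
    )
    smoking <- stats::runif(n_women) < cfg$smoking_prev
    nulli <- stats::runif(n_women) < cfg$nulliparous_prev
    parity <- ifelse(nulli, 0L, 1L + stats::rpois(n_women, 0.5))
    fetal_sex <- ifelse(stats::runif(n_women) < cfg$female_prev,
                        "female", "male")
    age <- round(stats::rnorm(n_women, cfg$age_mean, cfg$age_sd), 1)
    bmi <- round(pmin(pmax(stats::rnorm(n_women, cfg$bmi_mean, cfg$bmi_sd),
                           18.5), 39.9), 1)
    ga_del <- ifelse(
      late,
      # provisional for late-term women; the labor-outcome generator
      # finalises delivery as sampling day + delay
      round(pmin(pmax(stats::rnorm(n_women, 291.7, 2.6), 285), 302)),
      round(pmin(pmax(stats::rnorm(n_women, cfg$ga_delivery_term_mean,
                                   cfg$ga_delivery_term_sd), 259), 302))
    )
    bw_z <- stats::rnorm(n_women)
    ref_mean <- mapply(function(g, s) .bw_ref_lookup(bw_reference, g, s)$mean,
                       ga_del, fetal_sex)
    ref_sd <- mapply(function(g, s) .bw_ref_lookup(bw_reference, g, s)$sd,
                     ga_del, fetal_sex)
    birth_weight <- round(ref_mean + bw_z * ref_sd)
    bw_group <- cut(stats::pnorm(bw_z), c(0, 0.25, 0.75, 1),
                    labels = c("low", "mid", "high"), include.lowest = TRUE)
    event <- ifelse(late, NA_character_,
                    ifelse(stats::runif(n_women) < cfg$cesarean_prev_term,
                           "cesarean", "spontaneous"))
    participants <- data.frame(
      id = id, cohort = cohort, age = age, bmi = bmi,
      bmi_class = bmi_class(bmi), smoking = smoking, parity = parity,
      fetal_sex = factor(fetal_sex, levels = c("female", "male")),
      birth_weight = birth_weight, bw_z = bw_z, bw_group = bw_group,
      ga_delivery = ga_del,
      study_group = factor(ifelse(late, "late_term", "term"),
                           levels = c("term", "late_term")),
      delivery_event = event,
      complication = FALSE, has_samples = TRUE,
      stringsAsFactors = FALSE
    )
    samples <- .draw_samples(participants, cfg)
    list(participants = participants, samples = samples)
  })
}

.bw_ref_lookup <- function(reference, ga, sex) {
  ref <- reference[reference$sex == sex, ]
  list(
    mean = stats::approx(ref$ga, ref$mean, xout = ga, rule = 2)$y,
    sd = stats::approx(ref$ga, ref$sd, xout = ga, rule = 2)$y
  )
}

.draw_samples <- function(participants, cfg) {
  rows <- list()
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    if (p$study_group == "late_term") {
      ga <- cfg$late_sample_day +
        sample(-cfg$late_sample_spread:cfg$late_sample_spread, 1)
      visits <- 1L
    } else {
      sched <- cfg$visit_schedule[[p$cohort]]
      attend <- stats::runif(length(sched)) < cfg$visit_attend_prob
      if (!any(attend)) attend[sample(length(sched), 1)] <- TRUE
      visits <- which(attend)
      ga <- round(sched[visits] + stats::rnorm(length(visits),
                                               0, cfg$visit_jitter_sd))
      ga <- pmin(pmax(ga, 40), 283)
      keep <- ga < p$ga_delivery
      if (!any(keep)) keep[1] <- TRUE
      ga <- ga[keep]
      visits <- visits[keep]
    }
    rows[[i]] <- data.frame(
      participant_id = p$id, visit = visits, ga = ga,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$sample_id <- sprintf("S%05d", seq_len(nrow(out)))
  out[, c("sample_id", "participant_id", "visit", "ga")]
}
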