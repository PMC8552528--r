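# Analyses specific to pregnancies beyond week 40+3: term vs late-term
# comparisons, Fine-Gray subdistribution hazards for time to spontaneous
# labor, covariate regressions and birth-weight z-scores.

#' Compare term and late-term cytokine levels
#'
#' Two-sided Mann-Whitney U tests (tie-corrected normal approximation) on log
#' concentrations between term samples (gestational days 259-283, weeks 37+0
#' to 40+3) and late-term samples (beyond day 283), per cytokine, with BH
#' correction across cytokines. Optionally excludes women delivering
#' (by any route) within `exclude_within_days` of sampling, removing the
#' immediate effect of approaching labor.
#'
#' @param panel Long panel (`cytokine`, `log_conc`, `ga`, `participant_id`).
#' @param outcomes Optional outcome table (`participant_id`,
#'   `days_to_delivery`) plus participant `ga_delivery` for term women; only
#'   needed when `exclude_within_days` is set.
#' @param participants Participant table with `ga_delivery` (used to compute
#'   sampling-to-delivery gaps for the exclusion).
#' @param exclude_within_days Optional integer; women with delivery within
#'   this many days of sampling are excluded before testing.
#' @return Data frame per cytokine: `n_term`, `n_late`, `median_term`,
#'   `median_late`, `statistic` (U), `p`, `p_adj`.
#' @export
compare_term_lateterm <- function(panel, participants = NULL,
                                  exclude_within_days = NULL) {
  d <- panel[panel$ga >= 259, ]
  d$group <- ifelse(d$ga > 283, "late", "term")
  if (!is.null(exclude_within_days)) {
    if (is.null(participants)) {
      stop("participants with ga_delivery required for the exclusion window")
    }
    del <- participants$ga_delivery[match(d$participant_id, participants$id)]
    gap <- del - d$ga
    d <- d[!is.na(gap) & gap > exclude_within_days, ]
  }
  if (length(unique(d$group)) < 2) {
    stop("a group was emptied; term-vs-late-term analysis aborted")
  }
  out <- lapply(unique(d$cytokine), function(ck) {
    sub <- d[d$cytokine == ck, ]
    x <- sub$log_conc[sub$group == "term"]
    y <- sub$log_conc[sub$group == "late"]
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    data.frame(cytokine = ck, n_term = length(x), n_late = length(y),
               median_term = stats::median(x), median_late = stats::median(y),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-cytokine Fine-Gray subdistribution hazards
#'
#' Univariate subdistribution-hazard regressions of time from sampling to
#' spontaneous labor on each normalized log cytokine. Event coding:
#' spontaneous labor is the event of interest; induction after randomization
#' (without prior spontaneous labor) is censoring; clinically indicated
#' induction — and cesarean, unless flagged as randomized — is a competing
#' event. Estimation uses the censoring-weighted partial likelihood of
#' cmprsk; hazard ratios are per 1 SD of log concentration when `z` is
#' standardized. P values are BH-adjusted across cytokines.
#'
#' @param outcomes Outcome table (`participant_id`, `days_to_delivery`,
#'   `event`).
#' @param z Numeric matrix participants x cytokines (rownames = participant
#'   ids) of normalized log concentrations.
#' @param gtol Newton convergence tolerance passed to the estimator.
#' @return Data frame per cytokine: `beta`, `hr`, `se`, `p`, `p_adj`,
#'   `converged`.
#' @export
fit_fine_gray <- function(outcomes, z, gtol = 1e-10) {
  ids <- intersect(outcomes$participant_id, rownames(z))
  oc <- outcomes[match(ids, outcomes$participant_id), ]
  zz <- z[ids, , drop = FALSE]
  status <- .fg_status(oc$event)
  if (sum(status == 1) < 10) stop("need >= 10 events of interest")
  rows <- lapply(colnames(zz), function(ck) {
    fit <- tryCatch(
      cmprsk::crr(ftime = oc$days_to_delivery, fstatus = status,
                  cov1 = matrix(zz[, ck], ncol = 1),
                  failcode = 1, cencode = 0, gtol = gtol),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$coef) || abs(fit$coef) > 20) {
      return(data.frame(cytokine = ck, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    se <- sqrt(diag(fit$var))
    data.frame(cytokine = ck, beta = unname(fit$coef),
               hr = exp(unname(fit$coef)), se = se,
               p = 2 * stats::pnorm(-abs(fit$coef / se)),
               converged = fit$converged %||% TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fg_status <- function(event) {
  st <- integer(length(event))
  st[event == "spontaneous"] <- 1L
  st[event %in% c("induced_clinical", "cesarean")] <- 2L
  st[event == "induced_randomized"] <- 0L
  st
}

#' Late-term covariate regressions
#'
#' Per cytokine, a linear model of z-score-normalized log concentration on
#' maternal age, BMI, parity and birth-weight z-score (continuous,
#' standardized so coefficients are comparable) and smoking and fetal sex
#' (categorical; non-smoking and female as references). BH correction over
#' the cytokine x covariate grid.
#'
#' @param panel Normalized late-term panel (`cytokine`, `value`,
#'   `participant_id`; one sample per woman).
#' @param participants Participant table with `age`, `bmi`, `parity`,
#'   `bw_z`, `smoking`, `fetal_sex`.
#' @return Data frame: `cytokine`, `covariate`, `estimate`, `se`, `p`,
#'   `p_adj`.
#' @export
lateterm_regressions <- function(panel, participants) {
  p <- participants[match(unique(panel$participant_id), participants$id), ]
  zs <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  covs <- data.frame(
    id = p$id,
    age = zs(p$age), bmi = zs(p$bmi), parity = zs(p$parity),
    bw_z = zs(p$bw_z),
    smoking = as.integer(p$smoking),
    fetal_sex_male = as.integer(p$fetal_sex == "male")
  )
  X <- as.matrix(covs[, -1])
  kap <- kappa(cbind(1, X), exact = FALSE)
  if (kap > 100) warning("covariate design poorly conditioned (kappa = ",
                         round(kap), ")")
  rows <- lapply(unique(panel$cytokine), function(ck) {
    sub <- panel[panel$cytokine == ck, ]
    y <- sub$value[match(covs$id, sub$participant_id)]
    fit <- stats::lm(y ~ age + bmi + parity + bw_z + smoking +
                       fetal_sex_male, data = covs)
    co <- summary(fit)$coefficients
    co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
    data.frame(cytokine = ck, covariate = rownames(co),
               estimate = co[, "Estimate"], se = co[, "Std. Error"],
               p = co[, "Pr(>|t|)"], stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Birth-weight z-score from a reference table
#'
#' `z = (weight - ref_mean(ga, sex)) / ref_sd(ga, sex)` with linear
#' interpolation between tabulated gestational ages; outside the reference
#' support the nearest endpoint is used and the value flagged.
#'
#' @param weight Birth weight in grams.
#' @param ga Gestational age at delivery, days.
#' @param sex `"female"` or `"male"`.
#' @param reference Reference table (`ga`, `sex`, `mean`, `sd`), e.g.
#'   [synthetic_bw_reference()].
#' @return List: `z`, `extrapolated` (logical).
#' @export
birthweight_zscore <- function(weight, ga, sex, reference = synthetic_bw_reference()) {
  ref <- reference[reference$sex == sex, ]
  if (nrow(ref) == 0) stop("no reference rows for sex ", sex)
  extrap <- ga < min(ref$ga) | ga > max(ref$ga)
  if (nrow(ref) == 1) {
    m <- rep(ref$mean, length(ga))
    s <- rep(ref$sd, length(ga))
  } else {
    m <- stats::approx(ref$ga, ref$mean, xout = ga, rule = 2)$y
    s <- stats::approx(ref$ga, ref$sd, xout = ga, rule = 2)$y
  }
  list(z = (weight - m) / s, extrapolated = extrap)
}
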