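# Panel-level operations: quantification-based exclusions, PCA outlier
# screening, cohort accounting, normalization schemes and covariate
# derivation.

#' Apply the panel quantification exclusion rule
#'
#' A cytokine is retained iff the fraction of its measurements outside
#' [LLOQ, ULOQ] is at most `threshold` (default 0.25): "more than 25%" out of
#' range excludes, exactly 25% retains. Records with `below_llod` or
#' `imputed_below_llod` status count as below LLOQ; `capped_ulod` as above
#' ULOQ.
#'
#' @param records Long ConcentrationRecord table (`cytokine`, `conc`,
#'   `status`).
#' @param curves Named list of `standard_curve` objects with limits.
#' @param threshold Maximum tolerated out-of-range fraction (default 0.25).
#' @return List: `retained` (cytokine names), `report` (per-cytokine
#'   fractions and decision).
#' @export
apply_panel_exclusions <- function(records, curves, threshold = 0.25) {
  report <- lapply(unique(records$cytokine), function(ck) {
    cur <- curves[[ck]]
    if (is.null(cur) || !is.finite(cur$lloq)) {
      stop("limits not populated for ", ck)
    }
    r <- records[records$cytokine == ck, ]
    below <- r$status %in% c("below_llod", "imputed_below_llod") |
      (!is.na(r$conc) & r$conc < cur$lloq)
    above <- r$status == "capped_ulod" | (!is.na(r$conc) & r$conc > cur$uloq)
    frac <- (sum(below) + sum(above & !below)) / nrow(r)
    data.frame(cytokine = ck, frac_below_lloq = sum(below) / nrow(r),
               frac_above_uloq = sum(above & !below) / nrow(r),
               frac_out_of_range = frac,
               retained = frac <= threshold,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, report)
  list(retained = report$cytokine[report$retained], report = report)
}

#' Screen participants for multivariate outliers
#'
#' Per cohort, PCA on the autoscaled log panel (one row per sample); a
#' participant is flagged when the robust Mahalanobis distance of any of
#' their samples on (PC1, PC2) exceeds the chi-square(2) quantile at
#' `level` (default 0.999). Flags are advisory: removal happens only through
#' an explicit removal list, mirroring a visual-inspection workflow.
#'
#' @param panel Long panel table (`participant_id`, `sample_id`, `cohort`,
#'   `cytokine`, `log_conc`).
#' @param level Chi-square quantile (default 0.999).
#' @param min_n Minimum participants per cohort to screen (default 10).
#' @return Data frame of flagged samples: `cohort`, `participant_id`,
#'   `sample_id`, `distance2`, `cutoff`.
#' @export
screen_outliers <- function(panel, level = 0.999, min_n = 10) {
  cutoff <- stats::qchisq(level, df = 2)
  flags <- list()
  for (ch in unique(panel$cohort)) {
    sub <- panel[panel$cohort == ch, ]
    wide <- stats::xtabs(log_conc ~ sample_id + cytokine, data = sub)
    wide <- matrix(wide, nrow(wide), ncol(wide), dimnames = dimnames(wide))
    if (length(unique(sub$participant_id)) < min_n) next
    sds <- apply(wide, 2, stats::sd)
    keep <- is.finite(sds) & sds > 1e-12
    if (sum(keep) < 2) next
    if (any(!keep)) {
      warning("constant cytokine column(s) dropped from outlier PCA in ",
              ch, ": ", paste(colnames(wide)[!keep], collapse = ", "))
    }
    x <- scale(wide[, keep, drop = FALSE])
    pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
    sc <- pc$x[, 1:2, drop = FALSE]
    rob <- MASS::cov.rob(sc)
    d2 <- stats::mahalanobis(sc, rob$center, rob$cov)
    hit <- d2 > cutoff
    if (any(hit)) {
      sid <- rownames(wide)[hit]
      pid <- sub$participant_id[match(sid, sub$sample_id)]
      flags[[length(flags) + 1]] <- data.frame(
        cohort = ch, participant_id = pid, sample_id = sid,
        distance2 = d2[hit], cutoff = cutoff, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(flags, list(NULL)))
  if (is.null(out)) {
    out <- data.frame(cohort = character(), participant_id = character(),
                      sample_id = character(), distance2 = numeric(),
                      cutoff = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Cohort accounting report
#'
#' Tallies the participant flow from assessment to inclusion. Exclusion
#' reasons are applied in a fixed priority order so no woman is counted
#' twice: pregnancy complications, then BMI below 18.5, then BMI at or above
#' 40, then missing serum samples; outlier removals (an explicit id list)
#' come last. Also reports the term / late-term split and per-trimester
#' sample counts with integer-rounded percentage shares.
#'
#' @param assessed Participant table with `id`, `complication` (logical),
#'   `bmi`, `has_samples` (logical), and `study_group` for included women.
#' @param outlier_removals Character vector of participant ids removed as
#'   outliers.
#' @param samples Optional sample table (`participant_id`, `ga`) for the
#'   trimester tally of included term-group samples.
#' @return Named list of counts; `final_included` = assessed - exclusions -
#'   outliers, and the categories always sum to `assessed`.
#' @export
cohort_accounting <- function(assessed, outlier_removals = character(0),
                              samples = NULL) {
  stopifnot(all(c("id", "complication", "bmi", "has_samples")
                %in% names(assessed)))
  n_assessed <- nrow(assessed)
  excl_compl <- assessed$complication
  excl_bmi_low <- !excl_compl & assessed$bmi < 18.5
  excl_bmi_high <- !excl_compl & !excl_bmi_low & assessed$bmi >= 40
  excl_missing <- !excl_compl & !excl_bmi_low & !excl_bmi_high &
    !assessed$has_samples
  eligible <- !(excl_compl | excl_bmi_low | excl_bmi_high | excl_missing)
  outlier <- eligible & assessed$id %in% outlier_removals
  included <- eligible & !outlier
  rep <- list(
    assessed = n_assessed,
    excluded_complications = sum(excl_compl),
    excluded_bmi_low = sum(excl_bmi_low),
    excluded_bmi_high = sum(excl_bmi_high),
    excluded_missing_samples = sum(excl_missing),
    outliers_removed = sum(outlier),
    final_included = sum(included)
  )
  if ("study_group" %in% names(assessed)) {
    rep$included_term <- sum(included & assessed$study_group == "term",
                             na.rm = TRUE)
    rep$included_late_term <- sum(included &
                                    assessed$study_group == "late_term",
                                  na.rm = TRUE)
  }
  if (!is.null(samples)) {
    keep <- samples$participant_id %in% assessed$id[included]
    tri <- ga_trimester(samples$ga[keep])
    term_tri <- tri[tri %in% c("T1", "T2", "T3")]
    counts <- table(factor(term_tri, levels = c("T1", "T2", "T3")))
    rep$samples_by_trimester <- as.list(as.integer(counts))
    names(rep$samples_by_trimester) <- c("T1", "T2", "T3")
    rep$samples_trimester_pct <- as.list(
      as.integer(round(100 * as.integer(counts) / sum(counts))))
    names(rep$samples_trimester_pct) <- c("T1", "T2", "T3")
    rep$samples_late_term <- sum(tri == "late")
  }
  rep
}

#' Normalize a cytokine panel
#'
#' Two schemes on log concentrations, per cytokine:
#' `"rmasca"` subtracts the overall mean (across cohorts) and divides by the
#' unweighted mean of the per-cohort standard deviations — not the pooled SD;
#' `"zscore"` is plain mean centering and division by the overall SD (used
#' for the late-term regressions). The constants are kept as metadata for the
#' inverse transform; zero-SD cytokines are flagged and left unscaled.
#'
#' @param panel Long panel table with `cytokine`, `log_conc` and (for
#'   `rmasca`) `cohort`.
#' @param scheme `"rmasca"` or `"zscore"`.
#' @return List: `panel` (with `value` = normalized log concentration),
#'   `metadata` (per-cytokine center and divisor), `flagged`.
#' @export
normalize_panel <- function(panel, scheme = c("rmasca", "zscore")) {
  scheme <- match.arg(scheme)
  panel$value <- NA_real_
  meta <- list(); flagged <- character(0)
  for (ck in unique(panel$cytokine)) {
    sel <- panel$cytokine == ck
    x <- panel$log_conc[sel]
    center <- mean(x, na.rm = TRUE)
    if (scheme == "rmasca") {
      sds <- tapply(x, panel$cohort[sel], stats::sd, na.rm = TRUE)
      sds <- sds[!is.na(sds)]
      divisor <- mean(sds)
    } else {
      divisor <- stats::sd(x, na.rm = TRUE)
    }
    if (!is.finite(divisor) || divisor < 1e-12) {
      flagged <- c(flagged, ck)
      panel$value[sel] <- x - center
      divisor <- NA_real_
    } else {
      panel$value[sel] <- (x - center) / divisor
    }
    meta[[ck]] <- data.frame(cytokine = ck, center = center,
                             divisor = divisor, scheme = scheme,
                             stringsAsFactors = FALSE)
  }
  list(panel = panel, metadata = do.call(rbind, meta), flagged = flagged)
}

#' Derive analysis covariates
#'
#' Adds BMI class (WHO cuts, left-closed), parity group (nulliparous vs
#' parous), birth-weight z-score and percentile group (<25th, 25th-75th,
#' >75th) from a reference table, and checks study eligibility (BMI in
#' [18.5, 40)). The trimester labeller for samples is [ga_trimester()].
#'
#' @param participants Participant table with `bmi`, `parity`,
#'   `birth_weight`, `ga_delivery`, `fetal_sex`.
#' @param bw_reference Reference table as in [synthetic_bw_reference()].
#' @return Participant table with `bmi_class`, `parous`, `bw_z`, `bw_group`,
#'   `bmi_eligible` columns (replacing any existing ones).
#' @export
derive_covariates <- function(participants, bw_reference = synthetic_bw_reference()) {
  p <- participants
  p$bmi_class <- bmi_class(p$bmi)
  p$parous <- p$parity > 0
  z <- mapply(function(w, g, s) birthweight_zscore(w, g, s, bw_reference)$z,
              p$birth_weight, p$ga_delivery, as.character(p$fetal_sex))
  p$bw_z <- as.numeric(z)
  p$bw_group <- cut(stats::pnorm(p$bw_z), c(0, 0.25, 0.75, 1),
                    labels = c("low", "mid", "high"), include.lowest = TRUE)
  p$bmi_eligible <- p$bmi >= 18.5 & p$bmi < 40
  p
}
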