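# Left-censored lognormal EM imputation for values below the detection
# limit, and donor-group mean substitution for missing gestational ages.

#' EM estimation for a left-censored lognormal sample
#'
#' Univariate EM on the log scale: with `m` observed logs and `n_cens` values
#' known only to lie below `log(llod)`, the E-step replaces each censored
#' value by the conditional moments of the normal truncated above at the
#' censoring point, and the M-step updates `(mu, sigma)`. Iterates to
#' `|d mu| + |d sigma| < tol` (default 1e-6) or `max_iter` (default 500).
#' Converges to the censored-data maximum-likelihood estimate.
#'
#' @param log_obs Observed (quantified) log values.
#' @param n_cens Number of censored values.
#' @param log_llod Log of the censoring limit.
#' @param tol,max_iter Convergence controls.
#' @return List: `mu`, `sigma`, `imputed_log` (conditional expectation, one
#'   value, strictly below `log_llod`), `iterations`, `converged`.
#' @export
em_censored_lognormal <- function(log_obs, n_cens, log_llod,
                                  tol = 1e-6, max_iter = 500) {
  m <- length(log_obs)
  if (m < 3) stop("need >= 3 quantified values")
  n <- m + n_cens
  mu <- mean(log_obs)
  sigma <- max(stats::sd(log_obs), 1e-3)
  if (n_cens == 0) {
    # ML variance (divisor n), consistent with the EM fixed point
    sigma_ml <- sqrt(mean((log_obs - mu)^2))
    return(list(mu = mu, sigma = sigma_ml, imputed_log = NA_real_,
                iterations = 0L, converged = TRUE))
  }
  L <- log_llod
  sum_y <- sum(log_obs)
  sum_y2 <- sum(log_obs^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a <- (L - mu) / sigma
    lam <- stats::dnorm(a) / pmax(stats::pnorm(a), 1e-300)
    e1 <- mu - sigma * lam                       # E[Y | Y < L]
    e2 <- mu^2 - 2 * mu * sigma * lam + sigma^2 * (1 - a * lam)  # E[Y^2 | Y < L]
    mu_new <- (sum_y + n_cens * e1) / n
    var_new <- (sum_y2 + n_cens * e2) / n - mu_new^2
    sigma_new <- sqrt(max(var_new, 1e-12))
    delta <- abs(mu_new - mu) + abs(sigma_new - sigma)
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  a <- (L - mu) / sigma
  imputed <- mu - sigma * stats::dnorm(a) / pmax(stats::pnorm(a), 1e-300)
  list(mu = mu, sigma = sigma, imputed_log = imputed,
       iterations = it, converged = converged)
}

#' Impute concentrations below LLOD
#'
#' Applies [em_censored_lognormal()] to the quantified values of one cytokine
#' and replaces every `below_llod` record by the conditional expectation
#' `exp(E[log X | X < llod])`, which is strictly below the limit. Refuses
#' (flagging the cytokine) when 80% or more of the records are censored.
#'
#' @param records ConcentrationRecord data frame for one cytokine (columns
#'   `conc`, `status`, `log_conc`).
#' @param llod Lower limit of detection on the concentration scale.
#' @return List: `records` (with `status = "imputed_below_llod"` rows
#'   filled), `fit` (the EM fit), `flagged` (TRUE if imputation refused).
#' @export
impute_below_llod <- function(records, llod) {
  cens <- records$status == "below_llod"
  quant <- records$status == "quantified"
  if (!any(cens)) {
    fit <- em_censored_lognormal(records$log_conc[quant], 0, log(llod))
    return(list(records = records, fit = fit, flagged = FALSE))
  }
  frac <- sum(cens) / (sum(cens) + sum(quant))
  if (frac >= 0.8) {
    return(list(records = records, fit = NULL, flagged = TRUE))
  }
  fit <- em_censored_lognormal(records$log_conc[quant], sum(cens), log(llod))
  records$conc[cens] <- exp(fit$imputed_log)
  records$log_conc[cens] <- fit$imputed_log
  records$status[cens] <- "imputed_below_llod"
  list(records = records, fit = fit, flagged = FALSE)
}

#' Fill missing gestational ages from cohort visit structure
#'
#' A sample lacking gestational age at sampling receives the mean observed
#' gestational age of samples from the same cohort and visit number; every
#' substitution is logged. Samples without any donor in their (cohort, visit)
#' group are dropped with a warning.
#'
#' @param samples Sample table (`sample_id`, `participant_id`, `visit`, `ga`).
#' @param participants Participant table (for the cohort of each sample).
#' @return List: `samples` (GA filled, unresolved rows removed), `log`
#'   (data frame of substitutions).
#' @export
impute_missing_ga <- function(samples, participants) {
  cohort_of <- stats::setNames(participants$cohort, participants$id)
  cohort <- unname(cohort_of[samples$participant_id])
  miss <- is.na(samples$ga)
  if (!any(miss)) {
    return(list(samples = samples,
                log = data.frame(sample_id = character(),
                                 cohort = character(), visit = integer(),
                                 ga_imputed = numeric())))
  }
  log_rows <- list()
  drop <- logical(nrow(samples))
  for (i in which(miss)) {
    donors <- !miss & cohort == cohort[i] & samples$visit == samples$visit[i]
    if (!any(donors)) {
      warning("no gestational-age donors for sample ", samples$sample_id[i],
              " (cohort ", cohort[i], ", visit ", samples$visit[i],
              "); sample dropped")
      drop[i] <- TRUE
      next
    }
    ga_hat <- mean(samples$ga[donors])
    samples$ga[i] <- ga_hat
    log_rows[[length(log_rows) + 1]] <- data.frame(
      sample_id = samples$sample_id[i], cohort = cohort[i],
      visit = samples$visit[i], ga_imputed = ga_hat,
      stringsAsFactors = FALSE
    )
  }
  list(samples = samples[!drop, ],
       log = do.call(rbind, c(log_rows, list(NULL))))
}
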