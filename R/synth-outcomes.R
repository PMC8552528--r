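# Late-term labor outcomes: a generative twin of the subdistribution-hazard
# analysis. Spontaneous labor (the event of interest) follows a Fine-Gray
# model with configurable per-cytokine log subdistribution hazard ratios;
# induction after randomization acts as censoring and clinically indicated
# induction as a competing event.

#' Default labor-outcome configuration
#'
#' Women are randomized 1:1 at sampling (about week 41+2) to early induction
#' (1-2 days later; reaching induction without spontaneous labor is recorded
#' as `induced_randomized` and treated as censoring downstream) or to
#' monitoring, where clinically indicated induction (competing event,
#' `induced_clinical`) occurs at about 8 days, capped by a policy induction
#' 11 days after sampling (about week 42+6). The spontaneous-labor
#' subdistribution has baseline probability `p0 = 0.8` and a gamma baseline
#' delay distribution; the generator rescales delays so that the empirical
#' mean sampling-to-delivery delay among observed spontaneous labors matches
#' `mean_delay` (default 3.4 days, SD of the baseline 2.5 days).
#'
#' @return Named list of outcome-generator parameters.
#' @export
default_outcome_config <- function() {
  list(
    p0 = 0.8,
    mean_delay = 3.4,
    sd_delay = 2.5,
    rand_prob = 0.5,
    induction_arm_delay = c(1, 2),
    clinical_mean = 8,
    clinical_shape = 4,
    policy_cap = 11,
    calibrate_mean = TRUE
  )
}

#' Simulate late-term labor outcomes
#'
#' Draws days from serum sampling to delivery for late-term participants from
#' a Fine-Gray subdistribution model: the probability of spontaneous labor is
#' `1 - (1 - p0)^exp(eta)` with `eta = Z %*% beta`, and conditional event
#' times invert the subdistribution CIF with a gamma baseline. Covariates
#' enter through `association`, a named vector of log subdistribution hazard
#' ratios per column of `z`; an empty map gives the all-null model.
#'
#' @param late_participants Data frame with at least `id` (one row per
#'   late-term woman).
#' @param z Numeric matrix (participants x covariates) of normalized
#'   cytokine values, rownames = participant ids. May be NULL when
#'   `association` is empty.
#' @param association Named numeric vector of log-HRs (names must be columns
#'   of `z`); empty for the null model.
#' @param config Outcome configuration ([default_outcome_config()]).
#' @param seed Integer seed.
#' @return Data frame: `participant_id`, `days_to_delivery`, `event`
#'   (`spontaneous`, `induced_randomized`, `induced_clinical`), `arm`.
#' @export
simulate_labor_outcomes <- function(late_participants, z = NULL,
                                    association = numeric(0),
                                    config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_outcome_config(), config)
  n <- nrow(late_participants)
  if (length(association) > 0) {
    if (is.null(z)) stop("z matrix required when association is non-empty")
    miss <- setdiff(names(association), colnames(z))
    if (length(miss) > 0) stop("association names not in z: ",
                               paste(miss, collapse = ", "))
    zi <- z[late_participants$id, names(association), drop = FALSE]
    eta <- drop(zi %*% association)
  } else {
    eta <- rep(0, n)
  }
  shape <- (cfg$mean_delay / cfg$sd_delay)^2
  scale0 <- cfg$mean_delay / shape
  with_seed(derive_seed(seed, "outcomes"), {
    p_event <- 1 - (1 - cfg$p0)^exp(eta)
    u_cause <- stats::runif(n)
    is_cause1 <- u_cause < p_event
    # conditional cause-1 time: invert F(t | cause 1) in closed form
    u_t <- stats::runif(n)
    gt <- (1 - (1 - u_t * p_event)^exp(-eta)) / cfg$p0
    t1_latent <- stats::qgamma(pmin(pmax(gt, 1e-12), 1 - 1e-12),
                               shape = shape, scale = scale0)
    arm <- ifelse(stats::runif(n) < cfg$rand_prob, "induction", "monitoring")
    ind_delay <- sample(cfg$induction_arm_delay, n, replace = TRUE)
    clin_time <- pmin(stats::rgamma(n, shape = cfg$clinical_shape,
                                    scale = cfg$clinical_mean / cfg$clinical_shape),
                      cfg$policy_cap)

    resolve <- function(s) {
      t1 <- t1_latent * s
      days <- numeric(n)
      event <- character(n)
      for (i in seq_len(n)) {
        if (arm[i] == "induction") {
          if (is_cause1[i] && t1[i] < ind_delay[i]) {
            days[i] <- t1[i]; event[i] <- "spontaneous"
          } else {
            days[i] <- ind_delay[i]; event[i] <- "induced_randomized"
          }
        } else {
          if (is_cause1[i] && t1[i] < cfg$policy_cap) {
            days[i] <- t1[i]; event[i] <- "spontaneous"
          } else if (is_cause1[i]) {
            days[i] <- cfg$policy_cap; event[i] <- "induced_clinical"
          } else {
            days[i] <- clin_time[i]; event[i] <- "induced_clinical"
          }
        }
      }
      list(days = days, event = event)
    }

    s <- 1
    res <- resolve(s)
    if (isTRUE(cfg$calibrate_mean)) {
      for (it in 1:5) {
        sp <- res$event == "spontaneous"
        if (sum(sp) < 5) break
        m <- mean(res$days[sp])
        if (m <= 0) break
        s <- s * cfg$mean_delay / m
        res <- resolve(s)
      }
    }
    if (any(res$days < 0)) stop("internal error: negative time to delivery")
    data.frame(
      participant_id = late_participants$id,
      days_to_delivery = res$days,
      event = res$event,
      arm = arm,
      stringsAsFactors = FALSE
    )
  })
}
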