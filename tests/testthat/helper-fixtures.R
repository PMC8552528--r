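# Fixture builders shared across test files. Everything is generated in code
# at test time; fixtures are small and deterministic under the given seed.

# Per-cytokine trajectory slice: pure noise or a known smooth signal.
mk_slice <- function(n_women = 100, seed = 1, signal = NULL, sd = 1,
                     samples_per_woman = 1:3) {
  set.seed(seed)
  pid <- sprintf("P%04d", seq_len(n_women))
  ns <- sample(samples_per_woman, n_women, replace = TRUE)
  d <- do.call(rbind, lapply(seq_len(n_women), function(i) data.frame(
    participant_id = pid[i],
    cohort = sample(c("A", "B"), 1),
    ga = round(runif(ns[i], 50, 280)),
    stringsAsFactors = FALSE
  )))
  d$conc <- rnorm(nrow(d), 10, sd)
  if (!is.null(signal)) d$conc <- d$conc + signal(d$ga)
  d
}

# Long normalized panel on a 3-timepoint design with optional group factor,
# subject intercepts and injected cell means.
mk_rmasca_panel <- function(n = 60, cyt = paste0("V", seq_len(5)),
                            beta_t = NULL, group_effect = NULL,
                            re_sd = 0.3, noise = 0.3, seed = 1,
                            groups = c("g0", "g1")) {
  set.seed(seed)
  if (is.null(beta_t)) beta_t <- matrix(rnorm(3 * length(cyt)), 3)
  rows <- vector("list", n * 3 * length(cyt))
  idx <- 0
  grp_of <- rep(groups, length.out = n)
  for (i in seq_len(n)) {
    u <- rnorm(length(cyt), 0, re_sd)
    for (t in 1:3) {
      for (k in seq_along(cyt)) {
        idx <- idx + 1
        g_add <- if (!is.null(group_effect) && grp_of[i] != groups[1]) {
          group_effect[t, k]
        } else 0
        rows[[idx]] <- data.frame(
          participant_id = sprintf("P%03d", i),
          trimester = c("T1", "T2", "T3")[t],
          grp = grp_of[i], cytokine = cyt[k],
          value = beta_t[t, k] + g_add + u[k] + rnorm(1, 0, noise),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Two-group long panel for the term vs late-term comparison.
mk_mw_panel <- function(x_term, y_late, cytokine = "A") {
  rbind(
    data.frame(participant_id = paste0("T", seq_along(x_term)),
               sample_id = paste0("ST", seq_along(x_term)),
               cytokine = cytokine, log_conc = x_term, ga = 270),
    data.frame(participant_id = paste0("L", seq_along(y_late)),
               sample_id = paste0("SL", seq_along(y_late)),
               cytokine = cytokine, log_conc = y_late, ga = 289)
  )
}

# A noiseless, artifact-free synthetic study in which the intra-lot anchor
# exchangeability assumption holds exactly (no visit jitter, no covariate
# effects, zero subject and residual variance).
mk_noiseless_sim <- function(n_women = 60, seed = 3) {
  tmpl <- generate_trajectory_params(seed = seed, covariate_effects = NULL)
  tmpl$subject_sd <- 0
  tmpl$residual_sd <- 0
  coh <- generate_cohort(n_women, seed = seed,
                         config = list(visit_jitter_sd = 0,
                                       late_sample_spread = 0))
  truth <- simulate_concentrations(coh$participants, coh$samples, tmpl,
                                   seed = seed)
  acfg <- default_assay_config(tmpl, seed = seed)
  acfg$lot_offsets <- lapply(acfg$lot_offsets, function(v) v * 0)
  acfg$plate_offset_sd <- 0
  acfg$theta <- c(0, 1)
  assay <- simulate_assay_fi(truth, coh$samples, coh$participants, acfg,
                             seed = seed)
  list(templates = tmpl, participants = coh$participants,
       samples = coh$samples, truth = truth, assay = assay,
       assay_config = acfg, outcomes = NULL)
}

# A small study with lot/plate artifacts and noise switched on.
mk_noisy_sim <- function(n_women = 60, seed = 3) {
  tmpl <- generate_trajectory_params(seed = seed)
  coh <- generate_cohort(n_women, seed = seed)
  truth <- simulate_concentrations(coh$participants, coh$samples, tmpl,
                                   seed = seed)
  acfg <- default_assay_config(tmpl, seed = seed)
  assay <- simulate_assay_fi(truth, coh$samples, coh$participants, acfg,
                             seed = seed)
  list(templates = tmpl, participants = coh$participants,
       samples = coh$samples, truth = truth, assay = assay,
       assay_config = acfg, outcomes = NULL)
}

# Known 5PL truth with exact duplicate standards (optionally noisy).
mk_standards <- function(params = list(lower = 30, slope = 1.2,
                                       infl_log = 4.5, upper = 20000,
                                       asym = 1.3),
                         n_levels = 8, dilution = 4, n_plates = 1,
                         theta = c(0, 1), seed = 1) {
  set.seed(seed)
  top <- exp(params$infl_log + 3)
  conc <- top / dilution^(seq_len(n_levels) - 1)
  std <- do.call(rbind, lapply(seq_len(n_plates), function(pl) {
    cc <- rep(conc, each = 2)
    mu <- fivepl(cc, params)
    data.frame(conc = cc, fi = mu + rnorm(length(cc)) *
                 sqrt(theta[1] * mu^theta[2]),
               plate_id = sprintf("P%d", pl))
  }))
  list(standards = std, params = params, top = top)
}
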