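# Shared configuration for the analysis scripts. Each numbered script is a
# self-contained stage: rather than passing serialized state, stages that
# need upstream objects re-derive them through the deterministic generators
# (bit-identical under STUDY_SEED), which keeps every intermediate
# reproducible from this one file.

library(gestaflux)

STUDY_SEED <- 42L
STUDY_CONFIG <- validate_config(list(
  seed = STUDY_SEED,
  n_women = 300L,
  # injected subdistribution log-HRs (per SD of log concentration) so the
  # late-term stage has a known signal to recover: higher levels of these
  # analytes shorten time to spontaneous labor
  # (kept sparse: the univariate subdistribution fits are non-collapsible,
  # so spreading the same signal over many analytes attenuates each
  # marginal hazard ratio)
  outcomes = list(association = list("IL-6" = 0.50, "eotaxin" = 0.40))
))
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(file.path(RESULTS_DIR, "figures"), showWarnings = FALSE)

get_sim <- function() simulate_study(STUDY_CONFIG)

get_prep <- function(sim = get_sim()) preprocess_assay(sim, STUDY_CONFIG)

write_result <- function(x, name) {
  utils::write.csv(x, file.path(RESULTS_DIR, name), row.names = FALSE)
  message("wrote results/", name)
}
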