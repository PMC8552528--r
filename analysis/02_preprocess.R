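#!/usr/bin/env Rscript
# Stage 2 — raw fluorescence to analysis panel: plate (intra-lot) and
# bridge-sample (inter-lot) correction, per-cytokine 5PL calibration with
# power-variance limits, ULOD capping, censored-EM imputation below LLOD,
# the 25% quantification exclusion rule, advisory PCA outlier screening and
# cohort accounting.

source("analysis/00_config.R")

sim <- get_sim()
prep <- get_prep(sim)

message(sprintf("panel: %d records across %d retained cytokines (of %d assayed)",
                nrow(prep$panel), length(unique(prep$panel$cytokine)),
                nrow(prep$exclusions$report)))
excl <- prep$exclusions$report[!prep$exclusions$report$retained, ]
if (nrow(excl) > 0) {
  message("excluded by the quantification rule: ",
          paste(sprintf("%s (%.0f%%)", excl$cytokine,
                        100 * excl$frac_out_of_range), collapse = ", "))
} else {
  message("no cytokine exceeded 25% of measurements outside [LLOQ, ULOQ]")
}
message(sprintf("censored below LLOD and imputed: %d records",
                sum(prep$panel$status == "imputed_below_llod")))
message(sprintf("outlier screen flagged %d sample(s); removal is opt-in",
                nrow(prep$outlier_flags)))
message(sprintf("accounting: %d assessed, %d included (%d term / %d late term)",
                prep$accounting$assessed, prep$accounting$final_included,
                prep$accounting$included_term,
                prep$accounting$included_late_term))

write_result(prep$panel[, c("sample_id", "participant_id", "cytokine",
                            "conc", "status", "log_conc", "ga", "trimester",
                            "cohort")], "panel.csv")
write_result(prep$adjustments, "adjustments.csv")
write_result(prep$exclusions$report, "exclusions.csv")
write_result(prep$imputation_log, "imputation_log.csv")
jsonlite::write_json(prep$accounting,
                     file.path(RESULTS_DIR, "accounting.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote results/accounting.json")
curves <- lapply(prep$curves, function(cu) {
  c(list(cytokine = cu$cytokine), cu$params,
    list(theta0 = cu$theta[1], theta1 = cu$theta[2], llod = cu$llod,
         lloq = cu$lloq, uloq = cu$uloq, ulod = cu$ulod))
})
jsonlite::write_json(curves, file.path(RESULTS_DIR, "curves.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote results/curves.json")
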