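#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic multi-cohort pregnancy study: 300 women
# across five cohorts (four term cohorts with 1-4 serum samples on visit
# schedules, one late-term cohort sampled once around week 41+2), 22
# cytokines + CRP with four canonical gestational shapes, covariate effects,
# a two-lot multiplex assay with plate artifacts and power-law noise, and
# late-term labor outcomes with competing events.

source("analysis/00_config.R")

sim <- get_sim()

n_late <- sum(sim$participants$study_group == "late_term")
message(sprintf("simulated %d women (%d term, %d late term), %d serum samples",
                nrow(sim$participants), nrow(sim$participants) - n_late,
                n_late, nrow(sim$samples)))
tri <- table(ga_trimester(sim$samples$ga))
message(sprintf("samples by stratum: T1 %d, T2 %d, T3 %d, late %d",
                tri["T1"], tri["T2"], tri["T3"], tri["late"]))
message(sprintf("assay wells: %d samples + %d standards + %d blanks",
                nrow(sim$assay$fi_long), nrow(sim$assay$standards),
                nrow(sim$assay$blanks)))
sp <- sim$outcomes$event == "spontaneous"
message(sprintf("late-term outcomes: %d spontaneous (mean delay %.1f d), %d randomized-induction, %d clinical-induction",
                sum(sp), mean(sim$outcomes$days_to_delivery[sp]),
                sum(sim$outcomes$event == "induced_randomized"),
                sum(sim$outcomes$event == "induced_clinical")))

write_result(sim$participants, "participants.csv")
write_result(sim$samples, "samples.csv")
write_result(sim$assay$fi_long, "fi_long.csv")
write_result(sim$assay$bridge_manifest, "bridge_manifest.csv")
write_result(sim$assay$standards, "standards.csv")
write_result(sim$outcomes, "outcomes.csv")
dir.create(file.path(RESULTS_DIR, "truth"), showWarnings = FALSE)
utils::write.csv(sim$truth, file.path(RESULTS_DIR, "truth/concentrations.csv"),
                 row.names = FALSE)
message("wrote results/truth/concentrations.csv")
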