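#!/usr/bin/env Rscript
# Stage 5 — analyses beyond week 40+3: term vs late-term Mann-Whitney
# comparisons (with and without the 4-day delivery exclusion window),
# per-cytokine Fine-Gray subdistribution hazards for time to spontaneous
# labor, O-PLS-DA prediction of spontaneous labor within four days with
# permutation testing, and late-term covariate regressions.

source("analysis/00_config.R")

sim <- get_sim()
prep <- get_prep(sim)
panel <- prep$panel

mw <- compare_term_lateterm(panel)
message(sprintf("term vs late term: %d of %d cytokines differ (BH p < 0.05)",
                sum(mw$p_adj < 0.05), nrow(mw)))
write_result(mw, "lateterm_tests.csv")
mw4 <- tryCatch(
  compare_term_lateterm(panel, sim$participants,
                        exclude_within_days =
                          STUDY_CONFIG$lateterm$exclude_within_days),
  error = function(e) { message("4-day window: ", conditionMessage(e)); NULL })
if (!is.null(mw4)) {
  message(sprintf("after excluding deliveries within 4 days: %d of %d differ",
                  sum(mw4$p_adj < 0.05), nrow(mw4)))
  write_result(mw4, "lateterm_tests_excl4d.csv")
}

late_panel <- panel[panel$trimester == "late", ]
norm <- normalize_panel(late_panel, "zscore")
z <- xtabs(value ~ participant_id + cytokine, data = norm$panel)
z <- matrix(z, nrow(z), ncol(z), dimnames = dimnames(z))

fg <- fit_fine_gray(sim$outcomes, z)
message(sprintf("Fine-Gray: %d cytokines with BH p < 0.05; HR range %.2f-%.2f per SD",
                sum(fg$p_adj < 0.05, na.rm = TRUE), min(fg$hr, na.rm = TRUE),
                max(fg$hr, na.rm = TRUE)))
write_result(fg, "finegray.csv")

oc <- sim$outcomes[match(rownames(z), sim$outcomes$participant_id), ]
y <- ifelse(oc$event == "spontaneous" & oc$days_to_delivery <= 4, 1L,
            ifelse(oc$days_to_delivery > 4, 0L, NA_integer_))
ok <- !is.na(y)
ev <- evaluate_and_permute(z[ok, , drop = FALSE], y[ok],
                           n_orth = STUDY_CONFIG$lateterm$n_orth,
                           n_perm = STUDY_CONFIG$lateterm$n_perm,
                           holdout = STUDY_CONFIG$lateterm$holdout,
                           seed = STUDY_SEED)
message(sprintf("O-PLS-DA (labor within 4 days, n=%d): holdout error %.0f%%, sensitivity %.0f%%, specificity %.0f%%, permutation p = %.3g",
                sum(ok), 100 * ev$error_rate, 100 * ev$sensitivity,
                100 * ev$specificity, ev$p_value))
fit <- fit_oplsda(z[ok, , drop = FALSE], y[ok],
                  n_orth = STUDY_CONFIG$lateterm$n_orth)
vip <- sort(fit$vip, decreasing = TRUE)
message("highest VIP: ",
        paste(sprintf("%s (%.2f)", names(vip)[1:5], vip[1:5]),
              collapse = ", "))
jsonlite::write_json(
  list(n = sum(ok), error_rate = ev$error_rate,
       sensitivity = ev$sensitivity, specificity = ev$specificity,
       permutation_p = ev$p_value, vip = as.list(fit$vip)),
  file.path(RESULTS_DIR, "oplsda.json"), auto_unbox = TRUE, digits = NA)
message("wrote results/oplsda.json")

reg <- lateterm_regressions(norm$panel, sim$participants)
message(sprintf("late-term regressions: %d of %d coefficients significant after BH",
                sum(reg$p_adj < 0.05), nrow(reg)))
write_result(reg, "regressions.csv")
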