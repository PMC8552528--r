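#!/usr/bin/env Rscript
# Stage 3 — gestational trajectories for the term study group: penalized
# cubic spline mixed models per cytokine, the 50 x 80% subsampling
# robustness screen, trimester contrasts against T1 with BH correction, and
# within-stratum Spearman correlation matrices.

source("analysis/00_config.R")
suppressMessages(library(ggplot2))

prep <- get_prep()
term_panel <- prep$panel[prep$panel$trimester != "late", ]

curves <- list(); robustness <- list()
for (ck in unique(term_panel$cytokine)) {
  slice <- term_panel[term_panel$cytokine == ck, ]
  fit <- tryCatch(suppressWarnings(fit_trajectory(slice)),
                  error = function(e) NULL)
  if (is.null(fit)) { message(ck, ": trajectory fit failed, skipped"); next }
  curves[[ck]] <- data.frame(cytokine = ck, ga = fit$grid,
                             mean = fit$mean_curve, lower = fit$lower,
                             upper = fit$upper)
  rb <- tryCatch(
    assess_robustness(slice,
                      n_runs = STUDY_CONFIG$trajectories$n_runs,
                      drop_frac = STUDY_CONFIG$trajectories$drop_frac,
                      seed = STUDY_SEED),
    error = function(e) NULL)
  if (!is.null(rb)) {
    robustness[[ck]] <- data.frame(cytokine = ck, mean_rho = rb$mean_rho,
                                   reliable = rb$reliable)
  }
}
curves <- do.call(rbind, curves)
robustness <- do.call(rbind, robustness)
message(sprintf("continuous trajectories: %d cytokines fitted, %d reliable (mean Spearman rho >= %.2f)",
                length(unique(curves$cytokine)), sum(robustness$reliable),
                STUDY_CONFIG$trajectories$reliability_threshold))
unrel <- robustness$cytokine[!robustness$reliable]
if (length(unrel) > 0) message("flagged unreliable: ",
                               paste(unrel, collapse = ", "))

trim_eff <- trimester_effects_panel(term_panel)
sig <- trim_eff[trim_eff$p_adj < 0.05, ]
message(sprintf("trimester contrasts vs T1: %d of %d significant after BH",
                nrow(sig), nrow(trim_eff)))

corrs <- correlations_by_trimester(prep$panel)
for (tri in names(corrs)) {
  write_result(as.data.frame(corrs[[tri]]$rho),
               sprintf("correlations_%s.csv", tri))
}
npos <- vapply(corrs, function(x) {
  sum(x$rho[upper.tri(x$rho)] > 0 & x$p_adj[upper.tri(x$p_adj)] < 0.05,
      na.rm = TRUE)
}, numeric(1))
message("significant positive correlations by stratum: ",
        paste(sprintf("%s=%d", names(npos), npos), collapse = ", "))

write_result(curves, "trajectories.csv")
write_result(robustness, "robustness.csv")
write_result(trim_eff, "trimester_effects.csv")

reliable_cyt <- robustness$cytokine[robustness$reliable]
pl <- ggplot(curves[curves$cytokine %in% reliable_cyt, ], aes(ga, mean)) +
  geom_ribbon(aes(ymin = lower, ymax = upper), alpha = 0.25) +
  geom_line() +
  facet_wrap(~cytokine, scales = "free_y") +
  labs(x = "Gestational age (days)", y = "Serum concentration",
       title = "Gestational trajectories (reliable cytokines)") +
  theme_minimal(base_size = 8)
ggsave(file.path(RESULTS_DIR, "figures", "trajectories.png"), pl,
       width = 10, height = 7, dpi = 150)
message("wrote results/figures/trajectories.png")
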