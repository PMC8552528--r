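#!/usr/bin/env Rscript
# Stage 4 — RM-ASCA+ of the term-group panel: rmasca normalization (overall
# mean centering, division by the unweighted mean of per-cohort SDs),
# per-cytokine LMMs, time and group+interaction effect matrices, PCA, and
# 7-fold jackknife percentile bands. The time-only analysis summarizes the
# shared gestational program; the BMI-class analysis shows how overweight
# and obese pregnancies deviate from normal-weight ones.

source("analysis/00_config.R")
suppressMessages(library(ggplot2))

prep <- get_prep()
term_panel <- prep$panel[prep$panel$trimester != "late", ]
term_panel$trimester <- droplevels(term_panel$trimester)
norm <- normalize_panel(term_panel, "rmasca")

## time-only decomposition with jackknife bands
spec_t <- rmasca_spec(group_var = NULL)
jk_t <- jackknife_validate(norm$panel, spec_t,
                           n_folds = STUDY_CONFIG$rmasca$n_folds,
                           n_iter = STUDY_CONFIG$rmasca$n_iter,
                           seed = STUDY_SEED)
tsc <- jk_t$full$time
message(sprintf("time decomposition: PC1 explains %.1f%%, PC2 %.1f%% (jackknife %d/%d iterations)",
                tsc$explained[1], tsc$explained[2], jk_t$n_success,
                STUDY_CONFIG$rmasca$n_iter))
pc1 <- tsc$loadings[, 1]
message(sprintf("PC1 loadings: %d positive, %d negative; strongest |loading|: %s",
                sum(pc1 > 0), sum(pc1 < 0),
                paste(names(sort(abs(pc1), decreasing = TRUE))[1:3],
                      collapse = ", ")))

write_result(cbind(tsc$cells, scores = tsc$scores,
                   lower = jk_t$time$scores_lower,
                   upper = jk_t$time$scores_upper), "sca_time_scores.csv")
write_result(data.frame(cytokine = rownames(tsc$loadings),
                        loadings = tsc$loadings,
                        lower = jk_t$time$loadings_lower,
                        upper = jk_t$time$loadings_upper),
             "sca_time_loadings.csv")

## BMI-class group decomposition
spec_g <- rmasca_spec(group_var = "bmi_class", group_ref = "normal")
jk_g <- jackknife_validate(norm$panel, spec_g,
                           n_folds = STUDY_CONFIG$rmasca$n_folds,
                           n_iter = STUDY_CONFIG$rmasca$n_iter,
                           seed = STUDY_SEED)
gsc <- jk_g$full$group
message(sprintf("BMI-class group component 1 explains %.1f%% of the group+interaction variation",
                gsc$explained[1]))
write_result(cbind(gsc$cells, scores = gsc$scores,
                   lower = jk_g$group$scores_lower,
                   upper = jk_g$group$scores_upper), "sca_bmi_scores.csv")
write_result(data.frame(cytokine = rownames(gsc$loadings),
                        loadings = gsc$loadings,
                        lower = jk_g$group$loadings_lower,
                        upper = jk_g$group$loadings_upper),
             "sca_bmi_loadings.csv")

sc_df <- data.frame(time = tsc$cells$time, score = tsc$scores[, 1],
                    lo = jk_t$time$scores_lower[, 1],
                    hi = jk_t$time$scores_upper[, 1])
pl <- ggplot(sc_df, aes(time, score, group = 1)) +
  geom_line() + geom_point() +
  geom_errorbar(aes(ymin = lo, ymax = hi), width = 0.1) +
  labs(title = sprintf("Time scores, PC1 (%.0f%% explained)",
                       tsc$explained[1]),
       x = "Trimester", y = "Score") +
  theme_minimal()
ggsave(file.path(RESULTS_DIR, "figures", "sca_time_pc1.png"), pl,
       width = 4, height = 3, dpi = 150)
message("wrote results/figures/sca_time_pc1.png")
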