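# Continuous trajectories, robustness screen, trimester contrasts and
# within-stratum correlations.

test_that("a noiseless linear trend is reproduced by the penalized spline", {
  set.seed(1)
  d <- mk_slice(60, seed = 1, sd = 0)
  d$conc <- 5 + 0.01 * d$ga
  # zero residual variance: REML step warnings are expected in this limit
  fit <- suppressWarnings(fit_trajectory(d))
  expected <- 5 + 0.01 * fit$grid
  # population curve linear up to the (constant) cohort offset
  off <- mean(fit$mean_curve - expected)
  expect_lt(max(abs(fit$mean_curve - expected - off)), 1e-3)
  expect_true(all(fit$lower <= fit$mean_curve & fit$mean_curve <= fit$upper))
})

test_that("a known sinusoid is recovered with small error at large n", {
  sig <- function(ga) 2 * sin(ga / 40)
  d <- mk_slice(400, seed = 2, signal = sig, sd = 1)
  fit <- fit_trajectory(d)
  truth <- 10 + sig(fit$grid)
  rmse <- sqrt(mean((fit$mean_curve - mean(fit$mean_curve) -
                       (truth - mean(truth)))^2))
  expect_lt(rmse, 0.1 * 2)
  expect_error(fit_trajectory(d[1:20, ]), ">= 30")
})

test_that("robustness screen: strong noiseless signal is reliable, pure noise is not", {
  sig <- function(ga) 5 * sin(ga / 40)
  d <- mk_slice(120, seed = 3, signal = sig, sd = 0)
  r <- assess_robustness(d, n_runs = 15, seed = 3)
  expect_gt(r$mean_rho, 0.999)
  expect_true(r$reliable)
  expect_true(all(r$rho >= -1 & r$rho <= 1))
  dn <- mk_slice(100, seed = 4, sd = 1)
  rn <- assess_robustness(dn, n_runs = 25, seed = 4)
  expect_lt(rn$mean_rho, 0.90)
  expect_false(rn$reliable)
})

test_that("robustness screen is invariant to participant relabeling", {
  sig <- function(ga) 3 * sin(ga / 50)
  d <- mk_slice(80, seed = 5, signal = sig, sd = 0.5)
  r1 <- assess_robustness(d, n_runs = 10, seed = 9)
  d2 <- d
  ids <- unique(d$participant_id)
  relab <- setNames(sprintf("Q%04d", rev(seq_along(ids))), ids)
  d2$participant_id <- unname(relab[d$participant_id])
  r2 <- assess_robustness(d2, n_runs = 10, seed = 9)
  expect_equal(r2$mean_rho, r1$mean_rho, tolerance = 1e-10)
})

test_that("trimester contrasts recover an injected second-trimester effect", {
  set.seed(6)
  n <- 400
  d <- do.call(rbind, lapply(seq_len(n), function(i) {
    tri <- sample(c("T1", "T2", "T3"), sample(2:3, 1))
    data.frame(participant_id = sprintf("P%03d", i),
               cohort = sample(c("A", "B"), 1), trimester = tri)
  }))
  u <- rnorm(n, 0, 0.4)
  names(u) <- sprintf("P%03d", seq_len(n))
  d$log_conc <- 2 - 0.3 * (d$trimester == "T2") + 0.1 * (d$trimester == "T3") +
    u[d$participant_id] + rnorm(nrow(d), 0, 0.3)
  r <- fit_trimester_lmm(d)
  expect_equal(r$contrast, c("T2", "T3"))
  expect_lt(abs(r$estimate[r$contrast == "T2"] + 0.3), 0.1)
  expect_lt(abs(r$estimate[r$contrast == "T3"] - 0.1), 0.1)
})

test_that("null trimester contrasts are small and BH keeps adjusted p monotone", {
  set.seed(7)
  pan <- do.call(rbind, lapply(paste0("V", 1:4), function(ck) {
    d <- mk_slice(80, seed = match(ck, paste0("V", 1:4)), sd = 1)
    data.frame(cytokine = ck, participant_id = d$participant_id,
               cohort = d$cohort, ga = d$ga, log_conc = rnorm(nrow(d)))
  }))
  res <- trimester_effects_panel(pan)
  expect_true(all(abs(res$estimate) < 3.5 * res$se))
  expect_true(all(res$p_adj >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})

test_that("stratified Spearman correlations: exact duplicates and a known copula", {
  n <- 300
  x <- rnorm(n)
  pan <- rbind(
    data.frame(participant_id = sprintf("P%03d", 1:n),
               sample_id = sprintf("S%03d", 1:n), ga = 100,
               cytokine = "A", log_conc = x),
    data.frame(participant_id = sprintf("P%03d", 1:n),
               sample_id = sprintf("S%03d", 1:n), ga = 100,
               cytokine = "Acopy", log_conc = x))
  cr <- correlations_by_trimester(pan)
  expect_equal(cr$T2$rho["A", "Acopy"], 1)
  # bivariate Gaussian with Pearson rho chosen so Spearman rho is 0.33
  set.seed(8)
  rho_p <- 2 * sin(pi * 0.33 / 6)
  xy <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho_p, rho_p, 1), 2))
  pan2 <- rbind(
    data.frame(participant_id = sprintf("P%03d", 1:n),
               sample_id = sprintf("S%03d", 1:n), ga = 150,
               cytokine = "A", log_conc = xy[, 1]),
    data.frame(participant_id = sprintf("P%03d", 1:n),
               sample_id = sprintf("S%03d", 1:n), ga = 150,
               cytokine = "B", log_conc = xy[, 2]))
  cr2 <- correlations_by_trimester(pan2)
  expect_lt(abs(cr2$T2$rho["A", "B"] - 0.33), 0.12)
})

test_that("duplicate samples within a stratum keep the earliest and strata respect minimum size", {
  pan <- rbind(
    data.frame(participant_id = "P1", sample_id = c("S1", "S2"),
               ga = c(100, 150), cytokine = "A", log_conc = c(1, 99)),
    data.frame(participant_id = sprintf("P%02d", 2:12),
               sample_id = sprintf("S%02d", 3:13), ga = 120,
               cytokine = "A", log_conc = rnorm(11)),
    data.frame(participant_id = c("P1", sprintf("P%02d", 2:12)),
               sample_id = c("S1", sprintf("S%02d", 3:13)),
               ga = c(100, rep(120, 11)), cytokine = "B",
               log_conc = rnorm(12)))
  pan$log_conc[pan$sample_id == "S2" & pan$cytokine == "B"] <- NA
  cr <- suppressMessages(correlations_by_trimester(pan[pan$cytokine %in%
                                                         c("A", "B"), ]))
  # P1 contributes S1 (ga 100), not S2
  expect_equal(cr$T2$n, 12)
  # a stratum below the minimum is skipped with a notice
  expect_message(correlations_by_trimester(
    data.frame(participant_id = c("P1", "P2"), sample_id = c("S1", "S2"),
               ga = 289, cytokine = rep("A", 2), log_conc = rnorm(2))),
    "skipped")
})
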