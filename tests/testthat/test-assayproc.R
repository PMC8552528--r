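# Batch correction, calibration, limits, censored imputation, exclusions,
# accounting and covariate derivation.

test_that("inter-lot factor matches the hand-evaluated bridge formula", {
  origin <- data.frame(sample_id = paste0("s", 1:8), fi = rep(50, 8))
  refm <- data.frame(sample_id = paste0("s", 1:8), fi = rep(100, 8))
  fac <- compute_inter_lot_adjustment(origin, refm, "x", "L2")
  expect_equal(fac$delta_log, log(2), tolerance = 1e-12)
  # a sample at FI 100 in the origin lot adjusts to 200
  expect_equal(100 * exp(fac$delta_log), 200, tolerance = 1e-12)
  # identical sets: no adjustment
  fac0 <- compute_inter_lot_adjustment(origin, origin, "x", "L2")
  expect_equal(fac0$delta_log, 0)
  expect_equal(fac$n, 8)
  expect_error(compute_inter_lot_adjustment(
    origin, data.frame(sample_id = paste0("t", 1:8), fi = rep(100, 8))),
    "identities")
  origin$fi[1] <- -1
  expect_error(compute_inter_lot_adjustment(origin, refm), "positive")
})

test_that("intra-lot adjustment equalizes plate anchor means and is a no-op for one plate", {
  fi <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    cytokine = "x",
    fi = c(10, 12, 40, 35),
    lot_id = "L1",
    plate_id = c("P1", "P1", "P2", "P2"),
    role = "sample"
  )
  res <- apply_intra_lot_adjustment(fi, anchor_ids = c("a1", "a2", "b1", "b2"))
  lot_mean <- mean(log(fi$fi))
  for (pl in c("P1", "P2")) {
    m <- mean(log(res$fi$fi[res$fi$plate_id == pl]))
    expect_equal(m, lot_mean, tolerance = 1e-12)
  }
  # hand-check of the two-plate example with equal means per plate
  fi2 <- fi; fi2$fi <- c(10, 10, 40, 40)
  res2 <- apply_intra_lot_adjustment(fi2, anchor_ids = fi2$sample_id)
  expect_equal(res2$fi$fi, c(20, 20, 20, 20), tolerance = 1e-12)
  # single-plate lot: unchanged
  fi3 <- fi; fi3$plate_id <- "P1"
  res3 <- apply_intra_lot_adjustment(fi3, anchor_ids = fi3$sample_id)
  expect_equal(res3$fi$fi, fi3$fi, tolerance = 1e-12)
  expect_error(apply_intra_lot_adjustment(fi, anchor_ids = c("a1", "a2")),
               "P2")
})

test_that("the two-step correction preserves within-plate rank order and re-applies to zero", {
  sim <- mk_noisy_sim(60, seed = 4)
  anch <- gestaflux:::.anchor_sample_ids(sim$samples, sim$participants,
                                         sim$assay_config)
  s1 <- apply_intra_lot_adjustment(sim$assay$fi_long, anch)
  s2 <- apply_inter_lot_adjustment(s1$fi, sim$assay$bridge_manifest, "L1")
  # rank preservation per plate and cytokine
  raw <- sim$assay$fi_long; adj <- s2$fi
  for (pl in unique(raw$plate_id)[1:3]) {
    sel <- raw$plate_id == pl & raw$cytokine == "IL-6" & raw$role == "sample"
    expect_equal(order(raw$fi[sel]), order(adj$fi[sel]))
  }
  # re-application: all deltas are zero and FI is a fixed point
  r1 <- apply_inter_lot_adjustment(s2$fi, sim$assay$bridge_manifest, "L1")
  r2 <- apply_intra_lot_adjustment(r1$fi, anch)
  expect_lt(max(abs(r1$factors$delta_log)), 1e-10)
  expect_lt(max(abs(r2$factors$delta_log)), 1e-10)
  expect_equal(r2$fi$fi, s2$fi$fi, tolerance = 1e-9)
})

test_that("5PL calibration recovers exact parameters from noiseless standards", {
  fx <- mk_standards()
  cur <- fit_standard_curve(fx$standards, "x")
  rel <- abs(unlist(cur$params) - unlist(fx$params)) / abs(unlist(fx$params))
  expect_lt(max(rel), 1e-4)
  # closed-form inverse round trip mid-curve
  conc <- c(5, 50, 500)
  expect_equal(fivepl_inverse(fivepl(conc, fx$params), cur$params), conc,
               tolerance = 1e-6)
  expect_error(fit_standard_curve(fx$standards[fx$standards$conc >
                                                 fx$top / 20, ]), ">= 5")
})

test_that("the power variance model is recovered from replicate spread", {
  fx <- mk_standards(n_plates = 4, theta = c(0.01, 1.8), seed = 42)
  cur <- fit_standard_curve(fx$standards, "x")
  expect_lt(abs(cur$theta[2] - 1.8), 0.2)
})

test_that("limits follow the blank + 3 SD rule and respond to noise monotonically", {
  fx <- mk_standards(params = list(lower = 30, slope = 1.5, infl_log = 4,
                                   upper = 20000, asym = 1))
  cur <- fit_standard_curve(fx$standards, "x")
  # zero-variance blanks with theta0 = 0: LLOD is the inverse at blank mean
  cur0 <- cur; cur0$theta <- c(0, 1)
  lim0 <- estimate_limits(cur0, blanks = rep(fivepl(0.5, fx$params), 4))
  expect_equal(lim0$llod, 0.5, tolerance = 1e-4)
  # doubling theta0 raises the LLOQ
  curA <- cur; curA$theta <- c(0.01, 1.8)
  curB <- cur; curB$theta <- c(0.02, 1.8)
  limA <- estimate_limits(curA, blanks = rep(30, 4))
  limB <- estimate_limits(curB, blanks = rep(30, 4))
  expect_gt(limB$lloq, limA$lloq)
  # ordering invariant
  for (l in list(lim0, limA, limB)) {
    expect_true(l$llod <= l$lloq && l$lloq < l$uloq && l$uloq <= l$ulod)
  }
  expect_error(estimate_limits(cur, blanks = numeric(0)), "non-empty")
})

test_that("FI conversion quantifies mid-curve, caps at ULOD and defers low values", {
  fx <- mk_standards()
  cur <- estimate_limits(fit_standard_curve(fx$standards, "x"),
                         blanks = rep(30.5, 4))
  tbl <- data.frame(sample_id = c("q", "hi", "lo", "bad"),
                    fi = c(fivepl(100, fx$params), 21000,
                           fivepl(cur$llod / 10, fx$params), NaN))
  rec <- fi_to_concentration(tbl, cur)
  expect_equal(rec$conc[1], 100, tolerance = 1e-6)
  expect_equal(rec$status[1], "quantified")
  expect_equal(rec$status[2], "capped_ulod")
  expect_equal(rec$conc[2], cur$ulod)
  expect_equal(rec$status[3], "below_llod")
  expect_true(is.na(rec$conc[3]))
  expect_equal(rec$status[4], "flagged_nonfinite")
})

test_that("censored EM matches the direct censored-likelihood MLE", {
  set.seed(10)
  x <- rlnorm(2000, 1, 0.5)
  L <- qlnorm(0.2, 1, 0.5)
  obs <- x[x >= L]; ncen <- sum(x < L)
  em <- em_censored_lognormal(log(obs), ncen, log(L))
  cdat <- data.frame(left = c(obs, rep(NA, ncen)),
                     right = c(obs, rep(L, ncen)))
  mle <- fitdistrplus::fitdistcens(cdat, "lnorm")$estimate
  expect_lt(abs(em$mu - mle["meanlog"]), 1e-3)
  expect_lt(abs(em$sigma - mle["sdlog"]), 1e-3)
  expect_true(em$converged)
  # no censoring: plain moments of the logs
  em0 <- em_censored_lognormal(log(obs), 0, log(L))
  expect_equal(em0$mu, mean(log(obs)))
  expect_equal(em0$sigma, sqrt(mean((log(obs) - mean(log(obs)))^2)))
})

test_that("imputation fills only below-LLOD records with values strictly under the limit", {
  set.seed(3)
  conc <- rlnorm(300, 2, 0.6)
  llod <- qlnorm(0.15, 2, 0.6)
  rec <- data.frame(sample_id = sprintf("s%03d", 1:300), cytokine = "x",
                    conc = ifelse(conc < llod, NA, conc),
                    status = ifelse(conc < llod, "below_llod", "quantified"),
                    log_conc = ifelse(conc < llod, NA, log(conc)))
  out <- impute_below_llod(rec, llod)
  imp <- out$records$status == "imputed_below_llod"
  expect_equal(sum(imp), sum(conc < llod))
  expect_true(all(out$records$conc[imp] < llod))
  expect_false(out$flagged)
  # quantified rows untouched
  expect_equal(out$records$conc[!imp], rec$conc[!imp])
  # >= 80% censored: refuse and flag
  rec2 <- rec
  rec2$status[1:270] <- "below_llod"; rec2$conc[1:270] <- NA
  out2 <- impute_below_llod(rec2, llod)
  expect_true(out2$flagged)
  expect_equal(out2$records$status, rec2$status)
})

test_that("the quantification exclusion rule is strict at 25%", {
  cur <- list(x = structure(list(cytokine = "x", lloq = 1, uloq = 100,
                                 llod = 0.5, ulod = 200),
                            class = "standard_curve"))
  mk_rec <- function(n_below, n_total) {
    data.frame(cytokine = "x",
               conc = c(rep(0.8, n_below), rep(50, n_total - n_below)),
               status = "quantified")
  }
  # 26 of 100 below LLOQ: excluded
  r <- apply_panel_exclusions(mk_rec(26, 100), cur)
  expect_length(r$retained, 0)
  # exactly 25 of 100: retained (rule is "more than 25%")
  r <- apply_panel_exclusions(mk_rec(25, 100), cur)
  expect_equal(r$retained, "x")
  # fully in range: retained
  r <- apply_panel_exclusions(mk_rec(0, 100), cur)
  expect_equal(r$retained, "x")
  expect_equal(r$report$frac_out_of_range, 0)
})

test_that("missing gestational ages are filled with cohort-visit means", {
  participants <- data.frame(id = c("P1", "P2", "P3", "P4"),
                             cohort = c("A", "A", "A", "B"))
  samples <- data.frame(sample_id = paste0("S", 1:5),
                        participant_id = c("P1", "P2", "P3", "P4", "P4"),
                        visit = c(2, 2, 2, 1, 2),
                        ga = c(100, 110, NA, 80, NA))
  expect_warning(out <- impute_missing_ga(samples, participants),
                 "no gestational-age donors")
  expect_equal(out$samples$ga[3], 105)
  expect_equal(nrow(out$log), 1)
  # the cohort-B visit-2 sample had no donor: dropped
  expect_false("S5" %in% out$samples$sample_id)
  # nothing missing: unchanged
  clean <- samples[1:2, ]
  out2 <- impute_missing_ga(clean, participants)
  expect_identical(out2$samples, clean)
  expect_equal(nrow(out2$log), 0)
})

test_that("outlier screening flags constructed outliers and stays calibrated under the null", {
  set.seed(12)
  n <- 500
  X <- matrix(rnorm(n * 6), n, 6)
  pan <- do.call(rbind, lapply(1:6, function(k) data.frame(
    participant_id = sprintf("P%04d", 1:n),
    sample_id = sprintf("S%04d", 1:n), cohort = "A",
    cytokine = paste0("V", k), log_conc = X[, k])))
  null_flags <- screen_outliers(pan)
  expect_lte(nrow(null_flags), 8)  # ~0.1% expected, allow robust-fit slack
  pan2 <- pan
  pan2$log_conc[pan2$participant_id == "P0001" &
                  pan2$cytokine %in% c("V1", "V2")] <- 10
  flags <- screen_outliers(pan2)
  expect_true("P0001" %in% flags$participant_id)
})

test_that("cohort accounting reproduces the printed participant flow", {
  n <- 943
  p <- data.frame(id = sprintf("P%04d", 1:n), complication = FALSE,
                  bmi = 24, has_samples = TRUE)
  p$complication[1:147] <- TRUE
  p$bmi[148:153] <- 17    # 6 underweight
  p$bmi[154:161] <- 41    # 8 morbidly obese
  p$has_samples[162:227] <- FALSE  # 66 without samples
  outliers <- p$id[300:308]        # 9 outliers among the eligible
  rep <- cohort_accounting(p, outliers)
  expect_equal(rep$assessed, 943)
  expect_equal(rep$excluded_complications, 147)
  expect_equal(rep$excluded_bmi_low, 6)
  expect_equal(rep$excluded_bmi_high, 8)
  expect_equal(rep$excluded_missing_samples, 66)
  expect_equal(rep$outliers_removed, 9)
  expect_equal(rep$final_included, 707)
  # categories always sum to assessed
  expect_equal(rep$final_included + rep$outliers_removed +
                 rep$excluded_complications + rep$excluded_bmi_low +
                 rep$excluded_bmi_high + rep$excluded_missing_samples,
               rep$assessed)
  # no exclusions: included = assessed
  clean <- data.frame(id = c("a", "b"), complication = FALSE, bmi = 24,
                      has_samples = TRUE)
  expect_equal(cohort_accounting(clean)$final_included, 2)
  # overlap resolved by priority: a complicated woman with BMI 41 counts once
  dual <- data.frame(id = "a", complication = TRUE, bmi = 41,
                     has_samples = FALSE)
  racc <- cohort_accounting(dual)
  expect_equal(racc$excluded_complications, 1)
  expect_equal(racc$excluded_bmi_high, 0)
  expect_equal(racc$excluded_missing_samples, 0)
})

test_that("trimester sample tallies use integer-rounded percentages", {
  p <- data.frame(id = sprintf("P%04d", 1:753), complication = FALSE,
                  bmi = 24, has_samples = TRUE)
  samples <- data.frame(participant_id = p$id,
                        ga = c(rep(50, 192), rep(150, 367), rep(250, 194)))
  rep <- cohort_accounting(p, samples = samples)
  expect_equal(unlist(rep$samples_by_trimester),
               c(T1 = 192L, T2 = 367L, T3 = 194L))
  expect_equal(unlist(rep$samples_trimester_pct),
               c(T1 = 25L, T2 = 49L, T3 = 26L))
})

test_that("rmasca normalization divides by the unweighted mean of cohort SDs", {
  set.seed(1)
  x1 <- rnorm(200, 5, 1)
  x2 <- rnorm(200, 5, 3)
  pan <- data.frame(cytokine = "x", cohort = rep(c("A", "B"), each = 200),
                    log_conc = c(x1, x2))
  out <- normalize_panel(pan, "rmasca")
  expected_div <- mean(c(sd(x1), sd(x2)))
  expect_equal(out$metadata$divisor, expected_div, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(expected_div, sd(c(x1, x2)))))
  # single cohort: divisor is that cohort's SD
  out1 <- normalize_panel(pan[pan$cohort == "A", ], "rmasca")
  expect_equal(out1$metadata$divisor, sd(x1), tolerance = 1e-12)
  # zscore scheme: plain autoscaling
  outz <- normalize_panel(pan, "zscore")
  expect_equal(sd(outz$panel$value), 1, tolerance = 1e-12)
  expect_equal(mean(outz$panel$value), 0, tolerance = 1e-12)
  # zero-SD cytokine flagged
  flat <- data.frame(cytokine = "y", cohort = "A", log_conc = rep(1, 10))
  expect_equal(normalize_panel(flat, "zscore")$flagged, "y")
})

test_that("covariate derivation uses left-closed BMI cuts and the day-283 late-term boundary", {
  expect_equal(as.character(bmi_class(c(24.9, 25.0, 29.9, 30.0))),
               c("normal", "overweight", "overweight", "obese"))
  expect_equal(as.character(ga_trimester(c(97, 98, 195, 196, 283, 284))),
               c("T1", "T2", "T2", "T3", "T3", "late"))
  p <- data.frame(id = "a", bmi = 25, parity = 2, birth_weight = 4050,
                  ga_delivery = 282, fetal_sex = "male", age = 30)
  ref <- data.frame(ga = c(275, 282, 289), sex = "male",
                    mean = c(3500, 3600, 3700), sd = 450)
  d <- derive_covariates(p, ref)
  expect_equal(as.character(d$bmi_class), "overweight")
  expect_true(d$parous)
  expect_equal(d$bw_z, 1.0, tolerance = 1e-12)
  expect_equal(as.character(d$bw_group), "high")
  expect_true(d$bmi_eligible)
})
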