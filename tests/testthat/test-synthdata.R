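# Synthetic study generator: cohort structure, trajectory templates,
# concentration model, assay forward model and labor outcomes.

test_that("cohort covariate prevalences behave binomially and degenerate limits hold", {
  coh <- generate_cohort(100, config = list(smoking_prev = 0.10), seed = 1)
  expect_gte(sum(coh$participants$smoking), 3)
  expect_lte(sum(coh$participants$smoking), 20)

  deg <- generate_cohort(2, seed = 2,
                         config = list(smoking_prev = 0, nulliparous_prev = 1,
                                       female_prev = 0))
  expect_true(all(!deg$participants$smoking))
  expect_true(all(deg$participants$parity == 0))
  expect_true(all(deg$participants$fetal_sex == "male"))

  expect_error(generate_cohort(1), "n_women")
  expect_error(generate_cohort(10, config = list(smoking_prev = 1.5)),
               "prevalence")
  expect_error(generate_cohort(10, config = list(cohorts = character(0))),
               "cohort")
})

test_that("late-term women carry exactly one sample beyond gestational day 283", {
  coh <- generate_cohort(200, seed = 5)
  late_ids <- coh$participants$id[coh$participants$study_group == "late_term"]
  late_samp <- coh$samples[coh$samples$participant_id %in% late_ids, ]
  expect_true(all(table(late_samp$participant_id) == 1))
  expect_true(all(late_samp$ga > 283))
  # term women: 1-4 samples each, all at or before day 283
  term_samp <- coh$samples[!coh$samples$participant_id %in% late_ids, ]
  expect_true(all(table(term_samp$participant_id) >= 1))
  expect_true(all(table(term_samp$participant_id) <= 4))
  expect_true(all(term_samp$ga <= 283))
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_cohort(50, seed = 9)
  b <- generate_cohort(50, seed = 9)
  expect_identical(a, b)
  t1 <- generate_trajectory_params(seed = 4)
  t2 <- generate_trajectory_params(seed = 4)
  expect_identical(t1, t2)
  tr1 <- simulate_concentrations(a$participants, a$samples, t1, seed = 7)
  tr2 <- simulate_concentrations(b$participants, b$samples, t2, seed = 7)
  expect_identical(tr1, tr2)
})

test_that("the four template shapes have the advertised geometry", {
  ga <- seq(40, 290, by = 1)
  inc <- shape_curve("increase", ga)
  dec <- shape_curve("decrease", ga)
  peak <- shape_curve("peak_mid", ga)
  dip <- shape_curve("dip_mid", ga)
  expect_true(all(diff(inc) >= -1e-12))
  expect_true(all(diff(dec) <= 1e-12))
  im <- which.max(peak)
  expect_gt(im, 5); expect_lt(im, length(ga) - 5)
  id <- which.min(dip)
  expect_gt(id, 5); expect_lt(id, length(ga) - 5)
})

test_that("template defaults assign eotaxin a decreasing shape with unique names", {
  tm <- generate_trajectory_params(seed = 1)
  expect_equal(tm$shape[tm$cytokine == "eotaxin"], "decrease")
  expect_equal(nrow(tm), 23)
  expect_false(anyDuplicated(tm$cytokine) > 0)
  single <- generate_trajectory_params("eotaxin", seed = 1)
  expect_equal(single$shape, "decrease")
})

test_that("noiseless concentrations equal the template curve and decrease by the amplitude", {
  tm <- generate_trajectory_params(c("eotaxin", "IL-6"), seed = 1,
                                   covariate_effects = NULL)
  tm$subject_sd <- 0; tm$residual_sd <- 0
  coh <- generate_cohort(10, seed = 1)
  tr <- simulate_concentrations(coh$participants, coh$samples, tm, seed = 1)
  for (k in 1:2) {
    sel <- tr$cytokine == tm$cytokine[k]
    expect_equal(tr$true_log_conc[sel],
                 evaluate_template(tm[k, ], tr$ga[sel]), tolerance = 1e-12)
  }
  # decreasing template with unit amplitude: drop from day 70 to day 280
  tm2 <- tm[tm$cytokine == "eotaxin", ]
  tm2$amplitude_log <- 1
  drop70_280 <- evaluate_template(tm2, 70) - evaluate_template(tm2, 280)
  expect_equal(drop70_280, shape_curve("decrease", 70) -
                 shape_curve("decrease", 280), tolerance = 1e-12)
  expect_gt(drop70_280, 0.7)
  expect_lte(drop70_280, 1)
})

test_that("an all-trimester obesity effect raises the obese group mean at every GA", {
  eff <- data.frame(covariate = "bmi_class", level = "obese",
                    cytokine = "CRP", effect_log = 0.4, profile = "all")
  tm <- generate_trajectory_params("CRP", seed = 2, covariate_effects = eff)
  tm$subject_sd <- 0; tm$residual_sd <- 0
  coh <- generate_cohort(80, seed = 2)
  coh$participants$bmi_class <- factor(
    rep(c("normal", "obese"), length.out = 80),
    levels = c("normal", "overweight", "obese"))
  tr <- simulate_concentrations(coh$participants, coh$samples, tm, seed = 2)
  cls <- coh$participants$bmi_class[match(tr$participant_id,
                                          coh$participants$id)]
  tmpl_mean <- evaluate_template(tm[1, ], tr$ga)
  expect_true(all(tr$true_log_conc[cls == "obese"] -
                    tmpl_mean[cls == "obese"] > 0.39))
  expect_true(all(abs(tr$true_log_conc[cls == "normal"] -
                        tmpl_mean[cls == "normal"]) < 1e-12))
})

test_that("identity assay returns the exact 5PL response and flags artifacts otherwise", {
  sim <- mk_noiseless_sim(40, seed = 6)
  fi <- sim$assay$fi_long
  samp <- fi[fi$role == "sample", ]
  tr <- sim$truth
  key <- paste(tr$sample_id, tr$cytokine)
  conc <- tr$true_conc[match(paste(samp$sample_id, samp$cytokine), key)]
  expected <- vapply(seq_len(nrow(samp)), function(i) {
    fivepl(conc[i], sim$assay_config$curve_params[[samp$cytokine[i]]])
  }, numeric(1))
  expect_equal(samp$fi, expected, tolerance = 1e-12)
})

test_that("a lot offset of log(2) doubles that lot's FI for matched samples", {
  sim <- mk_noiseless_sim(40, seed = 8)
  acfg <- sim$assay_config
  acfg$lot_offsets$L2["IL-6"] <- log(2)
  assay2 <- simulate_assay_fi(sim$truth, sim$samples, sim$participants,
                              acfg, seed = 8)
  a <- sim$assay$fi_long; b <- assay2$fi_long
  sel <- a$role == "sample" & a$cytokine == "IL-6" & a$lot_id == "L2"
  expect_equal(b$fi[sel] / a$fi[sel], rep(2, sum(sel)), tolerance = 1e-10)
  selref <- a$role == "sample" & a$cytokine == "IL-6" & a$lot_id == "L1"
  expect_equal(b$fi[selref], a$fi[selref], tolerance = 1e-12)
})

test_that("every plate carries duplicate standards for every cytokine and bridge samples span lots", {
  sim <- mk_noisy_sim(60, seed = 3)
  std <- sim$assay$standards
  counts <- with(std, table(plate_id, cytokine))
  expect_true(all(counts == counts[1, 1]))
  expect_true(all(table(std$replicate) > 0))
  bm <- sim$assay$bridge_manifest
  expect_equal(nrow(bm), sim$assay_config$bridge_n)
  fi <- sim$assay$fi_long
  for (sid in bm$sample_id) {
    expect_true(any(fi$sample_id == sid & fi$lot_id == "L2" &
                      fi$role == "sample"))
    expect_true(any(fi$sample_id == sid & fi$lot_id == "L1" &
                      fi$role == "bridge"))
  }
})

test_that("null labor-outcome model is covariate-independent and calibrates its mean delay", {
  late <- data.frame(id = sprintf("P%04d", 1:500))
  oc <- simulate_labor_outcomes(late, seed = 1)
  expect_true(all(oc$days_to_delivery >= 0))
  expect_setequal(unique(oc$event),
                  c("spontaneous", "induced_randomized", "induced_clinical"))
  sp <- oc$event == "spontaneous"
  expect_equal(mean(oc$days_to_delivery[sp]), 3.4, tolerance = 1e-6)
  # null association: Fine-Gray recovers beta ~ 0
  z <- matrix(rnorm(500), ncol = 1, dimnames = list(late$id, "c1"))
  fg <- fit_fine_gray(oc, z)
  expect_lt(abs(fg$beta), 3 * fg$se)
  expect_error(
    simulate_labor_outcomes(late, z = NULL, association = c(c1 = 0.5)),
    "z matrix")
})
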