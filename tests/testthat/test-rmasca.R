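# RM-ASCA+: per-cytokine mixed models, effect-matrix separation, PCA and
# jackknife validation.

test_that("null data give near-zero fixed effects", {
  pan <- mk_rmasca_panel(n = 50, beta_t = matrix(0, 3, 5), noise = 0.5,
                         re_sd = 0.3, seed = 11)
  fits <- fit_effect_models(pan, rmasca_spec(group_var = "grp",
                                             covariate = NULL))
  for (f in fits$fits) {
    se <- sqrt(diag(f$vcov))
    expect_true(all(abs(f$coef[-1]) < 4 * se[-1]))
  }
})

test_that("an injected categorical time effect is recovered", {
  beta <- matrix(0, 3, 5)
  beta[, 1] <- c(0, 1, 2)  # +1, +2 SD at T2, T3 for V1
  pan <- mk_rmasca_panel(n = 300, beta_t = beta, noise = 0.5, re_sd = 0.3,
                         seed = 12, groups = "g0")
  fits <- fit_effect_models(pan, rmasca_spec(group_var = NULL,
                                             covariate = NULL))
  co <- fits$fits[["V1"]]$coef
  expect_lt(abs(co["..timeT2"] - 1), 0.15)
  expect_lt(abs(co["..timeT3"] - 2), 0.15)
  # direct least-squares oracle on the balanced design
  sub <- pan[pan$cytokine == "V1", ]
  ls <- coef(lm(value ~ factor(trimester, levels = c("T1", "T2", "T3")),
                data = sub))
  expect_lt(abs(co["..timeT2"] - ls[2]), 0.05)
  expect_lt(abs(co["..timeT3"] - ls[3]), 0.05)
})

test_that("effect matrices are additive and vanish for null coefficients", {
  pan <- mk_rmasca_panel(n = 40, noise = 0.2, re_sd = 0.3, seed = 13,
                         group_effect = matrix(rnorm(15, 0, 0.5), 3))
  spec <- rmasca_spec(group_var = "grp", covariate = NULL)
  fits <- fit_effect_models(pan, spec)
  em <- build_effect_matrices(fits)
  des <- gestaflux:::.effect_design(fits)
  full <- sapply(names(fits$fits), function(ck) {
    b <- fits$fits[[ck]]$coef[colnames(des$X)]
    b[is.na(b)] <- 0
    drop(des$X %*% b) - fits$fits[[ck]]$coef["(Intercept)"]
  })
  expect_lt(max(abs(em$time + em$group - full)), 1e-8)
  # all-zero coefficients give zero matrices
  fits0 <- fits
  for (ck in names(fits0$fits)) fits0$fits[[ck]]$coef[] <- 0
  em0 <- build_effect_matrices(fits0)
  expect_true(all(em0$time == 0) && all(em0$group == 0))
  expect_error(build_effect_matrices(
    structure(list(fits = fits$fits[1], spec = spec), class = "rmasca_fits")),
    ">= 2")
})

test_that("balanced design with zero subject variance matches cell-mean PCA", {
  pan <- mk_rmasca_panel(n = 40, cyt = paste0("V", 1:6), noise = 0,
                         re_sd = 0, seed = 14, groups = "g0")
  spec <- rmasca_spec(group_var = NULL, covariate = NULL)
  res <- rmasca(pan, spec, n_components = 2)
  cm <- with(pan, tapply(value, list(trimester, cytokine), mean))
  cm <- cm[c("T1", "T2", "T3"), rownames(res$time$loadings)]
  pc <- prcomp(scale(cm, scale = FALSE), center = FALSE)
  sc <- pc$x[, 1:2]
  for (j in 1:2) {
    if (cor(sc[, j], res$time$scores[, j]) < 0) sc[, j] <- -sc[, j]
  }
  expect_lt(max(abs(res$time$scores - sc)), 1e-8)
  expect_equal(res$time$explained,
               100 * pc$sdev[1:2]^2 / sum(pc$sdev^2), tolerance = 1e-8)
})

test_that("PCA of effect matrices: rank-1 pattern, variance ratios and orthonormal loadings", {
  # rank-1: all cytokines share one time profile
  load_true <- c(1, -2, 0.5, 3, -1, 0.7)
  pan <- mk_rmasca_panel(n = 30, cyt = paste0("V", 1:6), noise = 0,
                         re_sd = 0, seed = 15, groups = "g0",
                         beta_t = c(0, 1, 2) %o% load_true)
  res <- rmasca(pan, rmasca_spec(group_var = NULL, covariate = NULL))
  expect_equal(res$time$explained[1], 100, tolerance = 1e-8)
  L <- res$time$loadings
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-10)
  # sign convention: dominant loading positive
  expect_gt(L[which.max(abs(L[, 1])), 1], 0)
  # two orthogonal patterns with 3:1 variance split 75% / 25%
  em <- res$effects
  M <- cbind(c(-1, 0, 1), c(1, -2, 1) / 3)
  em$time <- M %*% t(qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2])
  colnames(em$time) <- paste0("V", 1:6)
  em$weights <- rep(1, 3)
  p2 <- pca_effects(em, "time", 2)
  expect_equal(p2$explained, c(75, 25), tolerance = 1e-6)
  # explained variance is non-increasing
  expect_true(all(diff(p2$explained) <= 1e-12))
  # zero matrix: flagged with undefined explained variance
  em$time[] <- 0
  p0 <- pca_effects(em, "time", 2)
  expect_true(p0$zero_matrix)
  expect_true(all(is.na(p0$explained)))
})

test_that("scores and loadings are invariant to cytokine order and participant labels", {
  pan <- mk_rmasca_panel(n = 40, noise = 0.2, re_sd = 0.3, seed = 16,
                         groups = "g0")
  spec <- rmasca_spec(group_var = NULL, covariate = NULL)
  r1 <- rmasca(pan, spec)
  pan2 <- pan[order(pan$cytokine, decreasing = TRUE), ]
  relab <- setNames(sprintf("Z%03d", 40:1), sprintf("P%03d", 1:40))
  pan2$participant_id <- unname(relab[pan2$participant_id])
  r2 <- rmasca(pan2, spec)
  cyt <- rownames(r1$time$loadings)
  expect_equal(r2$time$loadings[cyt, ], r1$time$loadings[cyt, ],
               tolerance = 1e-8)
  expect_equal(r2$time$scores, r1$time$scores, tolerance = 1e-8)
})

test_that("a sustained +0.5 SD group effect yields uniformly positive group scores with bands excluding zero", {
  ge <- matrix(0.5, 3, 5)
  pan <- mk_rmasca_panel(n = 120, group_effect = ge, noise = 0.4,
                         re_sd = 0.3, seed = 17)
  spec <- rmasca_spec(group_var = "grp", covariate = NULL)
  jk <- jackknife_validate(pan, spec, n_folds = 7, n_iter = 21, seed = 17,
                           n_components = 1)
  g1 <- jk$full$group$cells$group == "g1"
  expect_true(all(jk$full$group$scores[g1, 1] > 0) ||
                all(jk$full$group$scores[g1, 1] < 0))
  lo <- jk$group$scores_lower[g1, 1]
  hi <- jk$group$scores_upper[g1, 1]
  expect_true(all(lo > 0) || all(hi < 0))
})

test_that("jackknife bands collapse onto the point estimate without noise", {
  beta <- c(0, 1, 2) %o% c(1, -1, 2, 0.5, -2)
  pan <- mk_rmasca_panel(n = 56, beta_t = beta, noise = 0, re_sd = 0,
                         seed = 18, groups = "g0")
  spec <- rmasca_spec(group_var = NULL, covariate = NULL)
  jk <- jackknife_validate(pan, spec, n_iter = 14, seed = 18)
  expect_lt(max(jk$time$scores_upper - jk$time$scores_lower), 1e-6)
  expect_lt(max(jk$time$loadings_upper - jk$time$loadings_lower), 1e-6)
  expect_gte(jk$n_success, 0.8 * 14)
})
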