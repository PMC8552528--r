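---
title: "Methods: longitudinal maternal serum cytokine profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal maternal serum cytokine profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gestaflux)
```

# Scope

gestaflux models the serum cytokine profile of normal pregnancy from first
trimester to beyond term. The package covers the full path from raw
multiplex fluorescence to biological conclusions: a synthetic multi-cohort
study generator, assay preprocessing (batch correction, calibration,
censoring, imputation, exclusions), penalized-spline trajectory models with
a robustness screen, a repeated-measures ASCA decomposition (RM-ASCA+) with
jackknife validation, and the late-term analyses (rank tests, competing
risks, discriminant prediction, covariate regressions).

Time is counted in gestational days throughout; the obstetric notation
`w+d` means `7*w + d` days, so week 14+0 is day 98. Trimester strata are
T1 (< day 98), T2 (days 98–195), T3 (days 196–283) and *late term*
(beyond day 283, i.e. beyond week 40+3). CRP is carried in µg/mL and all
cytokines in pg/mL; units are metadata and are never converted.

# The synthetic study generator

No participant-level data are distributed with the package, so every
analysis is exercised against a generator that reproduces the statistical
*structure* the methods assume.

**Cohort.** `generate_cohort()` draws women from five cohorts: four term
cohorts with fixed visit schedules (1–4 serum samples between roughly day
40 and day 283, with per-visit jitter), and one late-term cohort sampled
exactly once at day 289 ± 2 (about week 41+2). Default marginal
prevalences are 10% smokers, 46% nulliparous and 42% female fetuses, with
56% of women in the late-term group; BMI is truncated to the eligibility
window [18.5, 40). Birth weights come from a bundled *synthetic*
birth-weight reference (`synthetic_bw_reference()`, mean/SD by gestational
age and sex); the real national reference is deliberately not shipped and
any table with the same columns can be substituted.

**Trajectories.** Each analyte follows one of four canonical shapes —
monotone increase, monotone decrease, second-trimester peak,
second-trimester dip — realised as cubic B-spline curves (4 interior knots
over days 40–290) whose control points fix the geometry; the
variation-diminishing property of B-splines guarantees the qualitative
shape. Log concentration is

$$\log C_{ij} = f_k(t_{ij}) + \sum_m \beta_{km}\,x_{im}\,w_m(t_{ij}) +
  u_{ik} + \varepsilon_{ijk},$$

with template curve $f_k$, covariate effects $\beta_{km}$ active over a
gestational profile $w_m$ (all trimesters, T1 only, T3 only, or T2–T3),
subject intercept $u_{ik}\sim N(0, 0.4^2)$ and residual
$\varepsilon\sim N(0, 0.3^2)$. Shape amplitudes are free parameters (the
motivating observations are relative); defaults are 0.5–1.0 log units, with
the eotaxin decline set to 1.5 as the most pronounced trend. Default
covariate effects encode the group signatures the analyses are designed to
detect (obesity raising acute-phase analytes in all trimesters, smoking
raising IL-12/IL-17/CRP, parity and fetal-sex effects confined to single
trimesters, birth-weight effects on IL-2 and FGF-b).

**Assay.** `simulate_assay_fi()` pushes true concentrations through
per-cytokine 5PL response curves, multiplies by lot and plate offsets
(log-scale SDs 0.15 and 0.08) and adds heteroscedastic noise with the power
law $\mathrm{var}(FI) = \theta_0\,\overline{FI}^{\theta_1}$
($\theta_0 = 0.01$, $\theta_1 = 1.8$, about 5% CV mid-curve). Eight bridge
samples per non-reference lot are re-assayed in the reference lot; every
plate carries duplicate standards (eight 4-fold dilution levels) and
duplicate blanks. Samples are randomized to plates within their cohort's
lot except the per-lot anchor set (one cohort, one visit), which is
distributed round-robin so each plate carries anchors; the number of plates
per lot never exceeds the anchor count, keeping the intra-lot correction
estimable.

**Labor outcomes.** For late-term women, time from sampling to delivery
follows a subdistribution-hazard (Fine–Gray) generative model: spontaneous
labor occurs with probability $1-(1-p_0)^{\exp(\eta)}$,
$\eta = z^\top\beta$ with configurable per-cytokine log hazard ratios, and
conditional event times invert the subdistribution CIF with a gamma
baseline in closed form. The trial structure is explicit: women are
randomized 1:1 at sampling to early induction (1–2 days later; reaching it
without labor is recorded as `induced_randomized` and treated as censoring)
or to monitoring, where clinically indicated induction (`induced_clinical`,
a competing event, mean ~8 days) is capped by a policy induction 11 days
after sampling. Because censoring truncates long spontaneous delays, the
generator rescales latent event times (five fixed-point iterations,
deterministic under the seed) so the *empirical* mean delay among observed
spontaneous labors equals the configured 3.4 days (baseline SD 2.5 days);
rescaling preserves the proportional subdistribution-hazards structure, so
estimator recovery is unaffected.

**What the generator does not emulate.** Cross-cytokine correlation:
subject intercepts are independent across analytes, so within-stratum
correlation matrices are near-diagonal, unlike real serum panels where
shared inflammatory programs induce broad positive correlation. Joint
covariate distributions beyond the stated marginals, pregnancy
complications, and lot-by-concentration interaction effects are also
absent. Tests passing on this generator therefore validate the *estimators
and their contracts*, not the biological shape of real data.

# Assay preprocessing

**Batch correction** operates on fluorescence intensity before
calibration; both steps are multiplicative on FI, i.e. additive on log FI:

$$\widehat{FI}_i = \exp\!\big(\log FI_i - \overline{\log FI}_{\text{source}}
  + \overline{\log FI}_{\text{target}}\big).$$

The intra-lot (plate) step uses an anchor set expected to be equal on group
level: each plate's anchor mean of log FI is moved to the lot-wide anchor
mean, so post-adjustment plate means agree to numerical precision. The
inter-lot step moves each non-reference lot onto the reference lot's scale
using the bridge samples' paired measurements. The pipeline estimates the
plate corrections *first* and the bridge-based lot delta on plate-corrected
FI: the plate deltas are invariant to lot-constant shifts, both corrections
commute as additive log shifts, and the composed table is then a fixed
point — re-running either step (in either order) yields deltas of zero.
Estimating the lot delta from raw FI instead would leave a residual
inter-lot delta after plate correction, breaking idempotence without
changing the plate corrections themselves.

A caveat the tests make explicit: the intra-lot correction *assumes* the
anchors are exchangeable. Any real heterogeneity among anchors (sampling-age
jitter, covariate differences) propagates into the corrected values by
design; the measurement round-trip identity therefore holds exactly only
when that assumption holds exactly.

**Calibration.** The curve family is the 5-parameter logistic,
parameterised in log concentration
($FI = a + (d-a)\,[1+e^{-b(\log c - e)}]^{-g}$; $g=1$ recovers the 4PL),
fitted to pooled reference-lot duplicate standards by variance-weighted
least squares with weights from the replicate power model
(log replicate variance regressed on log replicate mean over plate ×
level groups; weights re-derived once from the first fit). When replicates
carry no numerical noise the variance model degenerates and an unweighted
fit with $\theta_0 = 0$ is used. The inverse is closed-form.

**Limits.** LLOD is the concentration at the inverse curve of
(blank mean + 3·SD$_{\text{model}}$), ULOD symmetrically on the upper
asymptote side at the top standard; LLOQ/ULOQ are where the model CV of
back-calculated concentration, $\mathrm{sd}(FI(c))/(c\,FI'(c))$, crosses
20% on a log-spaced grid over the standard support. The 3·SD and 20% CV
constants are configurable defaults; limits are clipped to satisfy
LLOD ≤ LLOQ < ULOQ ≤ ULOD, with flags when the curve cannot be inverted at
the required FI.

**Censoring.** FI above the curve at ULOD is capped at ULOD. Back-calculated
concentrations below LLOD are imputed by a univariate left-censored
lognormal EM: the E-step replaces censored values by conditional moments of
the normal truncated above at log LLOD, the M-step updates $(\mu,\sigma)$,
iterating to $|\Delta\mu| + |\Delta\sigma| < 10^{-6}$ (max 500 iterations);
the imputed value $\exp(E[\log X \mid X < \text{LLOD}])$ is strictly below
the limit. The EM converges to the censored-data MLE, which the tests
verify against an independent direct likelihood maximization. Imputation is
refused (and the analyte flagged) at ≥ 80% censoring. The imputation is
univariate per cytokine — a deliberately transparent choice; borrowing
information across analytes (compositional imputation) is a possible
extension.

**Exclusions and accounting.** An analyte is retained iff at most 25% of
its measurements fall outside [LLOQ, ULOQ] — the rule is strict, so exactly
25% is retained. Participant accounting applies exclusion reasons in a
fixed priority (complications, then BMI < 18.5, then BMI ≥ 40, then missing
samples, then the explicit outlier-removal list), so the categories always
sum to the assessed count. Outlier *flags* come from an automated screen
(per cohort, PCA of the autoscaled log panel; robust Mahalanobis distance
of (PC1, PC2) against the χ²(2) 0.999 quantile) but removal is opt-in via
configuration, mirroring a visual-inspection workflow.

**Normalization.** Two schemes on natural-log concentrations: the RM-ASCA+
scheme subtracts the overall mean and divides by the *unweighted mean of
per-cohort SDs* (not the pooled SD — cohorts contribute equally regardless
of size); the z-score scheme (for the late-term regressions) is ordinary
autoscaling. Constants are stored for the inverse transform.

# Trajectory modelling

The continuous trajectory per analyte is an additive mixed model on the
untransformed concentration: a penalized cubic regression spline in
gestational age (basis dimension 10, knots at quantiles), cohort as a fixed
effect, participant as a random intercept, smoothness chosen by REML with a
double penalty (`select = TRUE`) and an inflated degrees-of-freedom cost
(`gamma = 4`). The last two choices are deliberately conservative: without
a null-space penalty the spline's unpenalized linear component produces
tiny but sign-consistent tilts under pure noise, and since robustness-screen
refits share 80% of their data such tilts yield spuriously perfect rank
correlations. With the double penalty and BIC-flavored cost, trends the data
do not support shrink to flat curves, while the fidelity cost for real
signals is negligible (sinusoid RMSE/amplitude 0.019 at 400 women versus
0.023 at `gamma = 2`). Curves are reported on 100 grid points spanning the
1st–99th GA percentiles, excluding the random effect, with the first cohort
as reference.

**Robustness screen.** Each analyte is refitted 50 times on stratified
(by cohort) random 80% subsets; each run's curve is Spearman-correlated
with the mean of all runs and the analyte is flagged unreliable when the
mean correlation falls below 0.90. A run whose curve variation is below
$10^{-3}$ of the response SD carries no rank information and contributes
ρ = 0 rather than correlating shared numerical residue across overlapping
subsets — without this convention, numerically flat null fits would
correlate near 1. Under these rules a pure-noise response at 100 women is
flagged unreliable in 20 of 20 seeds while a noiseless signal keeps
mean ρ = 0.99994.

**Trimester contrasts** use a linear mixed model on log concentration
(trimester + cohort fixed, participant random intercept) with Wald
contrasts against the first trimester and Benjamini–Hochberg correction
across the full cytokine × contrast family. **Correlations** are Spearman,
computed separately within T1/T2/T3/late term on one sample per participant
per stratum (earliest kept on duplicates), with BH over all pairs within a
stratum.

# RM-ASCA+

The multivariate decomposition proceeds in two steps. First, one linear
mixed model per analyte on the rmasca-normalized value:

$$y = \beta_0 + \beta_t + \beta_g + \beta_{tg} + \beta_{\text{cohort}} +
  u_{\text{participant}} + \varepsilon,$$

with categorical time (T1/T2/T3), a grouping factor with a declared
reference level, their interaction, and cohort as adjustment. Second, the
fixed-effect contributions are assembled per design cell (time × group)
into *effect matrices*: the time partition carries the time main effects;
the group partition carries the group main effect plus interaction (the
deviation from the reference group at each time). Intercept and cohort
terms never enter. The partitions are additive by construction: their sum
equals the full fixed-effect prediction minus intercept and adjustment
terms, which the tests verify to 1e-8.

PCA of each partition is an SVD of the column-centered effect matrix with
rows weighted by the square root of the cell observation counts — the
expansion-to-observations convention for unbalanced designs; on a balanced
design with no random-effect variance the scores coincide with a plain PCA
of centered cell means (machine precision in the tests). Loadings are
orthonormal; the sign convention makes each component's largest-magnitude
loading positive; explained variance comes from the squared singular
values.

**Jackknife.** Each of 100 iterations draws a fresh stratified (by group)
partition of participants into 7 subsets with relative group sizes
preserved, excludes one subset (rotating across iterations) and reruns the
full analysis. Refit components are matched to the full-data components by
maximal absolute loading correlation and sign-aligned — PCA signs are
arbitrary, so alignment must precede aggregation. Bands are the 2.5th and
97.5th percentiles of the aligned scores and loadings; at least 80% of
iterations must succeed. Time as categorical trimester (rather than
continuous) matches the design-cell score displays; a continuous-time
variant is out of scope.

# Late-term analyses

**Term vs late term.** Two-sided Mann–Whitney U tests (tie-corrected normal
approximation) on log concentrations between term samples (days 259–283)
and late-term samples (beyond day 283), BH-corrected across analytes. The
sensitivity variant removes women delivering within 4 days of sampling by
any route ("within four days" means a delay ≤ 4; "after more than four
days" means > 4 — the two phrases partition at 4).

**Fine–Gray.** Per-cytokine univariate subdistribution-hazard regressions
of time to spontaneous labor on normalized log concentration, with
spontaneous labor the event of interest, randomized induction treated as
censoring and clinically indicated induction (and cesarean, unless flagged
randomized) as competing events. Estimation is the censoring-weighted
partial likelihood (IPCW with Kaplan–Meier censoring weights, Breslow
ties) via the cmprsk engine at a tightened convergence tolerance; with no
competing events and no censoring the estimate coincides with the Cox
partial-likelihood estimate to 1e-6, which the tests assert, and the
generator's known log-HR of 0.5 is recovered within ±0.1 at 2000 women.
Note the estimator is non-collapsible: when several analytes jointly drive
the hazard, each univariate fit estimates an attenuated marginal effect.

**O-PLS-DA.** The classifier splits autoscaled predictors into components
orthogonal to the outcome (removed first; default one orthogonal component,
configurable since the original count is unknown) and a single predictive
component; classification thresholds the predictive score at the value
maximizing training balanced accuracy. VIP is computed from the
predictive-component weights; for a single component
$\mathrm{VIP}_j = \sqrt{K w_j^2 / \sum w^2}$, so the mean squared VIP is
exactly 1. Observed holdout metrics come from one stratified 90/10 split;
the permutation test shuffles labels, redraws an (unstratified) 90/10
split, refits, and reports
$p = (1 + \#\{e_{\text{perm}} \le e_{\text{obs}}\})/(n_{\text{perm}}+1)$ —
the +1 smoothing keeps p above zero, with floor $1/(n_{\text{perm}}+1)$.
Stratifying the observed split but not the permuted ones makes the test
slightly conservative at small n; it remains super-uniform (valid) under
the null, which the acceptance suite checks across 50 seeds.

**Regressions.** Per analyte, ordinary linear models of z-score-normalized
log concentration on standardized age, BMI, parity and birth-weight z-score
plus smoking and fetal sex (references: non-smoking, female), BH over the
cytokine × covariate grid. Birth-weight z-scores interpolate the reference
table linearly in gestational age, with nearest-endpoint extrapolation
flagged.

# Numerical and reproducibility choices

* One RNG stream per sub-generator (cohort, concentrations, assay,
  outcomes, analysis), derived from the master seed by a fixed affine map
  modulo 2³¹−1; fixed seed ⇒ byte-identical tables.
* EM tolerance $10^{-6}$ on $|\Delta\mu|+|\Delta\sigma|$; 5PL fits run the
  Levenberg–Marquardt engine at `ftol = ptol = 1e-14`; Fine–Gray Newton
  tolerance $10^{-10}$.
* Degenerate inputs are first-class: zero-variance replicates fall back to
  unweighted calibration; constant columns are dropped (with warnings) from
  PCA screens and O-PLS-DA; zero effect matrices yield flagged zero
  components; empty association maps give the all-null outcome model.
* Test and validation problem sizes are chosen to make each check sharp but
  cheap: EM vs MLE at n = 2000 over 20 seeds, Fine–Gray size at n = 200
  over 2000 replicates, recovery at n = 2000, robustness nulls at 100 women
  × 50 runs × 20 seeds, jackknife coverage at 120 participants × 21
  iterations over 10–20 seeds, permutation calibration at n = 120 with 200
  permutations over 50 seeds. The analysis scripts use a 300-woman study
  with the full protocol settings (50 robustness runs, 100 jackknife
  iterations, 1000 permutations).

# Known limitations

* The round-trip identity of the preprocessing stack is exact only under
  anchor exchangeability; real anchor heterogeneity biases plate
  corrections by the anchors' true differences.
* The univariate censored imputation ignores cross-analyte information.
* The robustness screen's reliability flag depends on the conservative
  smoothing configuration; with an unpenalized null space the screen cannot
  reject pure noise.
* Univariate Fine–Gray hazard ratios are marginal, attenuated quantities
  when multiple analytes drive the hazard jointly; no multivariable
  competing-risks model is provided.
* The synthetic generator's independence of analytes makes correlation-type
  results trivially null; injectable cross-analyte structure would be the
  natural extension.
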