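# End-to-end orchestration: simulate -> preprocess -> trajectories ->
# RM-ASCA+ -> late-term, from a single validated configuration, with a
# reproducibility manifest.

#' Default pipeline configuration
#'
#' Every analysis threshold defaults to the protocol value: 25%
#' quantification exclusion, robustness screen of 50 runs with 20% dropped
#' and a 0.90 reliability cut, 7-fold jackknife with 100 iterations, 1000
#' permutations, 4-day delivery exclusion window.
#'
#' @return Nested named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    n_women = 300L,
    panel = default_panel()$cytokine,
    stages = list(simulate = TRUE, preprocess = TRUE, trajectories = TRUE,
                  rmasca = TRUE, lateterm = TRUE),
    study = list(),
    assay = list(),
    outcomes = list(),
    preprocess = list(exclusion_threshold = 0.25,
                      outlier_removals = character(0)),
    trajectories = list(n_runs = 50L, drop_frac = 0.20,
                        reliability_threshold = 0.90,
                        cytokines = NULL),
    rmasca = list(group_var = "bmi_class", jackknife = FALSE,
                  n_folds = 7L, n_iter = 100L, n_components = 2L),
    lateterm = list(exclude_within_days = 4L, n_orth = 1L,
                    n_perm = 1000L, holdout = 0.10)
  )
}

#' Validate a pipeline configuration
#'
#' Merges user entries over the defaults, rejects unknown keys and collects
#' every bound violation (rather than failing on the first).
#'
#' @param config Named list (possibly nested) of overrides, or a path to a
#'   YAML file.
#' @return The merged configuration, or an error listing all violations.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config) else
      stop("config file not found: ", config)
    if (is.null(config)) config <- list()
  }
  defaults <- default_pipeline_config()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  for (blk in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[blk]]) && !is.null(names(defaults[[blk]])) &&
        is.list(config[[blk]])) {
      unk <- setdiff(names(config[[blk]]),
                     c(names(defaults[[blk]]),
                       if (blk %in% c("study", "assay", "outcomes"))
                         names(config[[blk]])))
      if (length(unk) > 0) {
        errors <- c(errors, paste0("unknown key(s) in ", blk, ": ",
                                   paste(unk, collapse = ", ")))
      }
    }
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single integer")
  chk(cfg$n_women >= 2, "n_women: must be >= 2")
  chk(cfg$preprocess$exclusion_threshold >= 0 &&
        cfg$preprocess$exclusion_threshold <= 1,
      "preprocess$exclusion_threshold: must be in [0, 1]")
  chk(cfg$trajectories$drop_frac > 0 && cfg$trajectories$drop_frac < 1,
      "trajectories$drop_frac: must be in (0, 1)")
  chk(cfg$trajectories$n_runs >= 2, "trajectories$n_runs: must be >= 2")
  chk(cfg$rmasca$n_folds >= 2, "rmasca$n_folds: must be >= 2")
  chk(cfg$lateterm$n_perm >= 1 && cfg$lateterm$n_perm == round(cfg$lateterm$n_perm),
      "lateterm$n_perm: must be a positive integer")
  chk(cfg$lateterm$holdout > 0 && cfg$lateterm$holdout < 1,
      "lateterm$holdout: must be in (0, 1)")
  if (length(errors) > 0) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  }
  cfg
}

#' Simulate a complete synthetic study
#'
#' Generates templates, cohort, true concentrations, assay readout and
#' late-term labor outcomes under a single master seed (one derived stream
#' per sub-generator).
#'
#' @param config Validated pipeline configuration.
#' @return List: `templates`, `participants`, `samples`, `truth`, `assay`
#'   (fi_long, bridge_manifest, standards, blanks), `assay_config`,
#'   `outcomes`.
#' @export
simulate_study <- function(config = validate_config()) {
  templates <- generate_trajectory_params(config$panel, seed = config$seed)
  cohort <- generate_cohort(config$n_women, config = config$study,
                            seed = config$seed)
  truth <- simulate_concentrations(cohort$participants, cohort$samples,
                                   templates, seed = config$seed)
  assay_cfg <- utils::modifyList(
    default_assay_config(templates, seed = config$seed), config$assay)
  assay <- simulate_assay_fi(truth, cohort$samples, cohort$participants,
                             assay_cfg, seed = config$seed)
  late <- cohort$participants[cohort$participants$study_group == "late_term", ]
  outcomes <- NULL
  if (nrow(late) >= 2) {
    z <- .truth_z_matrix(truth, cohort$samples, late)
    assoc <- cfg_get(config$outcomes, "association", numeric(0))
    oc_cfg <- config$outcomes
    oc_cfg$association <- NULL
    outcomes <- simulate_labor_outcomes(late, z = z,
                                        association = unlist(assoc) %||% numeric(0),
                                        config = oc_cfg, seed = config$seed)
    # make delivery day consistent with the generated delay
    idx <- match(outcomes$participant_id, cohort$participants$id)
    ga_samp <- cohort$samples$ga[match(outcomes$participant_id,
                                       cohort$samples$participant_id)]
    cohort$participants$ga_delivery[idx] <-
      round(ga_samp + outcomes$days_to_delivery)
    cohort$participants$delivery_event[idx] <- outcomes$event
  }
  list(templates = templates, participants = cohort$participants,
       samples = cohort$samples, truth = truth, assay = assay,
       assay_config = assay_cfg, outcomes = outcomes)
}

# standardized per-participant matrix of true late-term log concentrations
.truth_z_matrix <- function(truth, samples, late) {
  late_samp <- samples[samples$participant_id %in% late$id, ]
  tr <- truth[truth$sample_id %in% late_samp$sample_id, ]
  wide <- stats::xtabs(true_log_conc ~ participant_id + cytokine, data = tr)
  wide <- matrix(wide, nrow(wide), ncol(wide), dimnames = dimnames(wide))
  scale(wide)
}

#' Preprocess a simulated assay into an analysis panel
#'
#' The full correction and calibration stack: missing-GA substitution,
#' inter-lot bridge adjustment, intra-lot anchor adjustment, per-cytokine
#' 5PL calibration from reference-lot standards, limit estimation from
#' reference-lot blanks, concentration estimation with ULOD capping,
#' censored-EM imputation below LLOD, the 25% quantification exclusion rule,
#' advisory outlier screening and cohort accounting.
#'
#' @param sim Output of [simulate_study()].
#' @param config Validated pipeline configuration.
#' @return List: `panel` (long, joined to samples and participants),
#'   `curves`, `adjustments`, `exclusions`, `outlier_flags`, `accounting`,
#'   `imputation_log`.
#' @export
preprocess_assay <- function(sim, config = validate_config()) {
  ga_fix <- impute_missing_ga(sim$samples, sim$participants)
  samples <- ga_fix$samples
  acfg <- sim$assay_config
  # plate corrections are estimated within lots and are invariant to
  # lot-constant shifts, so removing them first cleans the bridge-sample
  # comparison and makes the two-step correction a fixed point on
  # re-application (the adjustments commute as additive log shifts)
  anchor_ids <- .anchor_sample_ids(samples, sim$participants, acfg)
  intra <- apply_intra_lot_adjustment(sim$assay$fi_long, anchor_ids)
  inter <- apply_inter_lot_adjustment(intra$fi, sim$assay$bridge_manifest,
                                      acfg$reference_lot)
  fi <- inter$fi

  ref_std <- sim$assay$standards[sim$assay$standards$lot_id ==
                                   acfg$reference_lot, ]
  ref_blank <- sim$assay$blanks[sim$assay$blanks$lot_id ==
                                  acfg$reference_lot, ]
  curves <- list()
  records <- list()
  imput_log <- list()
  for (ck in unique(fi$cytokine)) {
    curve <- fit_standard_curve(ref_std[ref_std$cytokine == ck, ], ck)
    curve <- estimate_limits(curve, ref_blank$fi[ref_blank$cytokine == ck])
    curves[[ck]] <- curve
    rec <- fi_to_concentration(
      fi[fi$cytokine == ck & fi$role == "sample", c("sample_id", "fi")],
      curve)
    imp <- impute_below_llod(rec, curve$llod)
    records[[ck]] <- imp$records
    imput_log[[ck]] <- data.frame(
      cytokine = ck, n_censored = sum(rec$status == "below_llod"),
      refused = imp$flagged,
      mu = if (!is.null(imp$fit)) imp$fit$mu else NA_real_,
      sigma = if (!is.null(imp$fit)) imp$fit$sigma else NA_real_,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)
  excl <- apply_panel_exclusions(records, curves,
                                 config$preprocess$exclusion_threshold)
  records <- records[records$cytokine %in% excl$retained, ]

  panel <- merge(records, samples, by = "sample_id")
  panel <- merge(panel, sim$participants, by.x = "participant_id",
                 by.y = "id")
  panel$trimester <- ga_trimester(panel$ga)
  flags <- screen_outliers(panel)
  removals <- config$preprocess$outlier_removals
  if (length(removals) > 0) {
    panel <- panel[!panel$participant_id %in% removals, ]
  }
  accounting <- cohort_accounting(sim$participants, removals,
                                  samples = samples)
  rownames(panel) <- NULL
  list(panel = panel, curves = curves,
       adjustments = rbind(inter$factors[, c("scope", "lot_id", "cytokine",
                                             "delta_log")],
                           intra$factors[, c("scope", "lot_id", "cytokine",
                                             "delta_log")]),
       exclusions = excl, outlier_flags = flags, accounting = accounting,
       imputation_log = do.call(rbind, imput_log))
}

.anchor_sample_ids <- function(samples, participants, acfg) {
  cohort_of <- stats::setNames(participants$cohort, participants$id)
  out <- lapply(acfg$lots, function(l) {
    anc <- acfg$anchors[[l]]
    sel <- cohort_of[samples$participant_id] == anc$cohort &
      samples$visit == anc$visit
    samples$sample_id[sel]
  })
  names(out) <- acfg$lots
  out
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order, writes stage artifacts
#' (CSV/JSON) under `out_dir` and a manifest recording the configuration
#' hash, seed, package version and per-stage row counts. Reruns with the
#' same configuration are bit-identical for the deterministic stages.
#'
#' @param config Configuration list or YAML path (validated internally).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gestaflux_run")) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("gestaflux")),
                   stages = list())
  res <- list(config = cfg)
  wcsv <- function(x, name) utils::write.csv(
    x, file.path(out_dir, name), row.names = FALSE)

  if (!isTRUE(cfg$stages$simulate)) {
    stop("pipeline requires the simulate stage")
  }
  sim <- simulate_study(cfg)
  res$sim <- sim
  wcsv(sim$participants, "participants.csv")
  wcsv(sim$samples, "samples.csv")
  wcsv(sim$assay$fi_long, "fi_long.csv")
  wcsv(sim$assay$bridge_manifest, "bridge_manifest.csv")
  wcsv(sim$assay$standards, "standards.csv")
  if (!is.null(sim$outcomes)) wcsv(sim$outcomes, "outcomes.csv")
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  utils::write.csv(sim$truth, file.path(out_dir, "truth", "concentrations.csv"),
                   row.names = FALSE)
  manifest$stages$simulate <- list(participants = nrow(sim$participants),
                                   samples = nrow(sim$samples),
                                   wells = nrow(sim$assay$fi_long))

  if (isTRUE(cfg$stages$preprocess)) {
    prep <- preprocess_assay(sim, cfg)
    res$prep <- prep
    wcsv(prep$panel[, c("sample_id", "participant_id", "cytokine", "conc",
                        "status", "log_conc", "ga", "trimester", "cohort")],
         "panel.csv")
    wcsv(prep$adjustments, "adjustments.csv")
    jsonlite::write_json(prep$accounting,
                         file.path(out_dir, "accounting.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(prep$exclusions$report,
                         file.path(out_dir, "exclusions.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$preprocess <- list(panel_rows = nrow(prep$panel),
                                       retained = length(prep$exclusions$retained))
  }

  if (isTRUE(cfg$stages$trajectories) && isTRUE(cfg$stages$preprocess)) {
    tp <- cfg$trajectories
    term_panel <- res$prep$panel[res$prep$panel$trimester != "late", ]
    cyts <- tp$cytokines %||% unique(term_panel$cytokine)
    tra <- list(); rob <- list()
    for (ck in cyts) {
      slice <- term_panel[term_panel$cytokine == ck, ]
      fit <- tryCatch(suppressWarnings(fit_trajectory(slice)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      tra[[ck]] <- data.frame(cytokine = ck, ga = fit$grid,
                              mean = fit$mean_curve, lower = fit$lower,
                              upper = fit$upper)
      rb <- tryCatch(
        assess_robustness(slice, n_runs = tp$n_runs,
                          drop_frac = tp$drop_frac, seed = cfg$seed,
                          reliability_threshold = tp$reliability_threshold),
        error = function(e) NULL)
      if (!is.null(rb)) {
        rob[[ck]] <- data.frame(cytokine = ck, mean_rho = rb$mean_rho,
                                reliable = rb$reliable)
      }
    }
    res$trajectories <- do.call(rbind, tra)
    res$robustness <- do.call(rbind, rob)
    if (!is.null(res$trajectories)) wcsv(res$trajectories, "trajectories.csv")
    if (!is.null(res$robustness)) {
      jsonlite::write_json(res$robustness, file.path(out_dir, "robustness.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    res$trimester_effects <- trimester_effects_panel(term_panel)
    wcsv(res$trimester_effects, "trimester_effects.csv")
    manifest$stages$trajectories <- list(fitted = length(tra))
  }

  if (isTRUE(cfg$stages$rmasca) && isTRUE(cfg$stages$preprocess)) {
    term_panel <- res$prep$panel[res$prep$panel$trimester != "late", ]
    term_panel$trimester <- droplevels(term_panel$trimester)
    norm <- normalize_panel(term_panel, "rmasca")
    spec <- rmasca_spec(group_var = cfg$rmasca$group_var)
    if (isTRUE(cfg$rmasca$jackknife)) {
      jk <- jackknife_validate(norm$panel, spec, n_folds = cfg$rmasca$n_folds,
                               n_iter = cfg$rmasca$n_iter, seed = cfg$seed,
                               n_components = cfg$rmasca$n_components)
      res$rmasca <- jk$full
      res$rmasca_bands <- jk
    } else {
      res$rmasca <- rmasca(norm$panel, spec, cfg$rmasca$n_components)
    }
    sc <- res$rmasca$time
    wcsv(cbind(sc$cells, as.data.frame(sc$scores)), "sca_scores.csv")
    wcsv(data.frame(cytokine = rownames(sc$loadings),
                    as.data.frame(sc$loadings)), "sca_loadings.csv")
    manifest$stages$rmasca <- list(
      components = ncol(sc$scores),
      explained_pc1 = unname(sc$explained[1]))
  }

  if (isTRUE(cfg$stages$lateterm) && isTRUE(cfg$stages$preprocess) &&
      !is.null(sim$outcomes)) {
    lt <- cfg$lateterm
    panel <- res$prep$panel
    res$lateterm_tests <- compare_term_lateterm(panel)
    res$lateterm_tests_excl <- tryCatch(
      compare_term_lateterm(panel, sim$participants,
                            exclude_within_days = lt$exclude_within_days),
      error = function(e) NULL)
    late_panel <- panel[panel$trimester == "late", ]
    if (nrow(late_panel) > 0) {
      norm <- normalize_panel(late_panel, "zscore")
      z <- stats::xtabs(value ~ participant_id + cytokine,
                        data = norm$panel)
      z <- matrix(z, nrow(z), ncol(z), dimnames = dimnames(z))
      res$finegray <- tryCatch(fit_fine_gray(sim$outcomes, z),
                               error = function(e) NULL)
      oc <- sim$outcomes[match(rownames(z), sim$outcomes$participant_id), ]
      y <- ifelse(oc$event == "spontaneous" & oc$days_to_delivery <= 4, 1L,
                  ifelse(oc$days_to_delivery > 4, 0L, NA_integer_))
      ok <- !is.na(y)
      if (sum(ok) >= 20 && length(unique(y[ok])) == 2) {
        res$oplsda <- evaluate_and_permute(z[ok, , drop = FALSE], y[ok],
                                           n_orth = lt$n_orth,
                                           n_perm = lt$n_perm,
                                           holdout = lt$holdout,
                                           seed = cfg$seed)
      }
      res$regressions <- lateterm_regressions(norm$panel, sim$participants)
      wcsv(res$regressions, "regressions.csv")
      if (!is.null(res$finegray)) wcsv(res$finegray, "finegray.csv")
      if (!is.null(res$oplsda)) {
        jsonlite::write_json(res$oplsda[c("error_rate", "sensitivity",
                                          "specificity", "p_value")],
                             file.path(out_dir, "oplsda.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    wcsv(res$lateterm_tests, "lateterm_tests.csv")
    manifest$stages$lateterm <- list(
      tested = nrow(res$lateterm_tests),
      finegray = if (!is.null(res$finegray)) nrow(res$finegray) else 0L)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

#' Hash a configuration for the manifest
#'
#' MD5 of the deterministically deparsed configuration.
#'
#' @param cfg Configuration list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg[order(names(cfg))]), tf)
  unname(tools::md5sum(tf))
}
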