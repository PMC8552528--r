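# Repeated-measures ASCA+: per-cytokine linear mixed models (time, group,
# time:group and cohort as fixed effects, participant random intercept),
# effect-matrix construction and separation into a time partition and a
# group-plus-interaction partition, PCA (SVD) of the cell-count-weighted
# effect matrices, and jackknife percentile bands.

#' RM-ASCA+ model specification
#'
#' @param time_var Column holding the time factor (default `"trimester"`,
#'   levels T1/T2/T3).
#' @param time_levels Ordered time levels.
#' @param group_var Optional grouping column (e.g. `"bmi_class"`); NULL for a
#'   time-only analysis.
#' @param group_ref Reference level of the group factor (defaults to its
#'   first level).
#' @param covariate Adjustment factor included in the LMMs but never in the
#'   effect matrices (default `"cohort"`).
#' @return A list of class `rmasca_spec`.
#' @export
rmasca_spec <- function(time_var = "trimester",
                        time_levels = c("T1", "T2", "T3"),
                        group_var = NULL, group_ref = NULL,
                        covariate = "cohort") {
  structure(list(time_var = time_var, time_levels = time_levels,
                 group_var = group_var, group_ref = group_ref,
                 covariate = covariate),
            class = "rmasca_spec")
}

.rmasca_prepare <- function(panel, spec) {
  d <- panel
  d$..time <- factor(d[[spec$time_var]], levels = spec$time_levels)
  d <- d[!is.na(d$..time), ]
  if (!is.null(spec$group_var)) {
    g <- factor(d[[spec$group_var]])
    if (!is.null(spec$group_ref)) g <- stats::relevel(g, ref = spec$group_ref)
    d$..group <- g
  }
  if (!is.null(spec$covariate) && spec$covariate %in% names(d)) {
    cv <- factor(d[[spec$covariate]])
    d$..cov <- if (nlevels(cv) > 1) cv else NULL
  }
  d
}

#' Fit per-cytokine effect models
#'
#' One linear mixed model per cytokine on the rmasca-normalized value:
#' fixed effects time + group + time:group (+ adjustment covariate), random
#' participant intercept. Coefficients and covariance matrices are retained
#' for effect-matrix construction.
#'
#' @param panel Normalized long panel (`cytokine`, `value`,
#'   `participant_id`, plus the spec's factors).
#' @param spec An [rmasca_spec()].
#' @return List of per-cytokine fits (`coef`, `vcov`, `terms` metadata) plus
#'   the observed design-cell counts.
#' @export
fit_effect_models <- function(panel, spec) {
  d <- .rmasca_prepare(panel, spec)
  has_group <- !is.null(spec$group_var)
  has_cov <- "..cov" %in% names(d) && !is.null(d$..cov)
  rhs <- if (has_group) "..time * ..group" else "..time"
  if (has_cov) rhs <- paste(rhs, "+ ..cov")
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant_id)"))
  cyt <- unique(d$cytokine)
  fits <- vector("list", length(cyt))
  names(fits) <- cyt
  for (ck in cyt) {
    sub <- d[d$cytokine == ck, ]
    fit <- lme4::lmer(form, data = sub,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    fe <- lme4::fixef(fit)
    if (any(is.na(fe))) {
      warning("rank-deficient design for ", ck, "; aliased terms dropped")
    }
    fits[[ck]] <- list(coef = fe, vcov = as.matrix(stats::vcov(fit)),
                       formula = form)
  }
  cell_vars <- c("..time", if (has_group) "..group")
  counts <- as.data.frame(table(d[d$cytokine == cyt[1], cell_vars,
                                  drop = FALSE]))
  names(counts) <- c("time", if (has_group) "group", "n")
  structure(list(fits = fits, spec = spec, cells = counts,
                 data_template = d[1, , drop = FALSE]),
            class = "rmasca_fits")
}

# Fixed-effect design matrix for the design cells, split by partition.
.effect_design <- function(fits) {
  spec <- fits$spec
  has_group <- !is.null(spec$group_var)
  cells <- fits$cells[fits$cells$n > 0, , drop = FALSE]
  nd <- data.frame(..time = factor(cells$time, levels = spec$time_levels))
  if (has_group) {
    tmpl <- fits$data_template$..group
    nd$..group <- factor(cells$group, levels = levels(tmpl))
  }
  rhs <- if (has_group) "~ ..time * ..group" else "~ ..time"
  trm <- stats::terms(stats::as.formula(rhs))
  X <- stats::model.matrix(trm, nd)
  labels <- attr(trm, "term.labels")
  asgn <- attr(X, "assign")
  time_cols <- which(asgn == match("..time", labels))
  group_cols <- integer(0)
  if (has_group) {
    group_cols <- which(asgn %in% c(match("..group", labels),
                                    match("..time:..group", labels)))
  }
  list(X = X, cells = cells, time_cols = time_cols, group_cols = group_cols)
}

#' Build separated effect matrices
#'
#' For every observed design cell (time level x group level) the fixed-effect
#' contribution of each partition's terms is assembled per cytokine: the
#' `time` partition carries the time main effects, the `group` partition the
#' group main effect plus the time:group interaction (the difference from the
#' reference group at each time). Intercept and adjustment-covariate terms
#' never enter the matrices. The two partitions sum to the full fixed-effect
#' prediction minus intercept and covariate terms.
#'
#' @param fits An `rmasca_fits` object.
#' @return List of class `effect_matrices`: `time` and (if a group factor is
#'   present) `group` matrices (cells x cytokines), `cells`, `weights`
#'   (observation counts per cell).
#' @export
build_effect_matrices <- function(fits) {
  if (length(fits$fits) < 2) stop("need models for >= 2 cytokines")
  des <- .effect_design(fits)
  cyt <- names(fits$fits)
  mk <- function(cols) {
    out <- sapply(cyt, function(ck) {
      beta <- fits$fits[[ck]]$coef
      b <- beta[colnames(des$X)]
      b[is.na(b)] <- 0
      if (length(cols) == 0) return(rep(0, nrow(des$X)))
      drop(des$X[, cols, drop = FALSE] %*% b[cols])
    })
    matrix(out, nrow = nrow(des$X), dimnames = list(NULL, cyt))
  }
  res <- list(time = mk(des$time_cols), cells = des$cells,
              weights = des$cells$n)
  if (length(des$group_cols) > 0) res$group <- mk(des$group_cols)
  structure(res, class = "effect_matrices")
}

#' PCA of an effect matrix
#'
#' Weighted SVD of the column-centered effect matrix: rows (design cells) are
#' weighted by the square root of their observation counts, mirroring the
#' observation-level expansion of the unbalanced-data ASCA convention.
#' Loadings are orthonormal; scores are the centered cell rows projected onto
#' the loadings; per-component explained variance comes from the squared
#' singular values. Sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param effects An `effect_matrices` object.
#' @param partition `"time"` or `"group"`.
#' @param n_components Number of components to keep (default 2).
#' @return List of class `sca_result`: `scores` (cells x components),
#'   `loadings` (cytokines x components), `explained` (percent), `cells`.
#' @export
pca_effects <- function(effects, partition = "time", n_components = 2) {
  M <- effects[[partition]]
  if (is.null(M)) stop("no such partition: ", partition)
  w <- effects$weights
  if (all(abs(M) < 1e-14)) {
    k <- min(n_components, ncol(M))
    return(structure(list(
      scores = matrix(0, nrow(M), k),
      loadings = matrix(0, ncol(M), k,
                        dimnames = list(colnames(M), NULL)),
      explained = rep(NA_real_, k), cells = effects$cells,
      zero_matrix = TRUE), class = "sca_result"))
  }
  mu <- colSums(M * w) / sum(w)
  Mc <- sweep(M, 2, mu)
  sv <- svd(sweep(Mc, 1, sqrt(w), "*"))
  k <- min(n_components, sum(sv$d > 1e-12 * sv$d[1]))
  k <- max(k, 1)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(M)
  # sign convention
  for (j in seq_len(k)) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- Mc %*% loadings
  explained <- 100 * sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = loadings,
                 explained = explained[seq_len(k)], cells = effects$cells,
                 zero_matrix = FALSE),
            class = "sca_result")
}

#' Full RM-ASCA+ analysis
#'
#' Convenience wrapper: fits the per-cytokine models, builds the separated
#' effect matrices and runs the PCA for each partition.
#'
#' @param panel Normalized long panel.
#' @param spec An [rmasca_spec()].
#' @param n_components Components per partition (default 2).
#' @return List: `fits`, `effects`, `time` (`sca_result`) and optionally
#'   `group` (`sca_result`).
#' @export
rmasca <- function(panel, spec = rmasca_spec(), n_components = 2) {
  fits <- fit_effect_models(panel, spec)
  effects <- build_effect_matrices(fits)
  out <- list(fits = fits, effects = effects,
              time = pca_effects(effects, "time", n_components))
  if (!is.null(effects$group)) {
    out$group <- pca_effects(effects, "group", n_components)
  }
  out
}

# Align a jackknife sca_result to the full-data result: match components by
# maximal absolute loading correlation, then flip signs to positive
# correlation.
.align_components <- function(full, jack) {
  kf <- ncol(full$loadings); kj <- ncol(jack$loadings)
  used <- logical(kj)
  ord <- integer(kf); sgn <- numeric(kf)
  for (j in seq_len(kf)) {
    cors <- sapply(seq_len(kj), function(m) {
      if (used[m]) return(NA_real_)
      suppressWarnings(stats::cor(full$loadings[, j], jack$loadings[, m]))
    })
    m <- which.max(abs(cors))
    used[m] <- TRUE
    ord[j] <- m
    sgn[j] <- ifelse(is.na(cors[m]) || cors[m] >= 0, 1, -1)
  }
  list(scores = sweep(jack$scores[, ord, drop = FALSE], 2, sgn, "*"),
       loadings = sweep(jack$loadings[, ord, drop = FALSE], 2, sgn, "*"))
}

#' Jackknife validation of RM-ASCA+
#'
#' Per iteration, participants are divided into `n_folds` stratified subsets
#' (relative group sizes preserved in each subset) and the analysis is rerun
#' with one subset excluded; refit components are aligned to the full-data
#' components by maximal absolute loading correlation and sign-flipped before
#' the 2.5th and 97.5th percentiles of scores and loadings are taken as
#' bands.
#'
#' @param panel Normalized long panel.
#' @param spec An [rmasca_spec()].
#' @param n_folds Number of stratified subsets (default 7).
#' @param n_iter Number of iterations (default 100).
#' @param seed Integer seed.
#' @param n_components Components per partition.
#' @return List with the full-data result (`full`) and, per partition,
#'   percentile bands: `scores_lower`/`scores_upper`,
#'   `loadings_lower`/`loadings_upper`, plus `n_success`.
#' @export
jackknife_validate <- function(panel, spec = rmasca_spec(), n_folds = 7,
                               n_iter = 100, seed = 1L, n_components = 2) {
  full <- rmasca(panel, spec, n_components)
  parts <- unique(panel[, c("participant_id",
                            if (!is.null(spec$group_var)) spec$group_var),
                        drop = FALSE])
  strat <- if (!is.null(spec$group_var)) {
    factor(parts[[spec$group_var]])
  } else {
    factor(rep("all", nrow(parts)))
  }
  if (min(table(strat)) < n_folds) {
    stop("need >= n_folds participants per group")
  }
  partitions <- c("time", if (!is.null(full$group)) "group")
  draws <- stats::setNames(
    lapply(partitions, function(p) list(scores = list(), loadings = list())),
    partitions)
  with_seed(derive_seed(seed, "analysis") + 31L, {
    n_success <- 0L
    for (it in seq_len(n_iter)) {
      fold <- unlist(lapply(split(seq_len(nrow(parts)), strat), function(ix) {
        stats::setNames(sample(rep_len(seq_len(n_folds), length(ix))),
                        parts$participant_id[ix])
      }))
      names(fold) <- sub("^[^.]*\\.", "", names(fold))
      drop_fold <- (it - 1L) %% n_folds + 1L
      keep_ids <- names(fold)[fold != drop_fold]
      sub <- panel[panel$participant_id %in% keep_ids, ]
      res <- tryCatch(rmasca(sub, spec, n_components), error = function(e) NULL)
      if (is.null(res)) next
      ok <- TRUE
      for (p in partitions) {
        if (is.null(res[[p]]) ||
            !identical(dim(res[[p]]$scores), dim(full[[p]]$scores))) {
          ok <- FALSE
        }
      }
      if (!ok) next
      n_success <- n_success + 1L
      for (p in partitions) {
        al <- .align_components(full[[p]], res[[p]])
        draws[[p]]$scores[[n_success]] <- al$scores
        draws[[p]]$loadings[[n_success]] <- al$loadings
      }
    }
  })
  if (n_success < 0.8 * n_iter) {
    stop("jackknife: only ", n_success, " of ", n_iter,
         " iterations succeeded")
  }
  bands <- list(full = full, n_success = n_success)
  qb <- function(lst, prob) {
    arr <- simplify2array(lst)
    apply(arr, c(1, 2), stats::quantile, probs = prob, names = FALSE)
  }
  for (p in partitions) {
    bands[[p]] <- list(
      scores_lower = qb(draws[[p]]$scores, 0.025),
      scores_upper = qb(draws[[p]]$scores, 0.975),
      loadings_lower = qb(draws[[p]]$loadings, 0.025),
      loadings_upper = qb(draws[[p]]$loadings, 0.975)
    )
  }
  bands
}
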