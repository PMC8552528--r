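# 5PL calibration: variance-weighted curve fitting from duplicate standards,
# power-model variance estimation, and detection / quantification limits.

#' Fit a 5PL standard curve with a power variance model
#'
#' The replicate variance model `var(FI) = theta0 * mean(FI)^theta1` is
#' estimated by regressing log replicate variance on log replicate mean
#' (replicate groups = plate x standard level); the 5PL parameters then
#' minimize the variance-weighted squared error, iterating weights once from
#' the fitted means. When replicates carry (numerically) no noise the
#' variance model degenerates and an unweighted fit with `theta0 = 0` is
#' returned.
#'
#' @param standards Data frame with `conc` (> 0), `fi`, and optionally
#'   `plate_id` delimiting replicate groups.
#' @param cytokine Analyte name carried into the result.
#' @return Object of class `standard_curve`: list with `cytokine`, `params`
#'   (lower, slope, infl_log, upper, asym), `theta`, `support` (concentration
#'   range of the standards), and empty limit slots (see [estimate_limits()]).
#' @export
fit_standard_curve <- function(standards, cytokine = NA_character_) {
  standards <- standards[standards$conc > 0 & is.finite(standards$fi), ]
  levels_ <- sort(unique(standards$conc))
  if (length(levels_) < 5) stop("need >= 5 distinct standard concentrations")
  grp <- if ("plate_id" %in% names(standards)) {
    interaction(standards$plate_id, standards$conc, drop = TRUE)
  } else {
    factor(standards$conc)
  }
  gm <- tapply(standards$fi, grp, mean)
  gv <- tapply(standards$fi, grp, stats::var)
  gn <- tapply(standards$fi, grp, length)
  if (!any(gn >= 2)) stop("need replicates (>= 2) at some standard level")
  ok <- !is.na(gv) & gv > 1e-12 & gn >= 2
  theta <- c(0, 1)
  if (sum(ok) >= 3) {
    vf <- stats::lm(log(gv[ok]) ~ log(gm[ok]))
    theta <- c(exp(unname(stats::coef(vf)[1])), unname(stats::coef(vf)[2]))
    if (theta[2] < 0) theta[2] <- 0
  }

  lo0 <- min(standards$fi) * 0.98
  up0 <- max(standards$fi) * 1.05
  y <- pmin(pmax((standards$fi - lo0) / (up0 - lo0), 1e-4), 1 - 1e-4)
  lin <- stats::lm(stats::qlogis(y) ~ log(standards$conc))
  b0 <- max(unname(stats::coef(lin)[2]), 0.2)
  e0 <- -unname(stats::coef(lin)[1]) / b0
  start <- list(lower = lo0, slope = b0, infl_log = e0, upper = up0, asym = 1)

  fit_once <- function(w) {
    minpack.lm::nlsLM(
      fi ~ lower + (upper - lower) /
        (1 + exp(-slope * (log(conc) - infl_log)))^asym,
      data = standards, start = start, weights = w,
      lower = c(0, 1e-3, min(log(standards$conc)) - 5, lo0, 1e-2),
      upper = c(up0, 20, max(log(standards$conc)) + 5, up0 * 4, 20),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    )
  }
  fit <- fit_once(rep(1, nrow(standards)))
  if (theta[1] > 0) {
    mu_hat <- pmax(stats::fitted(fit), 1e-6)
    fit <- fit_once(1 / (theta[1] * mu_hat^theta[2]))
  }
  p <- as.list(stats::coef(fit))
  if (p$slope <= 0 || p$asym <= 0 || p$upper <= p$lower) {
    stop("calibration failed for ", cytokine,
         ": fitted curve is not monotone between asymptotes (params: ",
         paste(sprintf("%s=%.3g", names(p), unlist(p)), collapse = ", "), ")")
  }
  structure(
    list(cytokine = cytokine, params = p, theta = theta,
         support = range(standards$conc),
         llod = NA_real_, ulod = NA_real_, lloq = NA_real_, uloq = NA_real_,
         flags = character(0)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("5PL standard curve for", x$cytokine, "\n")
  cat(sprintf("  params: lower=%.3g slope=%.3g infl_log=%.3g upper=%.3g asym=%.3g\n",
              x$params$lower, x$params$slope, x$params$infl_log,
              x$params$upper, x$params$asym))
  cat(sprintf("  variance model: var = %.3g * mean^%.3g\n",
              x$theta[1], x$theta[2]))
  cat(sprintf("  limits: LLOD=%.4g LLOQ=%.4g ULOQ=%.4g ULOD=%.4g\n",
              x$llod, x$lloq, x$uloq, x$ulod))
  invisible(x)
}

#' Estimate detection and quantification limits
#'
#' Detection limits come from the blank signal and the power variance model:
#' LLOD is the concentration at the inverse curve of
#' `blank mean + 3 * sd_model(blank mean)` and ULOD symmetrically at
#' `FI(top) - 3 * sd_model(FI(top))` on the upper side. Quantification limits
#' are where the model CV of back-calculated concentration,
#' `sd_model(FI(c)) / (dFI/dc * c)`, crosses `cv_limit` (default 20%),
#' located on a log-spaced grid over the standard support. Limits are ordered
#' `llod <= lloq < uloq <= ulod`; a curve too flat to invert at the required
#' FI falls back to the support bounds and is flagged.
#'
#' @param curve A fitted `standard_curve`.
#' @param blanks Numeric vector of blank-well FI.
#' @param cv_limit CV threshold for LOQ (default 0.20).
#' @param grid_n Grid resolution (default 400).
#' @return The curve with `llod`, `ulod`, `lloq`, `uloq` populated.
#' @export
estimate_limits <- function(curve, blanks, cv_limit = 0.20, grid_n = 400) {
  if (length(blanks) == 0) stop("blanks must be non-empty")
  p <- curve$params
  theta <- curve$theta
  sd_model <- function(fi) sqrt(theta[1] * pmax(fi, 0)^theta[2])
  grid <- exp(seq(log(curve$support[1]), log(curve$support[2]),
                  length.out = grid_n))

  blank_mean <- mean(blanks)
  fi_llod <- blank_mean + 3 * sd_model(blank_mean)
  llod <- fivepl_inverse(fi_llod, p)
  if (!is.finite(llod) || llod <= 0) {
    llod <- curve$support[1]
    curve$flags <- c(curve$flags, "llod_at_support_bound")
  }
  fi_top <- fivepl(curve$support[2], p)
  fi_ulod <- fi_top - 3 * sd_model(fi_top)
  ulod <- fivepl_inverse(fi_ulod, p)
  if (!is.finite(ulod) || ulod <= 0 || fi_ulod <= p$lower) {
    ulod <- curve$support[2]
    curve$flags <- c(curve$flags, "ulod_at_support_bound")
  }
  ulod <- min(ulod, curve$support[2])

  cv <- sd_model(fivepl(grid, p)) / (fivepl_deriv(grid, p) * grid)
  okcv <- is.finite(cv) & cv <= cv_limit
  if (any(okcv)) {
    lloq <- grid[which(okcv)[1]]
    uloq <- grid[rev(which(okcv))[1]]
  } else {
    lloq <- curve$support[1]
    uloq <- curve$support[2]
    curve$flags <- c(curve$flags, "loq_undefined")
  }
  lloq <- max(lloq, llod)
  uloq <- min(uloq, ulod)
  if (lloq >= uloq) {
    curve$flags <- c(curve$flags, "degenerate_loq_window")
    lloq <- llod
    uloq <- ulod
  }
  curve$llod <- llod; curve$ulod <- ulod
  curve$lloq <- lloq; curve$uloq <- uloq
  curve
}

#' Convert fluorescence to concentration
#'
#' Applies the closed-form inverse 5PL. FI at or above the curve's value at
#' ULOD is capped at ULOD (`status = "capped_ulod"`); back-calculated
#' concentrations below LLOD (including FI at or below the lower asymptote)
#' are marked `"below_llod"` with `conc = NA`, pending censored imputation;
#' non-finite FI is flagged, not fatal.
#'
#' @param fi_table Data frame with at least `sample_id` and `fi` (rows for
#'   one cytokine).
#' @param curve A `standard_curve` with limits populated.
#' @return Data frame `sample_id`, `cytokine`, `conc`, `status`, `log_conc`.
#' @export
fi_to_concentration <- function(fi_table, curve) {
  if (!is.finite(curve$llod) || !is.finite(curve$ulod)) {
    stop("curve limits must be populated before conversion")
  }
  conc <- fivepl_inverse(fi_table$fi, curve$params)
  status <- rep("quantified", nrow(fi_table))
  status[!is.finite(fi_table$fi)] <- "flagged_nonfinite"
  capped <- is.finite(conc) & conc > curve$ulod
  capped[is.infinite(conc)] <- TRUE
  status[capped & status == "quantified"] <- "capped_ulod"
  conc[capped] <- curve$ulod
  low <- !capped & (!is.finite(conc) | conc < curve$llod)
  low[status == "flagged_nonfinite"] <- FALSE
  status[low] <- "below_llod"
  conc[low | status == "flagged_nonfinite"] <- NA_real_
  data.frame(
    sample_id = fi_table$sample_id,
    cytokine = curve$cytokine,
    conc = conc,
    status = status,
    log_conc = log(conc),
    stringsAsFactors = FALSE
  )
}
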