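# Multiplex immunoassay forward model: 5PL response curves, lot and plate
# multiplicative artifacts on fluorescence intensity (FI), power-law
# heteroscedastic noise, bridge samples re-assayed in the reference lot, and
# duplicate standards and blanks on every plate.

#' Five-parameter logistic response
#'
#' The asymmetric sigmoid standard in immunoassay calibration, parameterised
#' in log concentration: `FI = lower + (upper - lower) /
#' (1 + exp(-slope * (log(conc) - infl_log)))^asym`. Strictly increasing in
#' concentration for positive `slope` and `asym`; `asym = 1` gives the 4PL.
#'
#' @param conc Concentrations (> 0; `conc = 0` returns the lower asymptote).
#' @param params List or named vector with `lower`, `slope`, `infl_log`,
#'   `upper`, `asym`.
#' @return Fluorescence intensities.
#' @export
fivepl <- function(conc, params) {
  p <- as.list(params)
  t <- suppressWarnings(log(conc))
  fi <- p$lower + (p$upper - p$lower) /
    (1 + exp(-p$slope * (t - p$infl_log)))^p$asym
  fi[conc <= 0] <- p$lower
  fi
}

#' Invert a 5PL curve
#'
#' Closed-form inverse of [fivepl()]. FI at or below the lower asymptote maps
#' to 0, FI at or above the upper asymptote to `Inf`; callers translate these
#' to censoring states.
#'
#' @param fi Fluorescence intensities.
#' @param params 5PL parameters as in [fivepl()].
#' @return Concentrations.
#' @export
fivepl_inverse <- function(fi, params) {
  p <- as.list(params)
  out <- rep(NA_real_, length(fi))
  out[!is.na(fi) & fi <= p$lower] <- 0
  out[!is.na(fi) & fi >= p$upper] <- Inf
  mid <- !is.na(fi) & fi > p$lower & fi < p$upper
  if (any(mid)) {
    ratio <- ((p$upper - p$lower) / (fi[mid] - p$lower))^(1 / p$asym) - 1
    out[mid] <- exp(p$infl_log - log(ratio) / p$slope)
  }
  out
}

# dFI/dconc, used for back-calculated concentration CV in limit estimation.
fivepl_deriv <- function(conc, params) {
  p <- as.list(params)
  t <- log(conc)
  u <- exp(-p$slope * (t - p$infl_log))
  dfi_dt <- (p$upper - p$lower) * p$asym * (1 + u)^(-p$asym - 1) * p$slope * u
  dfi_dt / conc
}

#' Default assay configuration
#'
#' Two reagent lots (L1 the reference), five plates per lot, per-cytokine
#' lot offsets (log-scale SD 0.15) and plate offsets (SD 0.08), power
#' variance noise `var(FI) = theta0 * mean(FI)^theta1` with defaults
#' theta0 = 0.01, theta1 = 1.8 (roughly 5% CV mid-curve), eight bridge
#' samples per non-reference lot, and eight-point four-fold standard series
#' in duplicate per plate. Per-cytokine 5PL truth is centred on each
#' template's dynamic range.
#'
#' @param templates `trajectory_templates` object (for curve placement).
#' @param seed Integer seed for offset draws.
#' @return Named list of assay parameters.
#' @export
default_assay_config <- function(templates, seed = 1L) {
  cyt <- templates$cytokine
  curve_params <- lapply(seq_along(cyt), function(k) {
    list(lower = 30, slope = 1.2,
         infl_log = templates$baseline_log[k] + templates$amplitude_log[k] / 2,
         upper = 20000, asym = 1)
  })
  names(curve_params) <- cyt
  with_seed(derive_seed(seed, "assay"), {
    lot_offsets <- list(
      L1 = stats::setNames(rep(0, length(cyt)), cyt),
      L2 = stats::setNames(stats::rnorm(length(cyt), 0, 0.15), cyt)
    )
  })
  list(
    lots = c("L1", "L2"),
    reference_lot = "L1",
    lot_of_cohort = c(C1 = "L1", C2 = "L1", C3 = "L1", C4 = "L2", C5 = "L2"),
    lot_offsets = lot_offsets,
    plates_per_lot = 5,
    plate_offset_sd = 0.08,
    theta = c(0.01, 1.8),
    bridge_n = 8,
    n_standards = 8,
    standard_dilution = 4,
    standard_top_log_offset = 3.0,
    anchors = list(L1 = list(cohort = "C2", visit = 1),
                   L2 = list(cohort = "C5", visit = 1)),
    curve_params = curve_params
  )
}

#' Simulate the multiplex assay readout
#'
#' Applies the forward model to true concentrations: `FI =
#' 5PL(conc) * exp(lot offset + plate offset) + noise`, with
#' `var(noise) = theta0 * mean^theta1`. Samples are randomized across plates
#' within their cohort's lot, except the per-lot anchor set (one cohort, one
#' visit) which is distributed round-robin so every plate carries anchors.
#' Bridge samples from each non-reference lot are additionally re-assayed in
#' the reference lot. Each plate carries duplicate standards and blanks.
#'
#' @param true_conc Output of [simulate_concentrations()].
#' @param samples Sample table from [generate_cohort()].
#' @param participants Participant table from [generate_cohort()].
#' @param assay Assay configuration ([default_assay_config()]).
#' @param seed Integer seed.
#' @return List: `fi_long` (per-well FI with role flags), `bridge_manifest`,
#'   `standards` (duplicate standard curves per plate), `blanks`.
#' @export
simulate_assay_fi <- function(true_conc, samples, participants, assay,
                              seed = 1L) {
  theta <- assay$theta
  if (theta[1] < 0 || theta[2] < 0) stop("theta must satisfy theta0>=0, theta1>=0")
  for (cp in assay$curve_params) {
    if (cp$slope <= 0 || cp$asym <= 0 || cp$upper <= cp$lower) {
      stop("invalid 5PL parameters: curve must be monotone between asymptotes")
    }
  }
  with_seed(derive_seed(seed, "assay") + 7L, {
    cohort_of <- stats::setNames(participants$cohort, participants$id)
    lot_of_sample <- unname(
      assay$lot_of_cohort[cohort_of[samples$participant_id]]
    )
    # plate count per lot never exceeds the available anchor samples, so
    # every plate can carry at least one anchor for intra-lot correction
    plate_ids <- lapply(assay$lots, function(l) {
      anc <- assay$anchors[[l]]
      in_lot <- lot_of_sample == l
      n_anchor <- sum(in_lot &
                        cohort_of[samples$participant_id] == anc$cohort &
                        samples$visit == anc$visit)
      n_plates <- max(1, min(assay$plates_per_lot, n_anchor))
      sprintf("%s-P%d", l, seq_len(n_plates))
    })
    names(plate_ids) <- assay$lots
    plate_offsets <- list()
    cyt <- names(assay$curve_params)
    for (l in assay$lots) {
      npl <- length(plate_ids[[l]])
      po <- matrix(stats::rnorm(npl * length(cyt), 0, assay$plate_offset_sd),
                   npl, length(cyt),
                   dimnames = list(plate_ids[[l]], cyt))
      plate_offsets[[l]] <- po
    }

    # plate assignment: anchors round-robin, everything else random
    plate_of_sample <- character(nrow(samples))
    for (l in assay$lots) {
      in_lot <- which(lot_of_sample == l)
      if (length(in_lot) == 0) next
      anc <- assay$anchors[[l]]
      is_anchor <- cohort_of[samples$participant_id[in_lot]] == anc$cohort &
        samples$visit[in_lot] == anc$visit
      anchor_idx <- in_lot[is_anchor]
      other_idx <- in_lot[!is_anchor]
      pl <- plate_ids[[l]]
      if (length(anchor_idx) > 0) {
        plate_of_sample[anchor_idx] <-
          pl[(seq_along(anchor_idx) - 1) %% length(pl) + 1]
      }
      if (length(other_idx) > 0) {
        plate_of_sample[other_idx] <- sample(pl, length(other_idx),
                                             replace = TRUE)
      }
    }

    noisy_fi <- function(mean_fi) {
      sd <- sqrt(theta[1] * pmax(mean_fi, 0)^theta[2])
      pmax(mean_fi + stats::rnorm(length(mean_fi)) * sd, 0.5)
    }
    measure <- function(conc, cytokine, lot, plate) {
      mu <- fivepl(conc, assay$curve_params[[cytokine]]) *
        exp(assay$lot_offsets[[lot]][cytokine] +
              plate_offsets[[lot]][plate, cytokine])
      noisy_fi(mu)
    }

    # bridge selection: bridge_n samples per non-reference lot, re-assayed
    # on a rotating plate of the reference lot
    ref <- assay$reference_lot
    bridge_rows <- list()
    for (l in setdiff(assay$lots, ref)) {
      in_lot <- which(lot_of_sample == l)
      if (length(in_lot) < assay$bridge_n) {
        stop("lot ", l, " has fewer samples than bridge_n")
      }
      pick <- sample(in_lot, assay$bridge_n)
      bridge_rows[[l]] <- data.frame(
        sample_id = samples$sample_id[pick],
        origin_lot = l,
        reference_lot = ref,
        reference_plate = plate_ids[[ref]][
          (seq_along(pick) - 1) %% length(plate_ids[[ref]]) + 1],
        stringsAsFactors = FALSE
      )
    }
    bridge_manifest <- if (length(bridge_rows) > 0) {
      do.call(rbind, bridge_rows)
    } else {
      data.frame(sample_id = character(), origin_lot = character(),
                 reference_lot = character(), reference_plate = character())
    }

    # sample wells
    fi_rows <- vector("list", length(cyt))
    for (k in seq_along(cyt)) {
      ck <- cyt[k]
      conc_k <- true_conc[true_conc$cytokine == ck, ]
      conc_k <- conc_k[match(samples$sample_id, conc_k$sample_id), ]
      fi <- numeric(nrow(samples))
      for (l in assay$lots) {
        in_lot <- lot_of_sample == l
        if (any(in_lot)) {
          fi[in_lot] <- measure(conc_k$true_conc[in_lot], ck, l,
                                plate_of_sample[in_lot])
        }
      }
      df <- data.frame(
        sample_id = samples$sample_id, cytokine = ck, fi = fi,
        lot_id = lot_of_sample, plate_id = plate_of_sample,
        role = "sample", stringsAsFactors = FALSE
      )
      # bridge re-assays in the reference lot
      if (nrow(bridge_manifest) > 0) {
        bm <- bridge_manifest
        bconc <- conc_k$true_conc[match(bm$sample_id, samples$sample_id)]
        bfi <- measure(bconc, ck, ref, bm$reference_plate)
        df <- rbind(df, data.frame(
          sample_id = bm$sample_id, cytokine = ck, fi = bfi,
          lot_id = ref, plate_id = bm$reference_plate,
          role = "bridge", stringsAsFactors = FALSE
        ))
      }
      fi_rows[[k]] <- df
    }
    fi_long <- do.call(rbind, fi_rows)
    fi_long$well <- sprintf("W%05d", seq_len(nrow(fi_long)))

    # duplicate standards and blanks on every plate
    std_rows <- list(); blank_rows <- list()
    for (l in assay$lots) {
      for (pl in plate_ids[[l]]) {
        for (ck in cyt) {
          cp <- assay$curve_params[[ck]]
          top <- exp(cp$infl_log + assay$standard_top_log_offset)
          conc <- top / assay$standard_dilution^(seq_len(assay$n_standards) - 1)
          conc2 <- rep(conc, each = 2)
          std_rows[[length(std_rows) + 1]] <- data.frame(
            cytokine = ck, conc = conc2,
            fi = measure(conc2, ck, l, pl),
            lot_id = l, plate_id = pl,
            replicate = rep(1:2, times = assay$n_standards),
            stringsAsFactors = FALSE
          )
          blank_rows[[length(blank_rows) + 1]] <- data.frame(
            cytokine = ck, fi = measure(c(0, 0), ck, l, pl),
            lot_id = l, plate_id = pl, replicate = 1:2,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    list(
      fi_long = fi_long,
      bridge_manifest = bridge_manifest,
      standards = do.call(rbind, std_rows),
      blanks = do.call(rbind, blank_rows)
    )
  })
}
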