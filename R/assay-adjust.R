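# Fluorescence-intensity batch correction, performed on FI before
# calibration: inter-lot adjustment anchored on bridge samples re-assayed in
# a reference lot, then intra-lot (plate-to-plate) adjustment anchored on a
# set of samples expected to be equal on group level. Both are multiplicative
# shifts on FI, i.e. additive on log FI:
#   adjusted FI_i = exp(log FI_i - mean(log FI, source set) + mean(log FI, target set))

#' Inter-lot adjustment factor from bridge samples
#'
#' The correction factor for one non-reference lot and one cytokine:
#' `delta_log = mean(log FI of the bridge samples re-assayed in the
#' reference lot) - mean(log FI of the same samples in their origin lot)`.
#' Multiplying origin-lot FI by `exp(delta_log)` moves the lot onto the
#' reference lot's scale.
#'
#' @param bridge_fi_origin Data frame (`sample_id`, `fi`): bridge samples as
#'   measured in their origin lot.
#' @param bridge_fi_reference Data frame (`sample_id`, `fi`): the same
#'   samples re-assayed in the reference lot.
#' @param cytokine Analyte name (carried into the output).
#' @param lot_id Origin lot id (carried into the output).
#' @return One-row data frame: `scope`, `lot_id`, `cytokine`, `delta_log`, `n`.
#' @export
compute_inter_lot_adjustment <- function(bridge_fi_origin, bridge_fi_reference,
                                         cytokine = NA_character_,
                                         lot_id = NA_character_) {
  if (nrow(bridge_fi_origin) == 0 || nrow(bridge_fi_reference) == 0) {
    stop("bridge sets must be non-empty")
  }
  if (!setequal(bridge_fi_origin$sample_id, bridge_fi_reference$sample_id)) {
    stop("bridge sample identities differ between origin and reference sets")
  }
  if (any(bridge_fi_origin$fi <= 0) || any(bridge_fi_reference$fi <= 0)) {
    stop("bridge FI values must be positive")
  }
  ref <- bridge_fi_reference[match(bridge_fi_origin$sample_id,
                                   bridge_fi_reference$sample_id), ]
  data.frame(
    scope = "inter_lot", lot_id = lot_id, cytokine = cytokine,
    delta_log = mean(log(ref$fi)) - mean(log(bridge_fi_origin$fi)),
    n = nrow(bridge_fi_origin),
    stringsAsFactors = FALSE
  )
}

#' Apply inter-lot correction to an FI table
#'
#' Computes bridge-based adjustment factors for every (non-reference lot,
#' cytokine) pair and rescales all FI measured in non-reference lots. Bridge
#' re-assay rows (role `bridge`, measured in the reference lot) are left
#' untouched and serve only to define the factors.
#'
#' @param fi_long Long FI table (`sample_id`, `cytokine`, `fi`, `lot_id`,
#'   `plate_id`, `role`).
#' @param bridge_manifest Data frame `sample_id`, `origin_lot` naming the
#'   bridge samples.
#' @param reference_lot Reference lot id.
#' @return List: `fi` (adjusted table), `factors` (adjustment factor table).
#' @export
apply_inter_lot_adjustment <- function(fi_long, bridge_manifest,
                                       reference_lot) {
  stopifnot(all(c("sample_id", "cytokine", "fi", "lot_id", "role")
                %in% names(fi_long)))
  lots <- setdiff(unique(fi_long$lot_id), reference_lot)
  factors <- list()
  out <- fi_long
  for (l in lots) {
    ids <- bridge_manifest$sample_id[bridge_manifest$origin_lot == l]
    if (length(ids) == 0) {
      stop("no bridge samples for non-reference lot ", l)
    }
    for (ck in unique(fi_long$cytokine)) {
      orig <- fi_long[fi_long$lot_id == l & fi_long$cytokine == ck &
                        fi_long$sample_id %in% ids &
                        fi_long$role == "sample", c("sample_id", "fi")]
      refm <- fi_long[fi_long$lot_id == reference_lot &
                        fi_long$cytokine == ck &
                        fi_long$sample_id %in% ids &
                        fi_long$role == "bridge", c("sample_id", "fi")]
      fac <- compute_inter_lot_adjustment(orig, refm, cytokine = ck,
                                          lot_id = l)
      factors[[length(factors) + 1]] <- fac
      sel <- out$lot_id == l & out$cytokine == ck
      out$fi[sel] <- out$fi[sel] * exp(fac$delta_log)
    }
  }
  ref_factors <- data.frame(
    scope = "inter_lot", lot_id = reference_lot,
    cytokine = unique(fi_long$cytokine), delta_log = 0, n = NA_integer_,
    stringsAsFactors = FALSE
  )
  list(fi = out, factors = rbind(do.call(rbind, c(factors, list(NULL))),
                                 ref_factors))
}

#' Intra-lot (plate-to-plate) adjustment
#'
#' Within each lot and cytokine, plate effects are removed using an anchor
#' set of samples expected to be equal on group level (one cohort, sampled at
#' approximately the same gestational age, randomized across plates):
#' `adjusted FI = exp(log FI - plate mean log FI of anchors + lot-wide mean
#' log FI of anchors)`. After adjustment the per-plate anchor means of log FI
#' equal the lot-wide anchor mean.
#'
#' @param fi_long Long FI table as in [apply_inter_lot_adjustment()].
#' @param anchor_ids Character vector of anchor `sample_id`s, or a named list
#'   of such vectors keyed by lot id.
#' @return List: `fi` (adjusted table), `factors` (per lot/plate/cytokine
#'   `delta_log` applied).
#' @export
apply_intra_lot_adjustment <- function(fi_long, anchor_ids) {
  out <- fi_long
  factors <- list()
  for (l in unique(fi_long$lot_id)) {
    ids <- if (is.list(anchor_ids)) anchor_ids[[l]] else anchor_ids
    if (is.null(ids) || length(ids) == 0) {
      stop("no anchor samples supplied for lot ", l)
    }
    in_lot <- fi_long$lot_id == l
    plates <- unique(fi_long$plate_id[in_lot])
    for (ck in unique(fi_long$cytokine[in_lot])) {
      sel_anchor <- in_lot & fi_long$cytokine == ck &
        fi_long$sample_id %in% ids & fi_long$role %in% c("sample", "bridge")
      if (!any(sel_anchor)) next
      lot_mean <- mean(log(fi_long$fi[sel_anchor]))
      for (pl in plates) {
        on_plate <- sel_anchor & fi_long$plate_id == pl
        if (!any(on_plate)) {
          stop("plate ", pl, " in lot ", l,
               " carries no anchor samples for ", ck)
        }
        delta <- lot_mean - mean(log(fi_long$fi[on_plate]))
        sel_adj <- in_lot & fi_long$cytokine == ck &
          fi_long$plate_id == pl & fi_long$role %in% c("sample", "bridge")
        out$fi[sel_adj] <- out$fi[sel_adj] * exp(delta)
        factors[[length(factors) + 1]] <- data.frame(
          scope = "intra_lot", lot_id = l, plate_id = pl, cytokine = ck,
          delta_log = delta, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(fi = out, factors = do.call(rbind, c(factors, list(NULL))))
}
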