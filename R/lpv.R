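# Treatment-detection rules: given a possible-ARDS event, check the current
# ventilator settings and protocol orders against the computerized
# ventilation/oxygenation protocols and emit typed recommendations. Exactly
# nine recommendation types exist, in two categories: seven promote adoption
# of the computerized protocols, two address a specific setting.

REC_TYPES <- c(
  protocols_not_ordered            = "adopt_protocol",
  cpap_ps_inappropriate            = "adopt_protocol",
  change_to_volume_control         = "adopt_protocol",
  nonstandard_mode                 = "adopt_protocol",
  ventilation_protocol_not_ordered = "adopt_protocol",
  noncompliant_mode                = "adopt_protocol",
  oxygenation_protocol_not_ordered = "adopt_protocol",
  peep_fio2_inappropriate          = "specific_setting",
  tidal_volume_too_large           = "specific_setting"
)

#' Recommendation type taxonomy
#'
#' @return Data frame mapping the nine recommendation types to their
#'   category (`adopt_protocol` or `specific_setting`).
#' @export
recommendation_types <- function() {
  data.frame(rec_type = names(REC_TYPES), category = unname(REC_TYPES),
             stringsAsFactors = FALSE)
}

new_recommendation <- function(rec_type, evidence, created_at) {
  stopifnot(rec_type %in% names(REC_TYPES))
  list(rec_type = rec_type, category = unname(REC_TYPES[[rec_type]]),
       evidence = evidence, created_at = created_at)
}

#' Predicted body weight (Devine)
#'
#' PBW in kg: males `50 + 0.91 * (height - 152.4)`, females
#' `45.5 + 0.91 * (height - 152.4)`, floored at 20 kg. Undefined (NA) when
#' sex or height is missing — tidal-volume checks are then skipped, never
#' guessed.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param height Height in cm; plausible range \[120, 230\].
#' @return Numeric vector of kg.
#' @examples
#' predicted_body_weight("male", 175)  # 70.57
#' @export
predicted_body_weight <- function(sex, height) {
  n <- max(length(sex), length(height))
  sex <- rep_len(sex, n); height <- rep_len(height, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(sex) & !is.na(height) & sex %in% c("male", "female")
  if (any(!is.na(height) & (height < 120 | height > 230)))
    stop("height outside plausible range [120, 230] cm", call. = FALSE)
  base <- ifelse(sex[ok] == "male", 50, 45.5)
  out[ok] <- pmax(20, base + 0.91 * (height[ok] - 152.4))
  out
}

#' Tidal volume check
#'
#' Fires `tidal_volume_too_large` when tidal volume strictly exceeds
#' `vt_per_pbw_max` mL per kg predicted body weight.
#'
#' @param tidal_volume Set tidal volume, mL.
#' @param pbw Predicted body weight, kg (must be defined; see
#'   [predicted_body_weight()]).
#' @param created_at Timestamp for the emitted recommendation.
#' @param cfg A [cds_config()].
#' @return A recommendation (list) or `NULL` when adherent.
#' @export
check_tidal_volume <- function(tidal_volume, pbw, created_at,
                               cfg = cds_config()) {
  if (is.na(pbw)) stop("PBW undefined; skip the tidal-volume check",
                       call. = FALSE)
  if (is.na(tidal_volume)) return(NULL)
  ratio <- tidal_volume / pbw
  if (ratio > cfg$vt_per_pbw_max)
    return(new_recommendation("tidal_volume_too_large",
                              sprintf("Vt %.0f mL at PBW %.1f kg = %.2f mL/kg (limit %.1f)",
                                      tidal_volume, pbw, ratio,
                                      cfg$vt_per_pbw_max),
                              created_at))
  NULL
}

#' PEEP/FiO2 combination check
#'
#' The charted FiO2 is mapped to the nearest grid level not above it (the
#' lowest level when charted FiO2 sits below the grid floor); the
#' combination is adherent when the charted PEEP lies within
#' `peep_tolerance` cmH2O of any allowed PEEP at that level.
#'
#' @param peep Charted PEEP, cmH2O.
#' @param fio2 Charted FiO2 fraction.
#' @param created_at Timestamp for the emitted recommendation.
#' @param cfg A [cds_config()]; selects the grid via `peep_strategy`.
#' @return A recommendation or `NULL` when adherent.
#' @export
check_peep_fio2 <- function(peep, fio2, created_at, cfg = cds_config()) {
  if (is.na(peep) || is.na(fio2)) return(NULL)
  grid <- cfg$peep_fio2_grids[[cfg$peep_strategy]]
  levels <- vapply(grid, function(r) r$fio2, numeric(1))
  idx <- which(levels <= fio2 + 1e-9)
  level <- if (length(idx)) max(idx) else 1L
  allowed <- grid[[level]]$peep
  if (min(abs(peep - allowed)) <= cfg$peep_tolerance + 1e-9) return(NULL)
  new_recommendation("peep_fio2_inappropriate",
                     sprintf("PEEP %g at FiO2 %.2f; allowed at level %.2f: %s (+/-%g)",
                             peep, fio2, grid[[level]]$fio2,
                             paste(allowed, collapse = ","),
                             cfg$peep_tolerance),
                     created_at)
}

#' Ventilator-mode rules
#'
#' CPAP/PS-class modes are inappropriate when PEEP > 10 cmH2O, FiO2 > 0.50
#' or PS > 15 cmH2O (any branch); an inappropriate CPAP/PS additionally
#' carries the companion advice to change to volume control per the
#' ventilation protocol. Non-spontaneous modes are checked against the
#' configured mode classes: modes outside the standard set fire
#' `nonstandard_mode`, standard-but-not-compliant modes fire
#' `noncompliant_mode`; compliant modes pass.
#'
#' @param mode Charted ventilator mode (character).
#' @param peep,fio2,pressure_support Current settings (used for the CPAP/PS
#'   limits).
#' @param created_at Timestamp for emitted recommendations.
#' @param cfg A [cds_config()].
#' @return List of recommendations (possibly empty).
#' @export
check_mode_rules <- function(mode, peep, fio2, pressure_support, created_at,
                             cfg = cds_config()) {
  recs <- list()
  if (is.na(mode)) return(recs)
  lim <- cfg$cpap_ps_limits
  if (mode %in% cfg$spontaneous_modes) {
    branches <- c(
      if (!is.na(peep) && peep > lim$peep) sprintf("PEEP %g > %g", peep, lim$peep),
      if (!is.na(fio2) && fio2 > lim$fio2 + 1e-9)
        sprintf("FiO2 %.2f > %.2f", fio2, lim$fio2),
      if (!is.na(pressure_support) && pressure_support > lim$ps)
        sprintf("PS %g > %g", pressure_support, lim$ps))
    if (length(branches)) {
      ev <- paste("CPAP/PS with", paste(branches, collapse = "; "))
      recs <- c(recs,
                list(new_recommendation("cpap_ps_inappropriate", ev, created_at),
                     new_recommendation("change_to_volume_control", ev,
                                        created_at)))
    }
  } else if (mode %in% cfg$compliant_modes) {
    # adherent mode
  } else if (mode %in% cfg$noncompliant_modes) {
    recs <- c(recs, list(new_recommendation(
      "noncompliant_mode", sprintf("mode `%s` not health-system compliant", mode),
      created_at)))
  } else {
    recs <- c(recs, list(new_recommendation(
      "nonstandard_mode", sprintf("nonstandard mode `%s`", mode), created_at)))
  }
  recs
}

#' Protocol-order check
#'
#' Emits the combined `protocols_not_ordered` when neither the computerized
#' ventilation nor the oxygenation protocol has been ordered, otherwise the
#' specific single-protocol recommendation; outputs are mutually exclusive.
#'
#' @param ventilation_ordered,oxygenation_ordered Logicals.
#' @param created_at Timestamp for emitted recommendations.
#' @return List of recommendations (possibly empty).
#' @export
check_protocol_orders <- function(ventilation_ordered, oxygenation_ordered,
                                  created_at) {
  if (!ventilation_ordered && !oxygenation_ordered)
    return(list(new_recommendation("protocols_not_ordered",
                                   "neither protocol ordered", created_at)))
  if (!ventilation_ordered)
    return(list(new_recommendation("ventilation_protocol_not_ordered",
                                   "ventilation protocol not ordered",
                                   created_at)))
  if (!oxygenation_ordered)
    return(list(new_recommendation("oxygenation_protocol_not_ordered",
                                   "oxygenation protocol not ordered",
                                   created_at)))
  list()
}

#' Assess lung-protective-ventilation adherence for a possible-ARDS event
#'
#' Re-checks the qualifying physiology (adjusted P/F at or below threshold),
#' then aggregates every applicable recommendation from the order, mode,
#' PEEP/FiO2 and tidal-volume checks. The event is LPV-adherent exactly when
#' no recommendation applies. With no ventilator settings ever charted the
#' adherence status is indeterminate and no event is emitted. Tidal-volume
#' checks are skipped (and flagged) when predicted body weight is undefined.
#'
#' @param state Encounter state list with elements `attrs`, `settings`
#'   (latest vent settings or `NULL`), `vent_ordered`, `oxy_ordered`,
#'   `last_pf_adjusted`.
#' @param now POSIXct evaluation time.
#' @param cfg A [cds_config()].
#' @return List with `status` (`"adherent"`, `"nonadherent"`,
#'   `"indeterminate"`, `"not_qualifying"`), `recommendations` (list) and
#'   `skipped_checks` (character).
#' @export
assess_lpv <- function(state, now, cfg = cds_config()) {
  if (is.na(state$last_pf_adjusted) ||
      state$last_pf_adjusted > cfg$pf_threshold)
    return(list(status = "not_qualifying", recommendations = list(),
                skipped_checks = character(0)))
  if (is.null(state$settings))
    return(list(status = "indeterminate", recommendations = list(),
                skipped_checks = "no_vent_settings"))
  s <- state$settings
  skipped <- character(0)
  recs <- check_protocol_orders(isTRUE(state$vent_ordered),
                                isTRUE(state$oxy_ordered), now)
  recs <- c(recs, check_mode_rules(s$mode, s$peep, s$fio2,
                                   s$pressure_support, now, cfg))
  r <- check_peep_fio2(s$peep, s$fio2, now, cfg)
  if (!is.null(r)) recs <- c(recs, list(r))
  pbw <- tryCatch(predicted_body_weight(state$attrs$sex, state$attrs$height),
                  error = function(e) NA_real_)
  if (is.na(pbw)) {
    skipped <- c(skipped, "tidal_volume_pbw_undefined")
  } else {
    r <- check_tidal_volume(s$tidal_volume, pbw, now, cfg)
    if (!is.null(r)) recs <- c(recs, list(r))
  }
  list(status = if (length(recs)) "nonadherent" else "adherent",
       recommendations = recs, skipped_checks = skipped)
}
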