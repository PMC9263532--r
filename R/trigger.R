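# Trigger detection: a newly charted PaO2 or a new chest radiograph starts
# one evaluation cycle. The trigger fires when every inclusion criterion
# holds and no exclusion criterion applies; otherwise the event is recorded
# as excluded with the full reason list.

#' Compute the (altitude-adjusted) PaO2/FiO2 ratio
#'
#' @param pao2 Arterial oxygen partial pressure, mmHg (> 0).
#' @param fio2 Inspired oxygen fraction in [0.21, 1.0].
#' @param barometric_pressure Site barometric pressure, mmHg. The adjusted
#'   ratio is `pf_ratio * 760 / barometric_pressure`.
#' @return List with `pf_ratio` and `pf_ratio_adjusted`.
#' @examples
#' compute_pf_ratio(82, 0.40)                       # 205
#' compute_pf_ratio(82, 0.40, 646)$pf_ratio_adjusted  # ~241.2
#' @export
compute_pf_ratio <- function(pao2, fio2, barometric_pressure = 760) {
  stopifnot(is.numeric(pao2), all(pao2 > 0),
            is.numeric(fio2), all(fio2 >= 0.21 - 1e-9), all(fio2 <= 1 + 1e-9),
            barometric_pressure > 0)
  ratio <- pao2 / fio2
  list(pf_ratio = ratio,
       pf_ratio_adjusted = ratio * 760 / barometric_pressure)
}

#' Evaluate trigger inclusion criteria
#'
#' Inclusion requires: age at least `min_age` years; a ventilator mode
#' charted strictly less than `vent_mode_window_hours` before `now`; an
#' altitude-adjusted P/F ratio at or below `pf_threshold`; intubation within
#' the last `intubation_window_hours`. Every failed criterion is returned,
#' not only the first. A patient charted as intubated with no intubation
#' time on record fails the intubation criterion with reason
#' `intubation_time_unknown`.
#'
#' @param attrs Named list of patient attributes (from the admission event).
#' @param pf_adjusted Altitude-adjusted P/F ratio (may be `NA` if no
#'   physiology is computable — the criterion then fails).
#' @param last_mode_time POSIXct time the ventilator mode was last charted,
#'   or `NA`.
#' @param now POSIXct evaluation time.
#' @param cfg A [cds_config()].
#' @return List with `pass` (logical) and `failed` (character reasons).
#' @export
evaluate_inclusion <- function(attrs, pf_adjusted, last_mode_time, now, cfg) {
  failed <- character(0)
  if (is.na(attrs$age) || attrs$age < cfg$min_age)
    failed <- c(failed, "age_below_minimum")
  if (is.na(last_mode_time) ||
      hours_between(last_mode_time, now) >= cfg$vent_mode_window_hours)
    failed <- c(failed, "vent_mode_not_recent")
  if (is.na(pf_adjusted) || pf_adjusted > cfg$pf_threshold)
    failed <- c(failed, "pf_ratio_above_threshold")
  it <- attrs$intubation_time
  if (is.null(it) || is.na(it)) {
    failed <- c(failed, "intubation_time_unknown")
  } else if (hours_between(it, now) > cfg$intubation_window_hours) {
    failed <- c(failed, "intubation_window_exceeded")
  }
  list(pass = length(failed) == 0L, failed = failed)
}

#' Evaluate trigger exclusion criteria
#'
#' Exclusions: pediatric ICU; palliative care; cardiothoracic-surgery
#' attending; ventricular assist device or other mechanical circulatory
#' support; spontaneous breathing via T-piece or tracheostomy mask; presence
#' of a pulmonary artery catheter. All applicable reasons are returned.
#'
#' @param attrs Named list of patient attributes.
#' @return List with `excluded` (logical) and `reasons` (character).
#' @export
evaluate_exclusion <- function(attrs) {
  reasons <- character(0)
  if (!is.na(attrs$care_unit) && attrs$care_unit == "picu")
    reasons <- c(reasons, "picu")
  if (isTRUE(attrs$palliative_care))
    reasons <- c(reasons, "palliative_care")
  if (!is.null(attrs$attending_specialty) &&
      !is.na(attrs$attending_specialty) &&
      grepl("cardiothoracic", attrs$attending_specialty, ignore.case = TRUE))
    reasons <- c(reasons, "cardiothoracic_attending")
  if (isTRUE(attrs$on_mcs))
    reasons <- c(reasons, "mechanical_circulatory_support")
  if (!is.na(attrs$airway_status) &&
      attrs$airway_status %in% c("t_piece", "trach_mask"))
    reasons <- c(reasons, "t_piece_or_trach_mask")
  if (isTRUE(attrs$pa_catheter))
    reasons <- c(reasons, "pa_catheter")
  list(excluded = length(reasons) > 0L, reasons = reasons)
}

hours_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

# Evaluate one potential trigger event against the running encounter state.
# `state` is the engine's per-encounter state list (see run_cds_engine);
# returns NULL when the event is not a trigger cause or no physiology is
# computable, otherwise a one-row trigger record.
trigger_process_event <- function(event, state, cfg) {
  cause <- switch(event$type,
                  blood_gas = "new_pao2",
                  radiograph = "new_chest_xray",
                  return(NULL))
  if (cause == "new_pao2") {
    if (is.na(state$last_fio2)) return(NULL)  # no FiO2 ever charted
    phys <- compute_pf_ratio(event$pao2, state$last_fio2,
                             cfg$barometric_pressure)
  } else {
    if (is.na(state$last_pf)) return(NULL)    # no P/F computable yet
    phys <- list(pf_ratio = state$last_pf,
                 pf_ratio_adjusted = state$last_pf_adjusted)
  }
  if (is.null(state$attrs)) return(NULL)      # no admission charted
  inc <- evaluate_inclusion(state$attrs, phys$pf_ratio_adjusted,
                            state$last_mode_time, event$time, cfg)
  exc <- evaluate_exclusion(state$attrs)
  fired <- inc$pass && !exc$excluded
  list(encounter_id = event$encounter_id,
       time = event$time,
       cause = cause,
       pf_ratio = phys$pf_ratio,
       pf_ratio_adjusted = phys$pf_ratio_adjusted,
       decision = if (fired) "fired" else "excluded",
       reasons = c(inc$failed, exc$reasons))
}
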