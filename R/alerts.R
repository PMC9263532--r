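# Alert lifecycle: delivery on chart open to treating clinicians, a rolling
# 16-hour per-clinician evocation window, an optional chart-close reminder
# for unaddressed recommendations, and permanent per-patient suppression
# after a "not ARDS" or contraindication response. Permanent suppression is
# absorbing for the remainder of the encounter.

#' Create an empty suppression state
#'
#' @return Object of class `suppression_state`: per-patient permanent
#'   suppression flag/cause plus per-clinician last-alert times.
#' @export
new_suppression_state <- function() {
  structure(list(permanent = FALSE, cause = NA_character_,
                 suppressed_at = as.POSIXct(NA, tz = "UTC"),
                 last_alert_time = list()),
            class = "suppression_state")
}

#' Should a pending alert be delivered to this clinician now?
#'
#' Delivery requires: no permanent suppression for the patient, and either
#' no prior alert to this clinician or at least `alert_window_hours` since
#' the last one (a rolling window — "once per shift, every 16 h").
#'
#' @param state A `suppression_state`.
#' @param clinician_id Clinician identifier.
#' @param now POSIXct.
#' @param cfg A [cds_config()].
#' @return List with `deliver` (logical) and `reason`.
#' @export
should_deliver <- function(state, clinician_id, now, cfg = cds_config()) {
  if (state$permanent)
    return(list(deliver = FALSE,
                reason = paste0("permanently_suppressed:", state$cause)))
  last <- state$last_alert_time[[clinician_id]]
  if (!is.null(last) &&
      hours_between(last, now) < cfg$alert_window_hours)
    return(list(deliver = FALSE, reason = "within_16h_window"))
  list(deliver = TRUE, reason = "eligible")
}

#' Record an alert delivery
#'
#' Updates the clinician's last-alert time atomically with delivery.
#'
#' @inheritParams should_deliver
#' @return Updated `suppression_state`.
#' @export
record_alert_delivery <- function(state, clinician_id, now) {
  state$last_alert_time[[clinician_id]] <- now
  state
}

#' Record a clinician response
#'
#' `not_ards` and `contraindication` responses permanently suppress alerts
#' for the patient (all clinicians, rest of the encounter);
#' `order_protocol` / `act_on_instruction` never change suppression. A
#' contraindication must carry a structured reason (`elevated_icp`,
#' `status_asthmaticus`, `severe_copd`) or `other` with nonempty free text.
#'
#' @param state A `suppression_state`.
#' @param action One of `order_protocol`, `act_on_instruction`, `not_ards`,
#'   `contraindication`.
#' @param now POSIXct response time.
#' @param reason Contraindication reason (required when `action` is
#'   `contraindication`).
#' @param reason_text Free text, required when `reason == "other"`.
#' @return Updated `suppression_state`.
#' @export
record_response <- function(state, action, now, reason = NA_character_,
                            reason_text = NA_character_) {
  action <- match.arg(action, c("order_protocol", "act_on_instruction",
                                "not_ards", "contraindication"))
  if (action == "contraindication") {
    reason <- match.arg(reason, c("elevated_icp", "status_asthmaticus",
                                  "severe_copd", "other"))
    if (reason == "other" && (is.na(reason_text) || !nzchar(reason_text)))
      stop("contraindication reason `other` requires nonempty free text",
           call. = FALSE)
  }
  if (action %in% c("not_ards", "contraindication") && !state$permanent) {
    state$permanent <- TRUE
    state$cause <- if (action == "not_ards") "not_ards"
                   else paste0("contraindication:", reason)
    state$suppressed_at <- now
  }
  state
}

#' Render the clinician-facing alert text
#'
#' Bundles the radiographic and physiologic evidence for the possible-ARDS
#' detection with the ventilator settings or orders behind each
#' recommendation.
#'
#' @param pf_adjusted Altitude-adjusted P/F ratio at detection.
#' @param recommendations List of recommendation lists (see
#'   [recommendation_types()]).
#' @param cfg A [cds_config()].
#' @return Character scalar.
#' @export
render_alert_text <- function(pf_adjusted, recommendations,
                              cfg = cds_config()) {
  head <- sprintf(paste0(
    "Possible ARDS: bilateral infiltrates on chest radiograph report and ",
    "altitude-adjusted P/F ratio %.0f mmHg (threshold %g). ",
    "Oxygenation target PaO2 %g-%g mmHg."),
    pf_adjusted, cfg$pf_threshold, cfg$pao2_target[1], cfg$pao2_target[2])
  body <- vapply(recommendations, function(r)
    sprintf("- [%s] %s", r$rec_type, r$evidence), "")
  paste(c(head, body), collapse = "\n")
}
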