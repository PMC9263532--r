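# Single-pass engine over an ordered encounter event stream. Each
# blood-gas or radiograph charting event may start a cycle: trigger
# evaluation (inclusion/exclusion), infiltrate detection on the most recent
# radiograph report, LPV adherence assessment, and alert delivery at the
# next eligible chart-open. All intermediate decisions are written to audit
# ledgers so the run is fully replayable.

new_encounter_state <- function() {
  list(attrs = NULL,
       settings = NULL,
       last_fio2 = NA_real_,
       last_mode_time = as.POSIXct(NA, tz = "UTC"),
       last_pf = NA_real_,
       last_pf_adjusted = NA_real_,
       last_report_text = NA_character_,
       vent_ordered = FALSE,
       oxy_ordered = FALSE,
       supp = new_suppression_state(),
       pending = NULL,
       sessions = list())
}

attrs_from_event <- function(ev) {
  list(age = ev$age, sex = ev$sex, height = ev$height,
       care_unit = ev$care_unit,
       palliative_care = isTRUE(ev$palliative_care),
       attending_specialty = ev$attending_specialty,
       on_mcs = isTRUE(ev$on_mcs), pa_catheter = isTRUE(ev$pa_catheter),
       airway_status = ev$airway_status,
       intubation_time = ev$intubation_time,
       site = ev$site)
}

# does this recommendation type still apply to the current treatment state?
rec_applies_now <- function(rec_type, state, cfg) {
  s <- state$settings
  if (is.null(s)) return(TRUE)
  now <- s$time
  recs <- switch(
    rec_type,
    protocols_not_ordered = ,
    ventilation_protocol_not_ordered = ,
    oxygenation_protocol_not_ordered =
      check_protocol_orders(isTRUE(state$vent_ordered),
                            isTRUE(state$oxy_ordered), now),
    cpap_ps_inappropriate = ,
    change_to_volume_control = ,
    nonstandard_mode = ,
    noncompliant_mode =
      check_mode_rules(s$mode, s$peep, s$fio2, s$pressure_support, now, cfg),
    peep_fio2_inappropriate = {
      r <- check_peep_fio2(s$peep, s$fio2, now, cfg)
      if (is.null(r)) list() else list(r)
    },
    tidal_volume_too_large = {
      pbw <- tryCatch(predicted_body_weight(state$attrs$sex,
                                            state$attrs$height),
                      error = function(e) NA_real_)
      if (is.na(pbw)) return(TRUE)
      r <- check_tidal_volume(s$tidal_volume, pbw, now, cfg)
      if (is.null(r)) list() else list(r)
    },
    stop("unknown rec_type: ", rec_type))
  # order-type recommendations resolve on the orders themselves (the
  # combined type needs both protocols ordered), not on the re-run check,
  # whose outputs are mutually exclusive by construction
  resolved <- switch(rec_type,
    protocols_not_ordered = isTRUE(state$vent_ordered) &&
      isTRUE(state$oxy_ordered),
    ventilation_protocol_not_ordered = isTRUE(state$vent_ordered),
    oxygenation_protocol_not_ordered = isTRUE(state$oxy_ordered),
    !rec_type %in% vapply(recs, function(r) r$rec_type, ""))
  !resolved
}

#' Run the CDS alert engine over an event stream
#'
#' Processes the ordered stream one event at a time and returns the full
#' set of audit ledgers: trigger decisions with reasons, possible-ARDS
#' events with adherence status, delivered alerts with their
#' recommendations, chart-close reminders, clinician responses, suppression
#' changes, and skipped/indeterminate evaluations.
#'
#' @param events A `cds_stream` (see [as_cds_stream()] /
#'   [read_event_stream()]).
#' @param cfg A [cds_config()].
#' @param detector Classifier for radiograph report text: a function
#'   `function(report_text)` returning a `detection_result` (anything with
#'   a logical `positive` element works). Defaults to the rule-based
#'   matcher with the shipped lexicon.
#' @return Object of class `cds_run`: list of data frames `triggers`,
#'   `possible_ards`, `alerts`, `recommendations`, `responses`,
#'   `suppression`, `log`, plus the `config` used.
#' @export
run_cds_engine <- function(events, cfg = cds_config(), detector = NULL) {
  events <- if (inherits(events, "cds_stream")) events
            else as_cds_stream(events)
  if (is.null(detector)) {
    rules <- load_infiltrate_rules()
    detector <- function(text) detect_bilateral_infiltrates(text, rules)
  }

  led <- new.env(parent = emptyenv())
  led$triggers <- list(); led$possible <- list(); led$alerts <- list()
  led$recs <- list(); led$responses <- list(); led$supp <- list()
  led$log <- list()
  alert_seq <- 0L

  add <- function(name, rec) {
    led[[name]][[length(led[[name]]) + 1L]] <- rec
  }

  enc_ids <- unique(events$encounter_id)
  for (enc in enc_ids) {
    rows <- which(events$encounter_id == enc)
    state <- new_encounter_state()
    for (i in rows) {
      ev <- lapply(events, function(col) col[i])
      tp <- ev$type
      if (tp == "admission") {
        state$attrs <- attrs_from_event(ev)
      } else if (tp == "vent_settings") {
        state$settings <- list(mode = ev$mode, tidal_volume = ev$tidal_volume,
                               peep = ev$peep, fio2 = ev$fio2,
                               pressure_support = ev$pressure_support,
                               time = ev$time)
        state$last_fio2 <- ev$fio2
        state$last_mode_time <- ev$time
      } else if (tp == "protocol_order") {
        if (ev$protocol %in% c("ventilation", "both"))
          state$vent_ordered <- TRUE
        if (ev$protocol %in% c("oxygenation", "both"))
          state$oxy_ordered <- TRUE
      } else if (tp %in% c("blood_gas", "radiograph")) {
        if (tp == "radiograph") state$last_report_text <- ev$report_text
        trig <- trigger_process_event(ev, state, cfg)
        if (tp == "blood_gas" && !is.na(state$last_fio2)) {
          phys <- compute_pf_ratio(ev$pao2, state$last_fio2,
                                   cfg$barometric_pressure)
          state$last_pf <- phys$pf_ratio
          state$last_pf_adjusted <- phys$pf_ratio_adjusted
        }
        if (is.null(trig)) {
          add("log", list(encounter_id = enc, time = ev$time,
                          what = paste0("trigger_skipped_", tp),
                          detail = "no physiology or no admission on record"))
          next
        }
        add("triggers", trig)
        if (trig$decision != "fired") next
        det <- detector(state$last_report_text)
        if (!isTRUE(det$positive)) {
          add("possible", list(encounter_id = enc, time = ev$time,
                               cause = trig$cause,
                               pf_ratio_adjusted = trig$pf_ratio_adjusted,
                               infiltrates_positive = FALSE,
                               status = "negative_detection",
                               n_recommendations = 0L))
          next
        }
        lpv <- assess_lpv(state, ev$time, cfg)
        if (lpv$status == "indeterminate") {
          add("log", list(encounter_id = enc, time = ev$time,
                          what = "lpv_indeterminate",
                          detail = paste(lpv$skipped_checks, collapse = ";")))
          next
        }
        add("possible", list(encounter_id = enc, time = ev$time,
                             cause = trig$cause,
                             pf_ratio_adjusted = trig$pf_ratio_adjusted,
                             infiltrates_positive = TRUE,
                             status = lpv$status,
                             n_recommendations = length(lpv$recommendations)))
        if (length(lpv$skipped_checks))
          add("log", list(encounter_id = enc, time = ev$time,
                          what = "check_skipped",
                          detail = paste(lpv$skipped_checks, collapse = ";")))
        if (lpv$status == "nonadherent") {
          state$pending <- list(created_at = ev$time,
                                recommendations = lpv$recommendations,
                                pf_adjusted = trig$pf_ratio_adjusted)
        } else {
          state$pending <- NULL
        }
      } else if (tp == "chart_open") {
        if (!ev$role %in% cfg$treating_roles) {
          add("log", list(encounter_id = enc, time = ev$time,
                          what = "chart_open_nontreating",
                          detail = paste(ev$clinician_id, ev$role)))
          next
        }
        session <- list(open_time = ev$time, alert_row = NA_integer_,
                        responded = FALSE)
        if (!is.null(state$pending)) {
          sd <- should_deliver(state$supp, ev$clinician_id, ev$time, cfg)
          if (sd$deliver) {
            alert_seq <- alert_seq + 1L
            aid <- sprintf("A%06d", alert_seq)
            state$supp <- record_alert_delivery(state$supp, ev$clinician_id,
                                                ev$time)
            add("alerts", list(alert_id = aid, encounter_id = enc,
                               clinician_id = ev$clinician_id,
                               created_at = state$pending$created_at,
                               delivered_at = ev$time,
                               n_recommendations =
                                 length(state$pending$recommendations),
                               reminder_delivered = FALSE))
            for (r in state$pending$recommendations)
              add("recs", list(alert_id = aid, encounter_id = enc,
                               clinician_id = ev$clinician_id,
                               rec_type = r$rec_type, category = r$category,
                               created_at = r$created_at,
                               delivered_at = ev$time,
                               evidence = r$evidence))
            session$alert_row <- length(led$alerts)
            session$rec_types <- vapply(state$pending$recommendations,
                                        function(r) r$rec_type, "")
          } else {
            add("log", list(encounter_id = enc, time = ev$time,
                            what = "alert_withheld", detail = sd$reason))
          }
        }
        state$sessions[[ev$clinician_id]] <- session
      } else if (tp == "chart_close") {
        session <- state$sessions[[ev$clinician_id]]
        if (!is.null(session) && !is.na(session$alert_row)) {
          unaddressed <- !session$responded &&
            any(vapply(session$rec_types, rec_applies_now, logical(1),
                       state = state, cfg = cfg))
          if (unaddressed)
            led$alerts[[session$alert_row]]$reminder_delivered <- TRUE
        }
        state$sessions[[ev$clinician_id]] <- NULL
      } else if (tp == "response") {
        prior <- any(vapply(led$alerts, function(a)
          a$encounter_id == enc && a$clinician_id == ev$clinician_id,
          logical(1)))
        if (!prior) {
          add("log", list(encounter_id = enc, time = ev$time,
                          what = "response_without_alert",
                          detail = ev$clinician_id))
          next
        }
        was <- state$supp$permanent
        state$supp <- record_response(state$supp, ev$action, ev$time,
                                      ev$reason, ev$reason_text)
        add("responses", list(encounter_id = enc,
                              clinician_id = ev$clinician_id,
                              time = ev$time, action = ev$action,
                              reason = ev$reason))
        if (!was && state$supp$permanent)
          add("supp", list(encounter_id = enc, time = ev$time,
                           cause = state$supp$cause))
        if (!is.null(state$sessions[[ev$clinician_id]]))
          state$sessions[[ev$clinician_id]]$responded <- TRUE
      }
    }
  }

  bind_records <- function(recs, template) {
    if (!length(recs)) return(template)
    out <- template[rep(1L, length(recs)), , drop = FALSE]
    for (nm in names(template)) {
      vals <- lapply(recs, function(r) {
        v <- r[[nm]]
        if (is.null(v)) NA else v
      })
      if (inherits(template[[nm]], "POSIXct")) {
        out[[nm]] <- as.POSIXct(vapply(vals, as.numeric, 1),
                                origin = "1970-01-01", tz = "UTC")
      } else if (nm == "reasons") {
        out[[nm]] <- vapply(vals, function(v)
          paste(v, collapse = ";"), "")
      } else out[[nm]] <- vapply(vals, function(v) v[[1]],
                                 template[[nm]][1])
    }
    rownames(out) <- NULL
    out
  }
  t0 <- as.POSIXct(0, origin = "1970-01-01", tz = "UTC")
  triggers <- bind_records(led$triggers, data.frame(
    encounter_id = "", time = t0, cause = "", pf_ratio = 0,
    pf_ratio_adjusted = 0, decision = "", reasons = "",
    stringsAsFactors = FALSE))
  possible <- bind_records(led$possible, data.frame(
    encounter_id = "", time = t0, cause = "", pf_ratio_adjusted = 0,
    infiltrates_positive = FALSE, status = "", n_recommendations = 0L,
    stringsAsFactors = FALSE))
  alerts <- bind_records(led$alerts, data.frame(
    alert_id = "", encounter_id = "", clinician_id = "", created_at = t0,
    delivered_at = t0, n_recommendations = 0L, reminder_delivered = FALSE,
    stringsAsFactors = FALSE))
  recs <- bind_records(led$recs, data.frame(
    alert_id = "", encounter_id = "", clinician_id = "", rec_type = "",
    category = "", created_at = t0, delivered_at = t0, evidence = "",
    stringsAsFactors = FALSE))
  responses <- bind_records(led$responses, data.frame(
    encounter_id = "", clinician_id = "", time = t0, action = "",
    reason = "", stringsAsFactors = FALSE))
  supp <- bind_records(led$supp, data.frame(
    encounter_id = "", time = t0, cause = "", stringsAsFactors = FALSE))
  log <- bind_records(led$log, data.frame(
    encounter_id = "", time = t0, what = "", detail = "",
    stringsAsFactors = FALSE))
  # empty templates carry one phantom row; drop it
  if (!length(led$triggers)) triggers <- triggers[0, ]
  if (!length(led$possible)) possible <- possible[0, ]
  if (!length(led$alerts)) alerts <- alerts[0, ]
  if (!length(led$recs)) recs <- recs[0, ]
  if (!length(led$responses)) responses <- responses[0, ]
  if (!length(led$supp)) supp <- supp[0, ]
  if (!length(led$log)) log <- log[0, ]

  structure(list(triggers = triggers, possible_ards = possible,
                 alerts = alerts, recommendations = recs,
                 responses = responses, suppression = supp, log = log,
                 config = cfg,
                 encounters = enc_ids),
            class = "cds_run")
}

#' @export
print.cds_run <- function(x, ...) {
  fired <- sum(x$triggers$decision == "fired")
  pos <- sum(x$possible_ards$infiltrates_positive &
               x$possible_ards$status %in% c("adherent", "nonadherent"))
  nonadh <- sum(x$possible_ards$status == "nonadherent")
  cat("<cds_run>\n")
  cat(sprintf("  encounters          : %d\n", length(x$encounters)))
  cat(sprintf("  trigger events      : %d (%d fired)\n",
              nrow(x$triggers), fired))
  cat(sprintf("  possible ARDS       : %d (%d nonadherent)\n", pos, nonadh))
  cat(sprintf("  alerts delivered    : %d (%d recommendations)\n",
              nrow(x$alerts), nrow(x$recommendations)))
  cat(sprintf("  responses           : %d (%d suppressing)\n",
              nrow(x$responses), nrow(x$suppression)))
  invisible(x)
}

#' Write run ledgers to a directory as JSONL
#'
#' @param run A `cds_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_ledgers <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("triggers", "possible_ards", "alerts", "recommendations",
               "responses", "suppression", "log")) {
    df <- run[[nm]]
    for (cl in names(df))
      if (inherits(df[[cl]], "POSIXct")) df[[cl]] <- format_cds_time(df[[cl]])
    path <- file.path(dir, paste0(nm, ".jsonl"))
    con <- file(path, open = "w")
    jsonlite::stream_out(df, con, verbose = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read run ledgers written by [write_run_ledgers()]
#'
#' @param dir Ledger directory.
#' @return A `cds_run`-shaped list (without the config element).
#' @export
read_run_ledgers <- function(dir) {
  out <- list()
  for (nm in c("triggers", "possible_ards", "alerts", "recommendations",
               "responses", "suppression", "log")) {
    path <- file.path(dir, paste0(nm, ".jsonl"))
    if (!file.exists(path)) stop("missing ledger: ", path, call. = FALSE)
    con <- file(path, open = "r")
    df <- jsonlite::stream_in(con, verbose = FALSE)
    close(con)
    for (cl in intersect(names(df),
                         c("time", "created_at", "delivered_at")))
      df[[cl]] <- parse_cds_time(df[[cl]])
    out[[nm]] <- df
  }
  out$encounters <- unique(c(out$triggers$encounter_id,
                             out$possible_ards$encounter_id))
  class(out) <- "cds_run"
  out
}
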