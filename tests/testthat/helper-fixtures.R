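# Shared fixture builders and independent oracles.

t_at <- function(hours, origin = as.POSIXct("2020-06-01 00:00:00",
                                            tz = "UTC")) {
  origin + hours * 3600
}

# compact event constructor: build a schema-valid stream from row lists
make_stream <- function(rows) {
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- lpvalert:::empty_event_frame(1L)
    e <- rows[[i]]
    if (is.null(e$event_id)) e$event_id <- i
    for (nm in names(e)) r[[nm]] <- e[[nm]]
    r
  }))
  as_cds_stream(df)
}

# a fully qualifying intubated adult admission
adm_row <- function(enc, time, ...) {
  defaults <- list(encounter_id = enc, time = time, type = "admission",
                   site = "A", age = 55, sex = "male", height = 175,
                   care_unit = "adult_icu", palliative_care = FALSE,
                   attending_specialty = "critical care", on_mcs = FALSE,
                   pa_catheter = FALSE, airway_status = "intubated",
                   intubation_time = time - 3600)
  utils::modifyList(defaults, list(...))
}

vent_row <- function(enc, time, mode = "volume_control", tidal_volume = 420,
                     peep = 8, fio2 = 0.40, pressure_support = 0, ...) {
  c(list(encounter_id = enc, time = time, type = "vent_settings",
         mode = mode, tidal_volume = tidal_volume, peep = peep, fio2 = fio2,
         pressure_support = pressure_support), list(...))
}

gas_row <- function(enc, time, pao2) {
  list(encounter_id = enc, time = time, type = "blood_gas", pao2 = pao2)
}

xray_row <- function(enc, time,
                     text = "Diffuse bilateral infiltrates consistent with edema.") {
  list(encounter_id = enc, time = time, type = "radiograph",
       report_text = text)
}

open_row <- function(enc, time, clinician = "md1", role = "physician") {
  list(encounter_id = enc, time = time, type = "chart_open",
       clinician_id = clinician, role = role)
}

close_row <- function(enc, time, clinician = "md1") {
  list(encounter_id = enc, time = time, type = "chart_close",
       clinician_id = clinician)
}

resp_row <- function(enc, time, clinician = "md1", action = "not_ards",
                     reason = NA_character_, reason_text = NA_character_) {
  list(encounter_id = enc, time = time, type = "response",
       clinician_id = clinician, action = action, reason = reason,
       reason_text = reason_text)
}

order_row <- function(enc, time, protocol) {
  list(encounter_id = enc, time = time, type = "protocol_order",
       protocol = protocol)
}

# a minimal nonadherent encounter: qualifying physiology, positive
# radiograph, PEEP far below the grid, one physician chart-open
nonadherent_encounter <- function(enc = "E1", t0 = t_at(0)) {
  make_stream(list(
    adm_row(enc, t0),
    vent_row(enc, t0 + 600, fio2 = 1.0, peep = 5),
    gas_row(enc, t0 + 1800, pao2 = 80),
    xray_row(enc, t0 + 2400),
    open_row(enc, t0 + 3000),
    close_row(enc, t0 + 3900)))
}

# Independent brute-force re-evaluation of the trigger logic: for each
# blood-gas / radiograph event, rescan the whole prefix from scratch and
# apply the inclusion/exclusion table directly. Returns a data frame of
# decisions comparable with run_cds_engine()$triggers.
brute_force_triggers <- function(events, cfg = cds_config()) {
  events <- as_cds_stream(as.data.frame(events))
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- lapply(events, function(col) col[i])
    if (!ev$type %in% c("blood_gas", "radiograph")) next
    pre <- events[seq_len(i) , ]
    pre <- pre[pre$encounter_id == ev$encounter_id, ]
    adm <- pre[pre$type == "admission", ]
    if (!nrow(adm)) next
    adm <- adm[nrow(adm), ]
    vs <- pre[pre$type == "vent_settings", ]
    # physiology: most recent PaO2 paired with most recent FiO2 at or
    # before it (for radiographs, the most recent such pair)
    gases <- pre[pre$type == "blood_gas", ]
    pf <- NA_real_
    if (ev$type == "blood_gas") {
      fio2s <- vs[vs$time <= ev$time, ]
      if (nrow(fio2s)) pf <- ev$pao2 / fio2s$fio2[nrow(fio2s)]
    } else if (nrow(gases)) {
      g <- gases[nrow(gases), ]
      fio2s <- vs[vs$time <= g$time, ]
      if (nrow(fio2s)) pf <- g$pao2 / fio2s$fio2[nrow(fio2s)]
    }
    if (is.na(pf)) next
    pf_adj <- pf * 760 / cfg$barometric_pressure
    fails <- character(0)
    if (adm$age < cfg$min_age) fails <- c(fails, "age")
    recent_mode <- nrow(vs) > 0 &&
      as.numeric(difftime(ev$time, vs$time[nrow(vs)], units = "hours")) <
        cfg$vent_mode_window_hours
    if (!recent_mode) fails <- c(fails, "mode")
    if (pf_adj > cfg$pf_threshold) fails <- c(fails, "pf")
    if (is.na(adm$intubation_time) ||
        as.numeric(difftime(ev$time, adm$intubation_time,
                            units = "hours")) > cfg$intubation_window_hours)
      fails <- c(fails, "intubation")
    if (adm$care_unit == "picu") fails <- c(fails, "picu")
    if (isTRUE(adm$palliative_care)) fails <- c(fails, "palliative")
    if (grepl("cardiothoracic", adm$attending_specialty,
              ignore.case = TRUE)) fails <- c(fails, "cts")
    if (isTRUE(adm$on_mcs)) fails <- c(fails, "mcs")
    if (adm$airway_status %in% c("t_piece", "trach_mask"))
      fails <- c(fails, "tpiece")
    if (isTRUE(adm$pa_catheter)) fails <- c(fails, "pac")
    out[[length(out) + 1L]] <- data.frame(
      encounter_id = ev$encounter_id, time = ev$time,
      decision = if (length(fails)) "excluded" else "fired",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(encounter_id = character(0),
                                      time = t_at(0)[0],
                                      decision = character(0)))
  do.call(rbind, out)
}

# random schema-valid mini-stream for property tests (single encounter)
random_mini_stream <- function(enc, n_events, t0 = t_at(0)) {
  rows <- list(adm_row(enc, t0,
                       age = sample(c(15, 40, 70), 1),
                       palliative_care = runif(1) < 0.1,
                       pa_catheter = runif(1) < 0.1,
                       airway_status = sample(c("intubated", "t_piece"), 1,
                                              prob = c(0.9, 0.1)),
                       intubation_time = t0 - sample(c(2, 200), 1,
                                                     prob = c(0.9, 0.1)) * 3600))
  time <- t0
  for (j in seq_len(n_events)) {
    time <- time + sample(300:7200, 1)
    kind <- sample(c("gas", "vent", "xray"), 1)
    rows[[length(rows) + 1L]] <-
      if (kind == "gas") gas_row(enc, time, pao2 = runif(1, 40, 400))
      else if (kind == "vent")
        vent_row(enc, time, fio2 = sample(c(0.3, 0.5, 0.8, 1.0), 1),
                 peep = sample(c(5, 8, 14), 1))
      else xray_row(enc, time, text = sample(c(
        "Diffuse bilateral infiltrates consistent with edema.",
        "Lungs are clear. Heart size normal."), 1))
  }
  make_stream(rows)
}
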