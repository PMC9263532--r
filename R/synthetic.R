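# Seeded generator of synthetic encounter event streams with planted
# possible-ARDS prevalence, LPV nonadherence, radiograph-report language and
# clinician response behaviour. Planted labels go to a ground-truth sidecar
# that the engine never reads. Values are sampled to satisfy or violate the
# rule thresholds, not to be clinically realistic trajectories.

#' Cohort specification
#'
#' Defaults encode the study conditions the generator emulates: 38% of
#' trigger-bearing encounters have at least one nonadherent possible-ARDS
#' episode, specific-setting recommendations are followed 65% of the time
#' and adopt-protocol recommendations 14% of the time, with about 1.5
#' charted trigger causes per encounter beyond the admission radiograph
#' cycle and a tertiary-site mix. Corrective changes land uniformly 5-115
#' minutes after alert delivery when followed and 125-175 minutes when not,
#' so both outcomes occur around the 120-minute adherence window.
#'
#' @param n_encounters Number of encounters (>= 1).
#' @param seed Integer RNG seed; the stream is a deterministic function of
#'   the spec.
#' @param p_possible_ards Probability an encounter develops qualifying
#'   physiology plus a positive radiograph report (encounter level; must be
#'   at least `p_nonadherent`).
#' @param p_nonadherent Probability an encounter has a nonadherent
#'   possible-ARDS episode (measured against trigger-bearing encounters,
#'   the initial-nonadherence denominator).
#' @param p_follow_adopt,p_follow_specific Probability an adopt-protocol /
#'   specific-setting recommendation is followed within the window.
#' @param mean_triggers_per_encounter Mean trigger events per encounter
#'   (>= 2; every encounter charts one blood gas and one radiograph, extra
#'   blood gases are Poisson).
#' @param p_suppress_response Probability a non-followed alert draws a
#'   "not ARDS" or contraindication response (exercises permanent
#'   suppression).
#' @param sites Named numeric vector of site weights.
#' @param violation_weights Named weights over planted violation kinds.
#' @param report_templates Template list as from
#'   [default_report_templates()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_encounters,
                        seed = 1L,
                        p_possible_ards = 0.60,
                        p_nonadherent = 0.38,
                        p_follow_adopt = 0.14,
                        p_follow_specific = 0.65,
                        mean_triggers_per_encounter = 3,
                        p_suppress_response = 0.30,
                        sites = c(A = 356, B = 235, C = 220, D = 150,
                                  E = 51),
                        violation_weights = c(
                          peep_fio2 = 0.585, tidal_volume = 0.074,
                          protocols_not_ordered = 0.185, cpap_ps = 0.048,
                          nonstandard_mode = 0.036,
                          ventilation_protocol_not_ordered = 0.015,
                          noncompliant_mode = 0.005,
                          oxygenation_protocol_not_ordered = 0.005),
                        report_templates = default_report_templates()) {
  spec <- list(n_encounters = as.integer(n_encounters), seed = as.integer(seed),
               p_possible_ards = p_possible_ards,
               p_nonadherent = p_nonadherent,
               p_follow_adopt = p_follow_adopt,
               p_follow_specific = p_follow_specific,
               mean_triggers_per_encounter = mean_triggers_per_encounter,
               p_suppress_response = p_suppress_response,
               sites = sites, violation_weights = violation_weights,
               report_templates = report_templates)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (is.na(spec$n_encounters) || spec$n_encounters < 1L)
    stop("n_encounters must be >= 1", call. = FALSE)
  for (nm in c("p_possible_ards", "p_nonadherent", "p_follow_adopt",
               "p_follow_specific", "p_suppress_response")) {
    v <- spec[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
  }
  if (spec$p_possible_ards < spec$p_nonadherent)
    stop("p_possible_ards must be >= p_nonadherent (nonadherent episodes ",
         "presuppose possible ARDS)", call. = FALSE)
  if (spec$mean_triggers_per_encounter < 2)
    stop("mean_triggers_per_encounter must be >= 2", call. = FALSE)
  if (is.null(names(spec$sites)) || any(spec$sites <= 0))
    stop("`sites` must be a named vector of positive weights", call. = FALSE)
  if (abs(sum(spec$violation_weights)) < 1e-12)
    stop("violation weights must not all be zero", call. = FALSE)
  missing_lab <- setdiff(c("positive", "uncertain", "negated", "clear"),
                         names(spec$report_templates))
  if (length(missing_lab))
    stop("report_templates missing label(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n=%d seed=%d  P(possible)=%.2f P(nonadherent)=%.2f\n",
              x$n_encounters, x$seed, x$p_possible_ards, x$p_nonadherent))
  cat(sprintf("  P(follow | specific)=%.2f  P(follow | adopt)=%.2f  sites: %s\n",
              x$p_follow_specific, x$p_follow_adopt,
              paste(names(x$sites), collapse = ",")))
  invisible(x)
}

#' Default radiograph-report templates
#'
#' Four labelled families: `positive` (non-negated bilateral infiltrate
#' language), `uncertain` (hedged but screen-positive), `negated`
#' (infiltrate terms inside negation scopes) and `clear` (no infiltrate
#' language). `{slot}` markers are filled with lexical jitter at render
#' time.
#'
#' @return Named list with `templates` per label and a `jitter` table.
#' @export
default_report_templates <- function() {
  list(
    positive = c(
      "Endotracheal tube in standard position. {adj} bilateral {inf} consistent with {cause}.",
      "Interval worsening of {adj2} {inf} bilaterally. Heart size stable.",
      "{adj} {inf} in both lungs, compatible with {cause}.",
      "There are bilateral {inf} with {adj2} distribution. Lines unchanged.",
      "Persistent bilateral {inf}. No pneumothorax."),
    uncertain = c(
      "Possible bilateral {inf}; cannot exclude {cause}.",
      "Questionable {adj2} bilateral {inf}, may represent {cause}.",
      "Hazy {inf} bilaterally, concerning for {cause}.",
      "Findings suspicious for bilateral {inf}; clinical correlation advised."),
    negated = c(
      "No focal {sinf} or consolidation. Lungs otherwise well aerated.",
      "Lines in standard position. No evidence of {sinf}.",
      "No {sinf} identified. Small left pleural effusion, stable.",
      "Interval clearing of {sinf}. Heart size within normal limits.",
      "Negative for {sinf}. Degenerative changes of the spine."),
    clear = c(
      "Lungs are clear. Heart size and mediastinum are normal.",
      "Clear lungs without pleural effusion. Tubes and lines unchanged.",
      "No acute cardiopulmonary abnormality.",
      "Heart size normal. Costophrenic angles are sharp."),
    jitter = list(
      adj = c("Diffuse", "Patchy", "Extensive", "Worsening", "Confluent"),
      adj2 = c("patchy", "diffuse", "perihilar", "dependent"),
      inf = c("infiltrates", "opacities", "airspace disease"),
      sinf = c("infiltrate", "consolidation", "airspace disease"),
      cause = c("pulmonary edema", "ARDS", "multifocal pneumonia",
                "diffuse alveolar damage"))
  )
}

#' Render a radiograph report for a planted label
#'
#' Draws a template of the requested label and fills jitter slots using the
#' current RNG state.
#'
#' @param label One of `positive`, `uncertain`, `negated`, `clear`.
#' @param templates Template list (see [default_report_templates()]).
#' @return Character scalar report text.
#' @export
render_report <- function(label, templates = default_report_templates()) {
  label <- match.arg(label, c("positive", "uncertain", "negated", "clear"))
  text <- sample(templates[[label]], 1L)
  for (slot in names(templates$jitter)) {
    pat <- paste0("{", slot, "}")
    while (grepl(pat, text, fixed = TRUE)) {
      text <- sub(pat, sample(templates$jitter[[slot]], 1L), text,
                  fixed = TRUE)
    }
  }
  text
}

# adherent baseline ventilator settings for a patient with this PBW:
# volume control, Vt 6 mL/kg, PEEP/FiO2 from the low-PEEP grid
adherent_settings <- function(pbw, cfg) {
  grid <- cfg$peep_fio2_grids[[cfg$peep_strategy]]
  lev <- grid[[sample.int(length(grid), 1L)]]
  list(mode = "volume_control", tidal_volume = round(6 * pbw),
       peep = lev$peep[sample.int(length(lev$peep), 1L)],
       fio2 = lev$fio2, pressure_support = 0)
}

# settings violating exactly the planted check (everything else adherent)
violating_settings <- function(kind, pbw, cfg) {
  s <- adherent_settings(pbw, cfg)
  if (kind == "peep_fio2") {
    s$fio2 <- 1.0
    s$peep <- 5            # far below every allowed PEEP at FiO2 1.0
  } else if (kind == "tidal_volume") {
    s$tidal_volume <- round((cfg$vt_per_pbw_max + runif(1, 1, 3.5)) * pbw)
  } else if (kind == "cpap_ps") {
    # PS branch of the CPAP/PS limits, so the planted violation stays
    # confined to the mode rules (PEEP/FiO2 pair remains grid-adherent)
    s$mode <- "cpap_ps"
    s$peep <- 8
    s$fio2 <- 0.40
    s$pressure_support <- 18
  } else if (kind == "nonstandard_mode") {
    s$mode <- "aprv"
  } else if (kind == "noncompliant_mode") {
    s$mode <- "pressure_control"
  }
  s
}

#' Generate a synthetic cohort event stream
#'
#' Deterministic given the spec (including its seed). Every encounter is an
#' intubated adult ICU stay with qualifying hypoxemia; the planted labels —
#' possible-ARDS status, nonadherent episode and its violation kind, and
#' per-recommendation follow decisions — are emitted to a ground-truth
#' sidecar the engine never sees.
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [cds_config()] (thresholds used to synthesize adherent and
#'   violating settings).
#' @return List with `events` (a `cds_stream`) and `truth` (the sidecar
#'   data frame).
#' @export
generate_cohort <- function(spec, cfg = cds_config()) {
  validate_cohort_spec(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  site_p <- spec$sites / sum(spec$sites)
  viol_p <- spec$violation_weights / sum(spec$violation_weights)
  q_adherent_possible <-
    if (spec$p_nonadherent >= 1) 0
    else (spec$p_possible_ards - spec$p_nonadherent) /
      (1 - spec$p_nonadherent)

  all_events <- vector("list", spec$n_encounters)
  truth <- vector("list", spec$n_encounters)

  for (i in seq_len(spec$n_encounters)) {
    enc <- sprintf("E%05d", i)
    site <- sample(names(site_p), 1L, prob = site_p)
    t0 <- origin + (i - 1) * 3600
    sex <- sample(c("male", "female"), 1L)
    height <- round(runif(1, 150, 195))
    pbw <- predicted_body_weight(sex, height)
    c1 <- sprintf("%s-md1", enc); c2 <- sprintf("%s-md2", enc)

    nonadherent <- runif(1) < spec$p_nonadherent
    possible <- nonadherent || runif(1) < q_adherent_possible
    violation <- if (nonadherent)
      sample(names(viol_p), 1L, prob = viol_p) else NA_character_
    report_label <- if (possible) {
      if (runif(1) < 0.25) "uncertain" else "positive"
    } else {
      if (runif(1) < 0.5) "negated" else "clear"
    }

    ev <- list(); eid <- 0L
    push <- function(time, type, ...) {
      eid <<- eid + 1L
      ev[[eid]] <<- c(list(encounter_id = enc, event_id = eid,
                           time = time, type = type), list(...))
    }
    push(t0, "admission", site = site, age = sample(25:85, 1L), sex = sex,
         height = height, care_unit = "adult_icu", palliative_care = FALSE,
         attending_specialty = "critical care", on_mcs = FALSE,
         pa_catheter = FALSE, airway_status = "intubated",
         intubation_time = t0 - 2 * 3600)

    settings <- if (nonadherent) {
      if (violation %in% c("protocols_not_ordered",
                           "ventilation_protocol_not_ordered",
                           "oxygenation_protocol_not_ordered"))
        adherent_settings(pbw, cfg)
      else violating_settings(violation, pbw, cfg)
    } else adherent_settings(pbw, cfg)
    push(t0 + 600, "vent_settings", mode = settings$mode,
         tidal_volume = settings$tidal_volume, peep = settings$peep,
         fio2 = settings$fio2, pressure_support = settings$pressure_support)

    # protocol orders: present unless the planted violation removes them
    omit_vent <- isTRUE(violation %in% c("protocols_not_ordered",
                                         "ventilation_protocol_not_ordered"))
    omit_oxy <- isTRUE(violation %in% c("protocols_not_ordered",
                                        "oxygenation_protocol_not_ordered"))
    if (!omit_vent) push(t0 + 900, "protocol_order", protocol = "ventilation")
    if (!omit_oxy) push(t0 + 960, "protocol_order", protocol = "oxygenation")

    # qualifying hypoxemia: adjusted P/F uniform in (120, 250]
    pao2 <- settings$fio2 * runif(1, 120, 250) *
      cfg$barometric_pressure / 760
    push(t0 + 1800, "blood_gas", pao2 = round(pao2, 1))
    push(t0 + 2400, "radiograph",
         report_text = render_report(report_label, spec$report_templates))

    followed <- NA
    if (nonadherent) {
      t_open <- t0 + 3000
      push(t_open, "chart_open", clinician_id = c1, role = "physician")
      if (runif(1) < 0.35)
        push(t_open + runif(1, 30, 290), "chart_open", clinician_id = c2,
             role = "physician")
      if (runif(1) < 0.2)
        push(t_open + 2700, "chart_open",
             clinician_id = sprintf("%s-rt1", enc),
             role = "respiratory_therapist")
      push(t_open + 1200, "chart_close", clinician_id = c1)

      specific <- violation %in% c("peep_fio2", "tidal_volume")
      p_follow <- if (specific) spec$p_follow_specific else
        spec$p_follow_adopt
      followed <- runif(1) < p_follow
      t_fix <- t_open + 60 * if (followed) runif(1, 5, 115) else
        runif(1, 125, 175)
      if (!followed && runif(1) < spec$p_suppress_response) {
        if (runif(1) < 0.5)
          push(t_open + 60 * runif(1, 5, 60), "response",
               clinician_id = c1, action = "not_ards")
        else
          push(t_open + 60 * runif(1, 5, 60), "response",
               clinician_id = c1, action = "contraindication",
               reason = sample(c("elevated_icp", "status_asthmaticus",
                                 "severe_copd"), 1L))
      }
      if (followed)
        push(t_fix - 1, "response", clinician_id = c1,
             action = if (omit_vent || omit_oxy) "order_protocol"
                      else "act_on_instruction")
      # corrective change (possibly after the window when not followed)
      if (omit_vent) push(t_fix, "protocol_order", protocol = "ventilation")
      if (omit_oxy) push(t_fix + 10, "protocol_order",
                         protocol = "oxygenation")
      if (!omit_vent && !omit_oxy) {
        good <- adherent_settings(pbw, cfg)
        push(t_fix, "vent_settings", mode = good$mode,
             tidal_volume = good$tidal_volume, peep = good$peep,
             fio2 = good$fio2, pressure_support = good$pressure_support)
      }
      if (runif(1) < 0.3)
        push(t_open + 4 * 3600, "chart_open", clinician_id = c1,
             role = "physician")
    } else if (runif(1) < 0.4) {
      # adherent encounters still get chart activity (no alert expected)
      push(t0 + 3000, "chart_open", clinician_id = c1, role = "physician")
      push(t0 + 3900, "chart_close", clinician_id = c1)
    }

    # extra blood-gas triggers late in the stay (new cycles)
    n_extra <- stats::rpois(1, max(0, spec$mean_triggers_per_encounter - 2))
    if (n_extra > 0) {
      for (j in seq_len(n_extra)) {
        pao2_j <- settings$fio2 * runif(1, 120, 250) *
          cfg$barometric_pressure / 760
        push(t0 + (4 + j) * 3600, "blood_gas", pao2 = round(pao2_j, 1))
      }
    }

    df <- do.call(rbind, lapply(ev, function(e) {
      r <- empty_event_frame(1L)
      for (nm in names(e)) r[[nm]] <- e[[nm]]
      r
    }))
    all_events[[i]] <- df
    truth[[i]] <- data.frame(encounter_id = enc, site = site,
                             possible_ards = possible,
                             nonadherent = nonadherent,
                             violation = violation,
                             followed = followed,
                             report_label = report_label,
                             stringsAsFactors = FALSE)
  }
  events <- as_cds_stream(do.call(rbind, all_events))
  list(events = events, truth = do.call(rbind, truth))
}

#' Write cohort stream and ground-truth sidecar
#'
#' @param cohort List from [generate_cohort()].
#' @param stream_path Output JSONL (or CSV) path for the event stream.
#' @param truth_path Output JSONL path for the ground-truth sidecar.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, stream_path, truth_path) {
  write_event_stream(cohort$events, stream_path)
  con <- file(truth_path, open = "w")
  jsonlite::stream_out(cohort$truth, con, verbose = FALSE)
  close(con)
  invisible(c(stream_path, truth_path))
}
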