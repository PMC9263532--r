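#' Engine configuration
#'
#' Builds the configuration object consumed by the trigger engine, the LPV
#' adherence checks, the alert manager and the evaluation helpers. Defaults
#' encode the deployed rule set: an altitude-adjusted P/F threshold of 255
#' mmHg, a 7-day ventilator-mode charting window, a 4-day intubation window,
#' adult age cutoff 18 years, a 16-hour per-clinician alert window, a 2-hour
#' recommendation-adherence window, a 6.5 mL/kg predicted-body-weight tidal
#' volume limit, CPAP/PS appropriateness limits (PEEP 10 cmH2O, FiO2 0.50,
#' PS 15 cmH2O) and an arterial oxygen target of 55-68 mmHg.
#'
#' @param pf_threshold Altitude-adjusted PaO2/FiO2 ratio at or below which a
#'   trigger qualifies (mmHg).
#' @param barometric_pressure Site barometric pressure in mmHg. The adjusted
#'   ratio is `pf_ratio * 760 / barometric_pressure`; the default 760 applies
#'   no adjustment because the 255 threshold is itself already
#'   altitude-adjusted (255 is approximately 300 scaled by a mountain-site
#'   pressure factor).
#' @param vent_mode_window_hours Maximum age, in hours, of the last charted
#'   ventilator mode for inclusion (strict `<`; 168 h = 7 days).
#' @param intubation_window_hours Maximum time since intubation for inclusion
#'   (`<=`; 96 h = 4 days).
#' @param min_age Minimum patient age in years (inclusion requires `>=`).
#' @param alert_window_hours Minimum spacing between alerts to the same
#'   clinician for the same patient ("once per shift").
#' @param adherence_window_minutes Window after alert delivery within which a
#'   consistent treatment change counts as the recommendation being followed.
#' @param vt_per_pbw_max Tidal volume limit in mL per kg predicted body
#'   weight; a recommendation fires on strict excess.
#' @param peep_strategy Which PEEP/FiO2 grid to check against, `"low_peep"`
#'   or `"high_peep"`.
#' @param peep_fio2_grids Named list of grids as returned by
#'   [load_peep_fio2_grids()]; defaults to the grids shipped with the
#'   package.
#' @param peep_tolerance Allowed deviation (cmH2O) from a grid PEEP value.
#' @param cpap_ps_limits Named list with elements `peep`, `fio2`, `ps`;
#'   CPAP/PS is inappropriate when any is strictly exceeded.
#' @param pao2_target Two-element numeric, the oxygenation protocol PaO2
#'   target range in mmHg (informational; rendered in alert text).
#' @param compliant_modes Ventilator modes fully compliant with the
#'   ventilation protocol.
#' @param spontaneous_modes Modes treated as CPAP/PS-class spontaneous modes,
#'   subject to the CPAP/PS limits instead of the mode-class rules.
#' @param noncompliant_modes Standard modes that are not health-system
#'   compliant (fire `noncompliant_mode`).
#' @param nonstandard_modes Modes outside the standard set (fire
#'   `nonstandard_mode`). Any mode not listed in one of the four classes is
#'   treated as nonstandard.
#' @param treating_roles Chart-open roles eligible to receive alerts.
#'
#' @return An object of class `cds_config` (a validated named list).
#' @examples
#' cfg <- cds_config()
#' cfg$pf_threshold
#' @export
cds_config <- function(pf_threshold = 255,
                       barometric_pressure = 760,
                       vent_mode_window_hours = 168,
                       intubation_window_hours = 96,
                       min_age = 18,
                       alert_window_hours = 16,
                       adherence_window_minutes = 120,
                       vt_per_pbw_max = 6.5,
                       peep_strategy = c("low_peep", "high_peep"),
                       peep_fio2_grids = load_peep_fio2_grids(),
                       peep_tolerance = 1,
                       cpap_ps_limits = list(peep = 10, fio2 = 0.50, ps = 15),
                       pao2_target = c(55, 68),
                       compliant_modes = "volume_control",
                       spontaneous_modes = "cpap_ps",
                       noncompliant_modes = c("pressure_control", "simv"),
                       nonstandard_modes = c("aprv", "hfov", "other"),
                       treating_roles = c("physician", "app")) {
  peep_strategy <- match.arg(peep_strategy)
  cfg <- list(
    pf_threshold = pf_threshold,
    barometric_pressure = barometric_pressure,
    vent_mode_window_hours = vent_mode_window_hours,
    intubation_window_hours = intubation_window_hours,
    min_age = min_age,
    alert_window_hours = alert_window_hours,
    adherence_window_minutes = adherence_window_minutes,
    vt_per_pbw_max = vt_per_pbw_max,
    peep_strategy = peep_strategy,
    peep_fio2_grids = peep_fio2_grids,
    peep_tolerance = peep_tolerance,
    cpap_ps_limits = cpap_ps_limits,
    pao2_target = pao2_target,
    compliant_modes = compliant_modes,
    spontaneous_modes = spontaneous_modes,
    noncompliant_modes = noncompliant_modes,
    nonstandard_modes = nonstandard_modes,
    treating_roles = treating_roles
  )
  validate_cds_config(cfg)
  structure(cfg, class = "cds_config")
}

validate_cds_config <- function(cfg) {
  num_pos <- c("pf_threshold", "barometric_pressure", "vent_mode_window_hours",
               "intubation_window_hours", "min_age", "alert_window_hours",
               "adherence_window_minutes", "vt_per_pbw_max", "peep_tolerance")
  for (nm in num_pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field `", nm, "` must be a single positive number",
           call. = FALSE)
  }
  if (length(cfg$pao2_target) != 2L || cfg$pao2_target[1] >= cfg$pao2_target[2])
    stop("`pao2_target` must be an increasing range", call. = FALSE)
  lim <- cfg$cpap_ps_limits
  if (!all(c("peep", "fio2", "ps") %in% names(lim)))
    stop("`cpap_ps_limits` needs elements peep, fio2, ps", call. = FALSE)
  if (!cfg$peep_strategy %in% names(cfg$peep_fio2_grids))
    stop("`peep_strategy` not present in `peep_fio2_grids`", call. = FALSE)
  for (g in cfg$peep_fio2_grids) validate_peep_grid(g)
  invisible(cfg)
}

validate_peep_grid <- function(grid) {
  fio2 <- vapply(grid, function(r) r$fio2, numeric(1))
  if (is.unsorted(fio2, strictly = TRUE))
    stop("grid FiO2 levels must be strictly increasing", call. = FALSE)
  if (abs(fio2[1] - 0.21) > 1e-9 || abs(fio2[length(fio2)] - 1.0) > 1e-9)
    stop("grid FiO2 levels must cover [0.21, 1.0]", call. = FALSE)
  for (r in grid) {
    if (length(r$peep) < 1L || any(r$peep < 0))
      stop("each grid level needs a nonempty, nonnegative PEEP set",
           call. = FALSE)
  }
  invisible(grid)
}

#' Load PEEP/FiO2 titration grids from a YAML file
#'
#' The default file ships the public ARDSNet lower-PEEP/higher-FiO2 and
#' higher-PEEP/lower-FiO2 tables. Each grid is an ordered list of
#' `{fio2, peep}` levels; see [check_peep_fio2()] for the lookup rule.
#'
#' @param path YAML file; defaults to the grids installed with the package.
#' @return Named list of grids, each a list of `list(fio2 =, peep =)` levels.
#' @export
load_peep_fio2_grids <- function(path = system.file("extdata",
                                                    "peep_fio2_grids.yaml",
                                                    package = "lpvalert")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(grid) {
    grid <- lapply(grid, function(r)
      list(fio2 = as.numeric(r$fio2), peep = as.numeric(r$peep)))
    validate_peep_grid(grid)
    grid
  })
}

#' @export
print.cds_config <- function(x, ...) {
  cat("<cds_config>\n")
  cat(sprintf("  adjusted P/F threshold : <= %g mmHg (P_b = %g mmHg)\n",
              x$pf_threshold, x$barometric_pressure))
  cat(sprintf("  inclusion windows      : mode < %g h, intubation <= %g h, age >= %g y\n",
              x$vent_mode_window_hours, x$intubation_window_hours, x$min_age))
  cat(sprintf("  alert window           : %g h per clinician\n",
              x$alert_window_hours))
  cat(sprintf("  adherence window       : %g min\n", x$adherence_window_minutes))
  cat(sprintf("  tidal volume limit     : %g mL/kg PBW\n", x$vt_per_pbw_max))
  cat(sprintf("  PEEP strategy          : %s (tolerance %g cmH2O)\n",
              x$peep_strategy, x$peep_tolerance))
  invisible(x)
}
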