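cfg <- cds_config()
now <- t_at(0)

test_that("predicted body weight matches the Devine anchors", {
  expect_equal(predicted_body_weight("male", 152.4), 50.0)
  expect_equal(predicted_body_weight("female", 152.4), 45.5)
  expect_equal(round(predicted_body_weight("male", 175), 2), 70.57)
  expect_true(is.na(predicted_body_weight(NA_character_, 175)))
  expect_true(is.na(predicted_body_weight("male", NA_real_)))
  expect_error(predicted_body_weight("male", 80), "plausible range")
  # floor: implausibly short but in-range heights never go below 20 kg
  expect_gte(predicted_body_weight("female", 120), 20)
})

test_that("tidal volume limit is strict at 6.5 mL/kg PBW", {
  expect_null(check_tidal_volume(420, 70, now, cfg))            # 6.0
  r <- check_tidal_volume(500, 70.57, now, cfg)                  # 7.09
  expect_equal(r$rec_type, "tidal_volume_too_large")
  expect_equal(r$category, "specific_setting")
  # exactly 6.5 mL/kg is adherent (strict >)
  expect_null(check_tidal_volume(6.5 * 70.57, 70.57, now, cfg))
  expect_false(is.null(check_tidal_volume(6.5 * 70.57 + 0.01, 70.57, now,
                                          cfg)))
  expect_error(check_tidal_volume(400, NA_real_, now, cfg), "PBW undefined")
})

test_that("PEEP/FiO2 grid lookup uses nearest-not-above level with tolerance", {
  expect_null(check_peep_fio2(5, 0.40, now, cfg))
  r <- check_peep_fio2(5, 1.0, now, cfg)
  expect_equal(r$rec_type, "peep_fio2_inappropriate")
  # within +/-1 cmH2O of an allowed value counts as adherent
  expect_null(check_peep_fio2(9, 0.40, now, cfg))   # allowed {5, 8}
  expect_false(is.null(check_peep_fio2(10.5, 0.40, now, cfg)))
  # charted FiO2 between levels maps down (0.45 -> level 0.40)
  expect_null(check_peep_fio2(8, 0.45, now, cfg))
  # below the lowest level uses the grid floor
  expect_null(check_peep_fio2(5, 0.21, now, cfg))
  # the high-PEEP strategy has different allowed sets
  cfg_hi <- cds_config(peep_strategy = "high_peep")
  expect_false(is.null(check_peep_fio2(5, 0.40, now, cfg_hi)))
  expect_null(check_peep_fio2(14, 0.40, now, cfg_hi))
})

test_that("CPAP/PS limits fire on any branch; mode classes map to their types", {
  # PEEP branch
  r <- check_mode_rules("cpap_ps", 12, 0.40, 10, now, cfg)
  expect_setequal(vapply(r, function(x) x$rec_type, ""),
                  c("cpap_ps_inappropriate", "change_to_volume_control"))
  # all three below limits: nothing
  expect_length(check_mode_rules("cpap_ps", 8, 0.45, 12, now, cfg), 0L)
  # FiO2 branch fires just above 50%
  r2 <- check_mode_rules("cpap_ps", 8, 0.51, 12, now, cfg)
  expect_true("cpap_ps_inappropriate" %in%
                vapply(r2, function(x) x$rec_type, ""))
  expect_length(check_mode_rules("cpap_ps", 8, 0.50, 12, now, cfg), 0L)
  # PS branch
  r3 <- check_mode_rules("cpap_ps", 8, 0.40, 16, now, cfg)
  expect_true("cpap_ps_inappropriate" %in%
                vapply(r3, function(x) x$rec_type, ""))
  # mode classes
  expect_length(check_mode_rules("volume_control", 8, 0.4, 0, now, cfg), 0L)
  expect_equal(check_mode_rules("pressure_control", 8, 0.4, 0, now,
                                cfg)[[1]]$rec_type, "noncompliant_mode")
  expect_equal(check_mode_rules("aprv", 8, 0.4, 0, now, cfg)[[1]]$rec_type,
               "nonstandard_mode")
  expect_equal(check_mode_rules("esoteric_mode", 8, 0.4, 0, now,
                                cfg)[[1]]$rec_type, "nonstandard_mode")
})

test_that("protocol-order recommendations are mutually exclusive", {
  types <- function(v, o) vapply(check_protocol_orders(v, o, now),
                                 function(x) x$rec_type, "")
  expect_equal(types(FALSE, FALSE), "protocols_not_ordered")
  expect_equal(types(TRUE, FALSE), "oxygenation_protocol_not_ordered")
  expect_equal(types(FALSE, TRUE), "ventilation_protocol_not_ordered")
  expect_length(types(TRUE, TRUE), 0L)
})

test_that("exactly nine recommendation types partition into 7 adopt + 2 specific", {
  tab <- recommendation_types()
  expect_equal(nrow(tab), 9L)
  expect_equal(sum(tab$category == "adopt_protocol"), 7L)
  expect_equal(sum(tab$category == "specific_setting"), 2L)
  expect_setequal(tab$rec_type[tab$category == "specific_setting"],
                  c("peep_fio2_inappropriate", "tidal_volume_too_large"))
})

test_that("assess_lpv aggregates recommendations, is pure, and respects preconditions", {
  state <- list(attrs = list(sex = "male", height = 175),
                settings = list(mode = "volume_control", tidal_volume = 550,
                                peep = 8, fio2 = 0.40, pressure_support = 0,
                                time = now),
                vent_ordered = FALSE, oxy_ordered = FALSE,
                last_pf_adjusted = 200)
  r <- assess_lpv(state, now, cfg)
  expect_equal(r$status, "nonadherent")
  # orders absent AND tidal volume high: two findings in one event
  expect_setequal(vapply(r$recommendations, function(x) x$rec_type, ""),
                  c("protocols_not_ordered", "tidal_volume_too_large"))
  # repeated evaluation without state change is identical
  expect_identical(r, assess_lpv(state, now, cfg))
  # all checks passing: adherent, nothing downstream
  ok <- state; ok$vent_ordered <- TRUE; ok$oxy_ordered <- TRUE
  ok$settings$tidal_volume <- 420
  expect_equal(assess_lpv(ok, now, cfg)$status, "adherent")
  # no settings charted: indeterminate, no event emitted
  ind <- state; ind$settings <- NULL
  expect_equal(assess_lpv(ind, now, cfg)$status, "indeterminate")
  # P/F no longer qualifying at assessment time
  nq <- state; nq$last_pf_adjusted <- 300
  expect_equal(assess_lpv(nq, now, cfg)$status, "not_qualifying")
  # missing height: tidal-volume check skipped and flagged, not guessed
  nh <- ok; nh$attrs$height <- NA_real_; nh$settings$tidal_volume <- 900
  rn <- assess_lpv(nh, now, cfg)
  expect_equal(rn$status, "adherent")
  expect_true("tidal_volume_pbw_undefined" %in% rn$skipped_checks)
})

test_that("tightening thresholds never removes a recommendation", {
  state <- list(attrs = list(sex = "male", height = 175),
                settings = list(mode = "volume_control", tidal_volume = 480,
                                peep = 9.8, fio2 = 0.40, pressure_support = 0,
                                time = now),
                vent_ordered = TRUE, oxy_ordered = TRUE,
                last_pf_adjusted = 200)
  loose <- cds_config(vt_per_pbw_max = 8, peep_tolerance = 2)
  tight <- cds_config(vt_per_pbw_max = 6, peep_tolerance = 0.5)
  recs_loose <- vapply(assess_lpv(state, now, loose)$recommendations,
                       function(x) x$rec_type, "")
  recs_tight <- vapply(assess_lpv(state, now, tight)$recommendations,
                       function(x) x$rec_type, "")
  expect_true(all(recs_loose %in% recs_tight))
  expect_gt(length(recs_tight), length(recs_loose))
})
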