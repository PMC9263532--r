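cfg <- cds_config()

test_that("the 16-hour window is per clinician and rolling from last delivery", {
  st <- new_suppression_state()
  t0 <- t_at(0)
  expect_true(should_deliver(st, "md1", t0, cfg)$deliver)
  st <- record_alert_delivery(st, "md1", t0)
  # 10 h later, same clinician: windowed
  r <- should_deliver(st, "md1", t0 + 10 * 3600, cfg)
  expect_false(r$deliver)
  expect_equal(r$reason, "within_16h_window")
  # 10 h later, different clinician: eligible
  expect_true(should_deliver(st, "md2", t0 + 10 * 3600, cfg)$deliver)
  # exactly 16 h later: eligible again (>=)
  expect_true(should_deliver(st, "md1", t0 + 16 * 3600, cfg)$deliver)
})

test_that("not-ARDS and contraindication responses suppress permanently; others never", {
  t0 <- t_at(0)
  st <- record_alert_delivery(new_suppression_state(), "md1", t0)
  st1 <- record_response(st, "act_on_instruction", t0 + 60)
  expect_false(st1$permanent)
  st2 <- record_response(st, "order_protocol", t0 + 60)
  expect_false(st2$permanent)
  st3 <- record_response(st, "not_ards", t0 + 60)
  expect_true(st3$permanent)
  expect_equal(st3$cause, "not_ards")
  expect_false(should_deliver(st3, "md9", t0 + 100 * 3600, cfg)$deliver)
  st4 <- record_response(st, "contraindication", t0 + 60,
                         reason = "status_asthmaticus")
  expect_true(st4$permanent)
  expect_match(st4$cause, "status_asthmaticus")
  st5 <- record_response(st, "contraindication", t0 + 60, reason = "other",
                         reason_text = "proning in progress")
  expect_true(st5$permanent)
  expect_error(record_response(st, "contraindication", t0 + 60,
                               reason = "other", reason_text = ""),
               "nonempty free text")
})

test_that("suppression is absorbing and the rate bound holds over randomized streams", {
  set.seed(99)
  n_streams <- 400
  for (k in seq_len(n_streams)) {
    st <- new_suppression_state()
    clinicians <- paste0("md", 1:3)
    t <- t_at(0)
    delivered <- list()
    suppressed_at <- NA
    for (step in 1:12) {
      t <- t + runif(1, 0, 12) * 3600
      cl <- sample(clinicians, 1)
      if (runif(1) < 0.08) {
        st <- record_response(st, sample(c("not_ards", "contraindication"), 1),
                              t, reason = "elevated_icp")
        if (is.na(suppressed_at)) suppressed_at <- t
      }
      sd <- should_deliver(st, cl, t, cfg)
      if (sd$deliver) {
        st <- record_alert_delivery(st, cl, t)
        delivered[[length(delivered) + 1L]] <- list(cl = cl, t = t)
      }
    }
    times <- vapply(delivered, function(d) as.numeric(d$t), 1)
    cls <- vapply(delivered, function(d) d$cl, "")
    # no delivery at/after permanent suppression
    if (!is.na(suppressed_at))
      expect_true(all(times < as.numeric(suppressed_at)))
    # per-clinician spacing >= 16 h
    for (cl in unique(cls)) {
      ts <- sort(times[cls == cl])
      if (length(ts) > 1) expect_true(all(diff(ts) >= 16 * 3600 - 1e-6))
    }
  }
})

test_that("alerts deliver on chart open only to treating clinicians and record reminders", {
  t0 <- t_at(0)
  base <- list(
    adm_row("E1", t0),
    vent_row("E1", t0 + 600, fio2 = 1.0, peep = 5),
    gas_row("E1", t0 + 1800, 80),
    xray_row("E1", t0 + 2400))
  # eligible clinician with pending nonadherence: alert + reminder at close
  s <- make_stream(c(base, list(open_row("E1", t0 + 3000),
                                close_row("E1", t0 + 3600))))
  run <- run_cds_engine(s, cfg)
  expect_equal(nrow(run$alerts), 1L)
  expect_equal(run$alerts$clinician_id, "md1")
  expect_gte(run$alerts$delivered_at, run$alerts$created_at)
  expect_true(run$alerts$reminder_delivered)
  # respiratory therapist: no delivery, logged
  s2 <- make_stream(c(base, list(open_row("E1", t0 + 3000, "rt1",
                                          "respiratory_therapist"))))
  run2 <- run_cds_engine(s2, cfg)
  expect_equal(nrow(run2$alerts), 0L)
  expect_true(any(run2$log$what == "chart_open_nontreating"))
  # no pending nonadherence: chart open delivers nothing
  s3 <- make_stream(list(adm_row("E1", t0), vent_row("E1", t0 + 60),
                         open_row("E1", t0 + 120)))
  expect_equal(nrow(run_cds_engine(s3, cfg)$alerts), 0L)
})

test_that("recommendations addressed before chart close suppress the reminder", {
  t0 <- t_at(0)
  s <- make_stream(list(
    adm_row("E1", t0),
    vent_row("E1", t0 + 600, fio2 = 1.0, peep = 5),
    gas_row("E1", t0 + 1800, 80),
    xray_row("E1", t0 + 2400),
    open_row("E1", t0 + 3000),
    # settings corrected during the session (PEEP into the FiO2-1.0 row)
    vent_row("E1", t0 + 3300, fio2 = 1.0, peep = 18),
    order_row("E1", t0 + 3310, "ventilation"),
    order_row("E1", t0 + 3320, "oxygenation"),
    close_row("E1", t0 + 3600)))
  run <- run_cds_engine(s, cfg)
  expect_equal(nrow(run$alerts), 1L)
  expect_false(run$alerts$reminder_delivered)
})

test_that("new biomedical data re-evokes the cycle outside the window; suppression ends it", {
  t0 <- t_at(0)
  base <- list(
    adm_row("E1", t0, intubation_time = t0 - 3600),
    vent_row("E1", t0 + 600, fio2 = 1.0, peep = 5),
    gas_row("E1", t0 + 1800, 80),
    xray_row("E1", t0 + 2400),
    open_row("E1", t0 + 3000))
  # fresh nonadherent event + chart open 17 h later: second alert
  again <- list(gas_row("E1", t0 + 18 * 3600, 82),
                open_row("E1", t0 + 18 * 3600 + 600))
  run <- run_cds_engine(make_stream(c(base, again)), cfg)
  expect_equal(nrow(run$alerts), 2L)
  # same but with a not-ARDS response in between: zero later alerts
  resp <- list(resp_row("E1", t0 + 3300, action = "not_ards"))
  run2 <- run_cds_engine(make_stream(c(base, resp, again)), cfg)
  expect_equal(nrow(run2$alerts), 1L)
  expect_equal(nrow(run2$suppression), 1L)
  expect_true(all(run2$alerts$delivered_at <= run2$suppression$time))
  # within-window reopen is withheld and logged
  soon <- list(open_row("E1", t0 + 4 * 3600))
  run3 <- run_cds_engine(make_stream(c(base, soon)), cfg)
  expect_equal(nrow(run3$alerts), 1L)
  expect_true(any(run3$log$what == "alert_withheld"))
})

test_that("alert text renders the physiologic evidence and each recommendation", {
  recs <- list(lpvalert:::new_recommendation("tidal_volume_too_large",
                                             "Vt 600 at PBW 70", t_at(0)))
  txt <- render_alert_text(200, recs, cfg)
  expect_match(txt, "P/F ratio 200")
  expect_match(txt, "tidal_volume_too_large")
  expect_match(txt, "55-68")
})
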