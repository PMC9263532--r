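test_that("initial guideline nonadherence counts encounters, not events", {
  summ <- data.frame(encounter_id = paste0("E", 1:6),
                     n_trigger_events = c(3, 1, 2, 1, 4, 0),
                     n_possible_ards_events = c(2, 1, 0, 0, 3, 0),
                     n_nonadherent_events = c(2, 1, 0, 0, 0, 0),
                     n_alerts_sent = c(4, 1, 0, 0, 0, 0))
  # 5 trigger-bearing encounters, 2 with a nonadherent event
  expect_equal(initial_nonadherence(summ), 0.40)
  none <- summ; none$n_nonadherent_events <- 0
  expect_equal(initial_nonadherence(none), 0)
  empty <- summ; empty$n_trigger_events <- 0
  expect_error(initial_nonadherence(empty), "undefined")
})

test_that("recommendation adherence reproduces the deployment percentages", {
  expect_equal(recommendation_adherence(1566, 3281)$percent, 47.7)
  expect_equal(recommendation_adherence(156, 1119)$percent, 13.9)
  expect_equal(recommendation_adherence(1410, 2162)$percent, 65.2)
  expect_equal(recommendation_adherence(0, 10)$percent, 0)
  expect_error(recommendation_adherence(0, 0), "undefined")
})

test_that("followed classification honours the 2-hour window", {
  t0 <- t_at(0)
  mk <- function(fix_minutes, fix = TRUE) {
    rows <- list(
      adm_row("E1", t0),
      vent_row("E1", t0 + 600, fio2 = 1.0, peep = 5),
      order_row("E1", t0 + 700, "ventilation"),
      order_row("E1", t0 + 710, "oxygenation"),
      gas_row("E1", t0 + 1800, 80),
      xray_row("E1", t0 + 2400),
      open_row("E1", t0 + 3000))
    if (fix)
      rows <- c(rows, list(vent_row("E1", t0 + 3000 + fix_minutes * 60,
                                    fio2 = 1.0, peep = 18)))
    make_stream(rows)
  }
  cfg <- cds_config()
  # settings enter the grid 90 min after delivery: followed
  s <- mk(90)
  run <- run_cds_engine(s, cfg)
  fol <- classify_followed(run, s, cfg)
  expect_equal(fol$rec_type, "peep_fio2_inappropriate")
  expect_true(fol$followed)
  # same change at 150 min: outside the window
  s2 <- mk(150)
  expect_false(classify_followed(run_cds_engine(s2, cfg), s2, cfg)$followed)
  # no change at all: not followed
  s3 <- mk(0, fix = FALSE)
  expect_false(classify_followed(run_cds_engine(s3, cfg), s3, cfg)$followed)
  # order-type recommendation: both protocols ordered 30 min after delivery
  s4 <- make_stream(list(
    adm_row("E4", t0),
    vent_row("E4", t0 + 600),  # grid-adherent settings
    gas_row("E4", t0 + 1800, 80),
    xray_row("E4", t0 + 2400),
    open_row("E4", t0 + 3000),
    order_row("E4", t0 + 3000 + 1800, "ventilation"),
    order_row("E4", t0 + 3000 + 1810, "oxygenation")))
  run4 <- run_cds_engine(s4, cfg)
  fol4 <- classify_followed(run4, s4, cfg)
  expect_equal(fol4$rec_type, "protocols_not_ordered")
  expect_true(fol4$followed)
  # a widened window flips the 150-minute change to followed
  cfg_wide <- cds_config(adherence_window_minutes = 240)
  expect_true(classify_followed(run_cds_engine(s2, cfg_wide), s2,
                                cfg_wide)$followed)
})

test_that("alerts-prevented arithmetic matches the site-mean formula", {
  one <- data.frame(n_possible_ards_events = 10, n_nonadherent_events = 4,
                    n_alerts_sent = 12)
  r <- alerts_prevented(one)
  expect_equal(r$count, 18)  # (10-4) * 12/4
  expect_equal(r$percent, 100 * 18 / (18 + 12))
  two <- rbind(one, data.frame(n_possible_ards_events = 6,
                               n_nonadherent_events = 6, n_alerts_sent = 6))
  r2 <- alerts_prevented(two)
  expect_equal(r2$count, 18)
  expect_equal(r2$percent, 50)
  # a site with zero nonadherent events contributes zero
  zero <- data.frame(n_possible_ards_events = 5, n_nonadherent_events = 0,
                     n_alerts_sent = 0)
  expect_equal(alerts_prevented(zero)$count, 0)
  bad <- data.frame(n_possible_ards_events = 3, n_nonadherent_events = 4,
                    n_alerts_sent = 2)
  expect_error(alerts_prevented(bad), "exceed")
  # single-site identity on random integers
  set.seed(11)
  for (i in 1:50) {
    non <- sample(1:20, 1); poss <- non + sample(0:20, 1)
    al <- sample(0:60, 1)
    df <- data.frame(n_possible_ards_events = poss,
                     n_nonadherent_events = non, n_alerts_sent = al)
    expect_equal(alerts_prevented(df)$count, (poss - non) * al / non)
  }
})

test_that("mean alerts per nonadherent event renders at one decimal", {
  expect_equal(mean_alerts_per_event(2876, 455)$rendered, 6.3)
  expect_equal(mean_alerts_per_event(1718, 170)$rendered, 10.1)
  expect_equal(mean_alerts_per_event(0, 5)$rendered, 0)
  expect_error(mean_alerts_per_event(10, 0), "undefined")
})

test_that("binomial intervals: Wald matches survey rendering, Clopper-Pearson is exact-style", {
  w <- binomial_ci(16, 22, "wald")
  expect_equal(round(w$lower, 2), 0.54)
  expect_equal(round(w$upper, 2), 0.91)
  expect_equal(binomial_ci(10, 10, "wald")$upper, 1)
  expect_equal(binomial_ci(10, 10, "clopper_pearson")$upper, 1)
  expect_equal(binomial_ci(0, 10, "clopper_pearson")$lower, 0)
  # Clopper-Pearson contains the point estimate and stays in [0, 1]
  set.seed(3)
  for (i in 1:60) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    for (m in c("clopper_pearson", "wald")) {
      ci <- binomial_ci(k, n, m)
      expect_lte(ci$lower, k / n + 1e-12)
      expect_gte(ci$upper, k / n - 1e-12)
      expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
    }
  }
  # cross-check the exact interval against stats::binom.test
  bt <- stats::binom.test(16, 22)$conf.int
  cp <- binomial_ci(16, 22, "clopper_pearson")
  expect_equal(cp$lower, bt[1], tolerance = 1e-9)
  expect_equal(cp$upper, bt[2], tolerance = 1e-9)
  expect_error(binomial_ci(5, 0), "n > 0")
})

test_that("two-proportion comparison reproduces the adopt-vs-specific contrast", {
  r <- proportion_difference_ci(156, 1119, 1410, 2162)
  expect_equal(round(r$difference, 2), 0.51)
  expect_equal(round(r$lower, 2), 0.48)
  expect_equal(round(r$upper, 2), 0.54)
  expect_lt(r$p_value, 0.001)
  same <- proportion_difference_ci(30, 100, 60, 200)
  expect_equal(same$difference, 0)
  expect_equal(same$lower, -same$upper)
  deg <- proportion_difference_ci(0, 10, 10, 10)
  expect_equal(deg$difference, 1)
  expect_true(is.finite(deg$lower) && is.finite(deg$upper))
  expect_lt(deg$p_value, 0.01)
})

test_that("contingency metrics cover the screening quantities and flag undefined ones", {
  perfect <- contingency_metrics(1, 0, 0, 1)
  expect_equal(perfect$sensitivity$estimate, 1)
  expect_equal(perfect$fpr$estimate, 0)
  expect_equal(perfect$accuracy$estimate, 1)
  cand <- contingency_metrics(35, 22, 5, 11)
  expect_equal(round(cand$accuracy$estimate, 2), 0.63)
  expect_equal(cand$sensitivity$estimate, 0.875)
  expect_equal(round(cand$ppv$estimate, 2), 0.61)
  expect_equal(round(cand$fpr$estimate, 2), 0.67)
  # exact CI for sensitivity spans 0.73-0.96 at this cell mix
  expect_equal(round(cand$sensitivity$lower, 2), 0.73)
  expect_equal(round(cand$sensitivity$upper, 2), 0.96)
  und <- contingency_metrics(0, 0, 3, 5)
  expect_true(is.na(und$ppv$estimate))
  expect_true("ppv" %in% und$undefined)
  expect_error(contingency_metrics(0, 0, 0, 0), "positive total")
})

test_that("Hanley-McNeil AUROC: boundary tables, intermediates, and pairwise oracle", {
  perfect <- auroc_hanley_mcneil(10, 0, 0, 8)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$se, 0)
  flat <- auroc_hanley_mcneil(7, 7, 3, 3)
  expect_equal(flat$auc, 0.5)
  cand <- auroc_hanley_mcneil(35, 22, 5, 11)
  expect_equal(round(cand$auc, 3), 0.604)
  expect_equal(cand$q1, cand$auc / (2 - cand$auc))
  expect_equal(cand$q2, 2 * cand$auc^2 / (1 + cand$auc))
  expect_true(cand$ci95[1] >= 0 && cand$ci95[2] <= 1)
  expect_error(auroc_hanley_mcneil(0, 3, 0, 4), "empty class")
  # independent oracle: exhaustive pairwise comparison of case scores
  auc_pairwise <- function(tp, fp, fn, tn) {
    pos <- c(rep(1, tp), rep(0, fn)); neg <- c(rep(1, fp), rep(0, tn))
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(cand$auc, auc_pairwise(35, 22, 5, 11))
  set.seed(5)
  for (i in 1:40) {
    cells <- c(sample(0:12, 2, TRUE), sample(0:12, 2, TRUE))
    if (cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
    expect_equal(auroc_hanley_mcneil(cells[1], cells[2], cells[3],
                                     cells[4])$auc,
                 auc_pairwise(cells[1], cells[2], cells[3], cells[4]))
  }
})

test_that("encounter-level contingency table is built from sidecar truth", {
  summ <- data.frame(encounter_id = c("E1", "E2", "E3", "E4"),
                     n_trigger_events = c(2, 1, 1, 1),
                     n_possible_ards_events = c(1, 0, 2, 0),
                     n_nonadherent_events = c(1, 0, 0, 0),
                     n_alerts_sent = c(1, 0, 0, 0))
  truth <- data.frame(encounter_id = c("E1", "E2", "E3", "E4"),
                      possible_ards = c(TRUE, TRUE, FALSE, FALSE))
  tab <- build_contingency(summ, truth)
  expect_equal(unname(tab), c(1L, 1L, 1L, 1L))
})
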