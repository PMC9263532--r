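# Service-outcome and accuracy statistics for an engine run: guideline
# nonadherence, recommendation adherence within a configurable window,
# alerts prevented by the treatment-detection step, binomial confidence
# intervals (Wald and Clopper-Pearson exact), a two-proportion z
# comparison, screening contingency metrics, and the nonparametric AUROC
# with the Hanley-McNeil standard error.

#' Per-encounter summaries of an engine run
#'
#' @param run A `cds_run` from [run_cds_engine()].
#' @param sites Optional named character vector mapping encounter_id to
#'   site id (e.g. from the admission events); defaults to a single site.
#' @return Data frame with one row per encounter: fired trigger count,
#'   possible-ARDS event count, nonadherent event count, alerts sent, site.
#' @export
summarize_encounters <- function(run, sites = NULL) {
  enc <- run$encounters
  cnt <- function(ids) {
    tab <- table(factor(ids, levels = enc))
    as.integer(tab)
  }
  fired <- run$triggers$encounter_id[run$triggers$decision == "fired"]
  pos <- run$possible_ards$encounter_id[
    run$possible_ards$status %in% c("adherent", "nonadherent")]
  nonadh <- run$possible_ards$encounter_id[
    run$possible_ards$status == "nonadherent"]
  out <- data.frame(encounter_id = enc,
                    n_trigger_events = cnt(fired),
                    n_possible_ards_events = cnt(pos),
                    n_nonadherent_events = cnt(nonadh),
                    n_alerts_sent = cnt(run$alerts$encounter_id),
                    stringsAsFactors = FALSE)
  out$site <- if (is.null(sites)) "site_1" else unname(sites[enc])
  out
}

#' Initial guideline nonadherence
#'
#' The fraction of patient encounters with at least one trigger event that
#' had at least one possible-ARDS event where LPV treatment was not
#' detected. Numerator and denominator count encounters, not events.
#'
#' @param summaries Data frame from [summarize_encounters()].
#' @return Proportion in \[0, 1\].
#' @export
initial_nonadherence <- function(summaries) {
  elig <- summaries$n_trigger_events > 0
  if (!any(elig))
    stop("no encounters with a trigger event; nonadherence undefined",
         call. = FALSE)
  sum(summaries$n_nonadherent_events[elig] > 0) / sum(elig)
}

#' Classify delivered recommendations as followed
#'
#' A recommendation counts as followed when a change in treatment
#' consistent with it — the relevant protocol order for order-type
#' recommendations, settings moved into compliance for setting- and
#' mode-type recommendations — is observed within `window_minutes` after
#' alert delivery. The encounter stream is replayed and the
#' recommendation-specific check re-evaluated at each charting event inside
#' the window.
#'
#' @param run A `cds_run`.
#' @param events The event stream the run was computed from.
#' @param cfg A [cds_config()]; `adherence_window_minutes` sets the window.
#' @return The run's `recommendations` ledger with a logical `followed`
#'   column added.
#' @export
classify_followed <- function(run, events, cfg = run$config) {
  if (is.null(cfg)) cfg <- cds_config()
  recs <- run$recommendations
  recs$followed <- FALSE
  if (!nrow(recs)) return(recs)
  window <- cfg$adherence_window_minutes * 60
  for (enc in unique(recs$encounter_id)) {
    rows <- which(events$encounter_id == enc)
    ridx <- which(recs$encounter_id == enc)
    # replay treatment state through the encounter; after each relevant
    # event, resolve any open recommendation whose check now passes
    state <- new_encounter_state()
    for (i in rows) {
      ev <- lapply(events, function(col) col[i])
      if (ev$type == "admission") state$attrs <- attrs_from_event(ev)
      changed <- FALSE
      if (ev$type == "vent_settings") {
        state$settings <- list(mode = ev$mode, tidal_volume = ev$tidal_volume,
                               peep = ev$peep, fio2 = ev$fio2,
                               pressure_support = ev$pressure_support,
                               time = ev$time)
        changed <- TRUE
      } else if (ev$type == "protocol_order") {
        if (ev$protocol %in% c("ventilation", "both"))
          state$vent_ordered <- TRUE
        if (ev$protocol %in% c("oxygenation", "both"))
          state$oxy_ordered <- TRUE
        changed <- TRUE
      }
      if (!changed || is.null(state$settings)) next
      dt <- as.numeric(difftime(ev$time, recs$delivered_at[ridx],
                                units = "secs"))
      open <- ridx[dt > 0 & dt <= window & !recs$followed[ridx]]
      for (j in open) {
        if (!rec_applies_now(recs$rec_type[j], state, cfg))
          recs$followed[j] <- TRUE
      }
    }
  }
  recs
}

#' Recommendation adherence proportion
#'
#' @param followed_count Recommendations followed within the window.
#' @param total_count Total recommendations delivered (> 0).
#' @return List with `proportion` and `percent` (rendered half-up at one
#'   decimal).
#' @examples
#' recommendation_adherence(1566, 3281)$percent  # 47.7
#' @export
recommendation_adherence <- function(followed_count, total_count) {
  if (total_count <= 0)
    stop("adherence undefined with zero recommendations", call. = FALSE)
  p <- followed_count / total_count
  list(proportion = p, percent = round_half_up(100 * p, 1))
}

# round half away from zero at `digits` (matches report rendering, where
# 47.75 -> 47.8, unlike banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Table-3-style adherence report by recommendation type
#'
#' @param followed_recs Recommendations ledger with a `followed` column
#'   (from [classify_followed()]).
#' @return Data frame with one row per recommendation type plus category
#'   subtotals and a total row: counts, percent of total instructions, and
#'   percent adherent.
#' @export
adherence_by_type <- function(followed_recs) {
  types <- recommendation_types()
  n <- vapply(types$rec_type, function(tp)
    sum(followed_recs$rec_type == tp), integer(1))
  k <- vapply(types$rec_type, function(tp)
    sum(followed_recs$followed[followed_recs$rec_type == tp]), integer(1))
  total <- nrow(followed_recs)
  row <- function(label, category, n, k)
    data.frame(recommendation = label, category = category, n = n,
               pct_of_total = if (total > 0) round_half_up(100 * n / total, 1)
                              else NA_real_,
               followed = k,
               pct_adherent = if (n > 0) round_half_up(100 * k / n, 1)
                              else NA_real_,
               stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(types)), function(i)
    row(types$rec_type[i], types$category[i], n[i], k[i])))
  for (cat in c("adopt_protocol", "specific_setting")) {
    sel <- types$category == cat
    out <- rbind(out, row(paste0("subtotal_", cat), cat, sum(n[sel]),
                          sum(k[sel])))
  }
  rbind(out, row("total", "all", total, sum(k)))
}

#' Alerts prevented by treatment-detection logic
#'
#' For each site, the difference between possible-ARDS events and
#' nonadherent possible-ARDS events is multiplied by that site's mean
#' alert messages per nonadherent event; sites with zero nonadherent events
#' contribute zero. The percentage relates prevented alerts to the total
#' that would have been sent under disease detection alone.
#'
#' @param per_site Data frame with columns `n_possible_ards_events`,
#'   `n_nonadherent_events`, `n_alerts_sent` (one row per site).
#' @return List with `count` and `percent`.
#' @examples
#' alerts_prevented(data.frame(n_possible_ards_events = 10,
#'                             n_nonadherent_events = 4,
#'                             n_alerts_sent = 12))  # 18 prevented, 60%
#' @export
alerts_prevented <- function(per_site) {
  diffs <- per_site$n_possible_ards_events - per_site$n_nonadherent_events
  if (any(diffs < 0))
    stop("nonadherent events exceed possible-ARDS events at some site",
         call. = FALSE)
  contrib <- ifelse(per_site$n_nonadherent_events > 0,
                    diffs * per_site$n_alerts_sent /
                      per_site$n_nonadherent_events,
                    0)
  count <- sum(contrib)
  sent <- sum(per_site$n_alerts_sent)
  list(count = count,
       percent = if (count + sent > 0) 100 * count / (count + sent) else 0)
}

#' Mean alert messages per nonadherent possible-ARDS event
#'
#' @param n_alerts Alert messages sent.
#' @param n_nonadherent_events Nonadherent possible-ARDS events (> 0).
#' @return List with `ratio` and `rendered` (one decimal).
#' @examples
#' mean_alerts_per_event(2876, 455)$rendered  # 6.3
#' @export
mean_alerts_per_event <- function(n_alerts, n_nonadherent_events) {
  if (n_nonadherent_events <= 0)
    stop("ratio undefined with zero nonadherent events", call. = FALSE)
  r <- n_alerts / n_nonadherent_events
  list(ratio = r, rendered = round_half_up(r, 1))
}

#' Binomial confidence interval
#'
#' `clopper_pearson` gives the exact interval from beta quantiles;
#' `wald` gives the normal approximation truncated to \[0, 1\].
#'
#' @param k Successes (0..n).
#' @param n Trials (> 0).
#' @param method `"clopper_pearson"` or `"wald"`.
#' @param conf Confidence level.
#' @return List with `estimate`, `lower`, `upper`, `method`.
#' @export
binomial_ci <- function(k, n, method = c("clopper_pearson", "wald"),
                        conf = 0.95) {
  method <- match.arg(method)
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n, n > 0",
                                     call. = FALSE)
  p <- k / n
  a <- 1 - conf
  if (method == "clopper_pearson") {
    lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - a / 2)
    se <- sqrt(p * (1 - p) / n)
    lower <- max(0, p - z * se)
    upper <- min(1, p + z * se)
  }
  list(estimate = p, lower = lower, upper = upper, method = method)
}

#' Two-proportion difference with Wald interval and z test
#'
#' Difference is `k2/n2 - k1/n1`; the confidence interval uses the
#' unpooled Wald standard error, the p-value the pooled two-proportion z
#' test. A degenerate zero standard error (all successes/failures) is
#' handled with a 0.5-count continuity floor.
#'
#' @param k1,n1 First group successes / trials.
#' @param k2,n2 Second group successes / trials.
#' @param conf Confidence level.
#' @return List with `difference`, `lower`, `upper`, `z`, `p_value`.
#' @export
proportion_difference_ci <- function(k1, n1, k2, n2, conf = 0.95) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  diff <- p2 - p1
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se == 0) {
    p1c <- (k1 + 0.5) / (n1 + 1); p2c <- (k2 + 0.5) / (n2 + 1)
    se <- sqrt(p1c * (1 - p1c) / n1 + p2c * (1 - p2c) / n2)
  }
  z_crit <- stats::qnorm(1 - (1 - conf) / 2)
  pp <- (k1 + k2) / (n1 + n2)
  se0 <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se0 == 0) se0 <- se
  z <- diff / se0
  list(difference = diff, lower = diff - z_crit * se,
       upper = diff + z_crit * se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Screening contingency metrics
#'
#' Sensitivity, specificity, false-positive rate, positive and negative
#' predictive value, and accuracy for a 2x2 screen-vs-gold-standard table,
#' each with a binomial confidence interval. Metrics with a zero
#' denominator are returned as `NA` and listed in `undefined`.
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts (total > 0).
#' @param ci_method Passed to [binomial_ci()].
#' @return Object of class `contingency_metrics`.
#' @export
contingency_metrics <- function(tp, fp, fn, tn,
                                ci_method = c("clopper_pearson", "wald")) {
  ci_method <- match.arg(ci_method)
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || sum(cells) == 0)
    stop("contingency table needs nonnegative counts with positive total",
         call. = FALSE)
  defs <- list(sensitivity = c(tp, tp + fn),
               specificity = c(tn, tn + fp),
               fpr = c(fp, fp + tn),
               ppv = c(tp, tp + fp),
               npv = c(tn, tn + fn),
               accuracy = c(tp + tn, sum(cells)))
  undefined <- character(0)
  est <- list()
  for (nm in names(defs)) {
    k <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n == 0) {
      est[[nm]] <- list(estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, method = ci_method)
      undefined <- c(undefined, nm)
    } else est[[nm]] <- binomial_ci(k, n, ci_method)
  }
  structure(c(est, list(table = cells, undefined = undefined)),
            class = "contingency_metrics")
}

#' @export
print.contingency_metrics <- function(x, ...) {
  cat("<contingency_metrics> tp/fp/fn/tn =",
      paste(x$table, collapse = "/"), "\n")
  for (nm in c("sensitivity", "specificity", "fpr", "ppv", "npv",
               "accuracy")) {
    e <- x[[nm]]
    if (is.na(e$estimate)) cat(sprintf("  %-11s: undefined\n", nm))
    else cat(sprintf("  %-11s: %.3f [%.3f, %.3f]\n", nm, e$estimate,
                     e$lower, e$upper))
  }
  invisible(x)
}

#' Nonparametric AUROC with Hanley-McNeil standard error
#'
#' For a binary screen the nonparametric area under the ROC curve equals
#' the probability a random diseased case outranks a random nondiseased
#' case, with ties credited one half:
#' `A = (tp*tn + 0.5*(tp*fp + fn*tn)) / ((tp+fn)*(fp+tn))`. The standard
#' error uses the Hanley-McNeil closed form with `Q1 = A/(2-A)` and
#' `Q2 = 2*A^2/(1+A)`; the confidence interval is `A +/- z*SE` truncated
#' to \[0, 1\].
#'
#' @param tp,fp,fn,tn Cell counts; both classes must be nonempty.
#' @param conf Confidence level.
#' @return Object of class `auroc_hm` with `auc`, `se`, `ci95`, `n_pos`,
#'   `n_neg`, `q1`, `q2`.
#' @examples
#' auroc_hanley_mcneil(35, 22, 5, 11)$auc  # ~0.604
#' @export
auroc_hanley_mcneil <- function(tp, fp, fn, tn, conf = 0.95) {
  n_pos <- tp + fn; n_neg <- fp + tn
  if (n_pos <= 0 || n_neg <= 0)
    stop("AUROC undefined with an empty class", call. = FALSE)
  a <- (tp * tn + 0.5 * (tp * fp + fn * tn)) / (n_pos * n_neg)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(auc = a, se = se,
                 ci95 = c(max(0, a - z * se), min(1, a + z * se)),
                 n_pos = n_pos, n_neg = n_neg, q1 = q1, q2 = q2),
            class = "auroc_hm")
}

#' @export
print.auroc_hm <- function(x, ...) {
  cat(sprintf("<auroc_hm> AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f; n+=%d, n-=%d)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Encounter-level contingency table against ground truth
#'
#' Screen-positive means the engine emitted at least one possible-ARDS
#' event for the encounter; truth is the (synthetic or adjudicated) label.
#'
#' @param summaries From [summarize_encounters()].
#' @param truth Data frame with `encounter_id` and logical `possible_ards`.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
build_contingency <- function(summaries, truth) {
  m <- merge(summaries, truth[, c("encounter_id", "possible_ards")],
             by = "encounter_id")
  screen <- m$n_possible_ards_events > 0
  gold <- as.logical(m$possible_ards)
  c(tp = sum(screen & gold), fp = sum(screen & !gold),
    fn = sum(!screen & gold), tn = sum(!screen & !gold))
}

#' Full service-outcome report for a run
#'
#' Computes the evaluation aggregates for an engine run: per-site
#' performance (trigger encounters, initial nonadherence, alerts sent,
#' alerts per nonadherent event, alerts prevented), the adherence-by-type
#' table, and, when ground truth is supplied, the accuracy block
#' (contingency metrics and Hanley-McNeil AUROC).
#'
#' @param run A `cds_run`.
#' @param events The event stream the run came from.
#' @param truth Optional ground-truth data frame (see
#'   [build_contingency()]).
#' @param cfg A [cds_config()].
#' @return Object of class `cds_report`.
#' @export
evaluate_run <- function(run, events, truth = NULL, cfg = run$config) {
  if (is.null(cfg)) cfg <- cds_config()
  adm <- events[events$type == "admission", ]
  sites <- NULL
  if (nrow(adm) && any(!is.na(adm$site)))
    sites <- stats::setNames(adm$site, adm$encounter_id)
  summaries <- summarize_encounters(run, sites)
  followed <- classify_followed(run, events, cfg)
  by_type <- adherence_by_type(followed)
  per_site <- do.call(rbind, lapply(split(summaries, summaries$site),
    function(s) data.frame(
      site = s$site[1],
      n_encounters = sum(s$n_trigger_events > 0),
      nonadherence_pct = if (any(s$n_trigger_events > 0))
        round_half_up(100 * initial_nonadherence(s), 0) else NA_real_,
      n_possible_ards_events = sum(s$n_possible_ards_events),
      n_nonadherent_events = sum(s$n_nonadherent_events),
      n_alerts_sent = sum(s$n_alerts_sent),
      alerts_per_event = if (sum(s$n_nonadherent_events) > 0)
        mean_alerts_per_event(sum(s$n_alerts_sent),
                              sum(s$n_nonadherent_events))$rendered
        else NA_real_,
      stringsAsFactors = FALSE)))
  rownames(per_site) <- NULL
  prevented <- alerts_prevented(per_site)
  overall <- list(
    n_encounters = sum(summaries$n_trigger_events > 0),
    n_trigger_events = sum(summaries$n_trigger_events),
    n_possible_ards_events = sum(summaries$n_possible_ards_events),
    n_nonadherent_events = sum(summaries$n_nonadherent_events),
    n_alerts_sent = sum(summaries$n_alerts_sent),
    n_recommendations = nrow(followed),
    initial_nonadherence = initial_nonadherence(summaries),
    recommendation_adherence = if (nrow(followed) > 0)
      recommendation_adherence(sum(followed$followed), nrow(followed))
      else NULL,
    alerts_prevented = prevented)
  accuracy <- NULL
  if (!is.null(truth)) {
    tab <- build_contingency(summaries, truth)
    accuracy <- list(
      table = tab,
      metrics = contingency_metrics(tab["tp"], tab["fp"], tab["fn"],
                                    tab["tn"]),
      auroc = tryCatch(auroc_hanley_mcneil(tab["tp"], tab["fp"], tab["fn"],
                                           tab["tn"]),
                       error = function(e) NULL))
  }
  structure(list(overall = overall, per_site = per_site,
                 adherence_by_type = by_type, encounter_summaries = summaries,
                 followed = followed, accuracy = accuracy),
            class = "cds_report")
}

#' @export
print.cds_report <- function(x, ...) {
  o <- x$overall
  cat("<cds_report>\n")
  cat(sprintf("  encounters with trigger : %d\n", o$n_encounters))
  cat(sprintf("  trigger events          : %d\n", o$n_trigger_events))
  cat(sprintf("  possible ARDS events    : %d (%d nonadherent)\n",
              o$n_possible_ards_events, o$n_nonadherent_events))
  cat(sprintf("  initial nonadherence    : %.1f%%\n",
              100 * o$initial_nonadherence))
  if (!is.null(o$recommendation_adherence))
    cat(sprintf("  recommendation adherence: %.1f%% of %d\n",
                o$recommendation_adherence$percent, o$n_recommendations))
  cat(sprintf("  alerts sent / prevented : %d / %.0f (%.0f%%)\n",
              o$n_alerts_sent, o$alerts_prevented$count,
              o$alerts_prevented$percent))
  if (!is.null(x$accuracy)) {
    cat("  accuracy block:\n")
    print(x$accuracy$metrics)
    if (!is.null(x$accuracy$auroc)) print(x$accuracy$auroc)
  }
  invisible(x)
}
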