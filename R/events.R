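# Event-stream schema shared by the generator, the engine and the readers.
# One row per charting fact; payload columns are NA when not applicable to
# the row's type. The (time, event_id) pair gives a strict total order
# within an encounter.

CDS_SCHEMA_VERSION <- "cds-event/1"

# canonical column order (also the canonical JSONL field order)
cds_event_columns <- function() {
  c("encounter_id", "event_id", "time", "type",
    # admission payload
    "site", "age", "sex", "height", "care_unit", "palliative_care",
    "attending_specialty", "on_mcs", "pa_catheter", "airway_status",
    "intubation_time",
    # physiology / settings payloads
    "pao2", "mode", "tidal_volume", "peep", "fio2", "pressure_support",
    # text / orders / workflow payloads
    "report_text", "protocol", "clinician_id", "role", "action",
    "reason", "reason_text")
}

cds_event_types <- function() {
  c("admission", "blood_gas", "vent_settings", "radiograph",
    "protocol_order", "chart_open", "chart_close", "response")
}

# required payload fields per type (others must be NA/absent)
cds_required_fields <- function() {
  list(
    admission      = c("age", "sex", "care_unit", "airway_status"),
    blood_gas      = "pao2",
    vent_settings  = c("mode", "fio2"),
    radiograph     = "report_text",
    protocol_order = "protocol",
    chart_open     = c("clinician_id", "role"),
    chart_close    = "clinician_id",
    response       = c("clinician_id", "action")
  )
}

character_cols <- c("encounter_id", "type", "site", "sex", "care_unit",
                    "attending_specialty", "airway_status", "mode",
                    "report_text", "protocol", "clinician_id", "role",
                    "action", "reason", "reason_text")
numeric_cols <- c("age", "height", "pao2", "tidal_volume", "peep", "fio2",
                  "pressure_support")
logical_cols <- c("palliative_care", "on_mcs", "pa_catheter")
time_cols <- c("time", "intubation_time")

#' Parse an ISO-8601 timestamp into UTC
#'
#' Accepts `YYYY-MM-DDTHH:MM:SSZ` or an explicit numeric offset
#' (`...+05:00` / `...+0500`); the internal representation is always POSIXct
#' in UTC so the 16-hour and 2-hour windows are unambiguous.
#'
#' @param x Character vector of timestamps.
#' @return POSIXct vector (UTC); `NA` inputs stay `NA`, unparsable inputs
#'   raise an error.
#' @export
parse_cds_time <- function(x) {
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  v <- x[ok]
  z <- grepl("Z$", v)
  res <- rep(as.POSIXct(NA, tz = "UTC"), length(v))
  if (any(z))
    res[z] <- as.POSIXct(v[z], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (any(!z)) {
    w <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", v[!z])
    res[!z] <- as.POSIXct(w, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  }
  if (anyNA(res))
    stop("unparsable ISO-8601 timestamp(s): ",
         paste(utils::head(v[is.na(res)], 3), collapse = ", "), call. = FALSE)
  out[ok] <- res
  out
}

#' Format a UTC timestamp canonically
#'
#' @param t POSIXct vector.
#' @return Character vector `YYYY-MM-DDTHH:MM:SSZ` (`NA` preserved).
#' @export
format_cds_time <- function(t) {
  out <- rep(NA_character_, length(t))
  ok <- !is.na(t)
  out[ok] <- format(as.POSIXct(t[ok], tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ",
                    tz = "UTC")
  out
}

#' Normalize a charted FiO2 value to a fraction
#'
#' EHR exports chart FiO2 in two dialects: a fraction in (0, 1] or a percent
#' in (1, 100]. Values above 1 are interpreted as percent and divided by
#' 100. The result must land in the physically meaningful range
#' [0.21, 1.0] (ambient air to pure oxygen) or an error is raised.
#'
#' @param raw Numeric vector of charted values.
#' @return Numeric vector of fractions in [0.21, 1.0].
#' @examples
#' normalize_fio2(c(0.21, 45, 100))
#' @export
normalize_fio2 <- function(raw) {
  if (!is.numeric(raw)) stop("FiO2 must be numeric", call. = FALSE)
  out <- ifelse(!is.na(raw) & raw > 1, raw / 100, raw)
  bad <- !is.na(out) & (out < 0.21 - 1e-9 | out > 1 + 1e-9)
  if (any(bad))
    stop("FiO2 value(s) outside [0.21, 1.0] after normalization: ",
         paste(utils::head(raw[bad], 3), collapse = ", "), call. = FALSE)
  pmin(pmax(out, 0.21), 1)
}

empty_event_frame <- function(n = 0L) {
  cols <- cds_event_columns()
  df <- data.frame(matrix(nrow = n, ncol = 0))
  for (cl in cols) {
    df[[cl]] <-
      if (cl %in% character_cols) rep(NA_character_, n)
      else if (cl %in% numeric_cols) rep(NA_real_, n)
      else if (cl %in% logical_cols) rep(NA, n)
      else if (cl %in% time_cols) rep(as.POSIXct(NA, tz = "UTC"), n)
      else rep(NA_integer_, n)  # event_id
  }
  df
}

#' Validate, order and class an event-stream data frame
#'
#' Enforces the stream contract: known event types, required payload fields
#' present per type, positive PaO2, FiO2 normalized to a fraction,
#' nonnegative settings, unique `event_id` within each encounter and
#' deterministic ordering by `(encounter_id, time, event_id)`.
#'
#' @param events Data frame with (a subset of) the canonical event columns.
#' @return The ordered stream with class `cds_stream`.
#' @export
as_cds_stream <- function(events) {
  full <- empty_event_frame(nrow(events))
  extra <- setdiff(names(events), names(full))
  if (length(extra))
    stop("unknown event column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (nm in names(events)) {
    v <- events[[nm]]
    if (nm %in% time_cols && !inherits(v, "POSIXct")) v <- parse_cds_time(v)
    if (nm %in% numeric_cols) v <- as.numeric(v)
    if (nm %in% logical_cols) v <- as.logical(v)
    if (nm == "event_id") v <- as.integer(v)
    if (nm %in% character_cols) v <- as.character(v)
    full[[nm]] <- v
  }
  if (nrow(full) == 0L) {
    class(full) <- c("cds_stream", "data.frame")
    return(full)
  }
  if (anyNA(full$encounter_id) || anyNA(full$event_id) || anyNA(full$time) ||
      anyNA(full$type))
    stop("every event needs encounter_id, event_id, time and type",
         call. = FALSE)
  unknown <- setdiff(unique(full$type), cds_event_types())
  if (length(unknown))
    stop("unknown event type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  req <- cds_required_fields()
  for (tp in intersect(names(req), unique(full$type))) {
    rows <- full$type == tp
    for (fld in req[[tp]]) {
      if (anyNA(full[[fld]][rows]))
        stop("event type `", tp, "` requires field `", fld, "`",
             call. = FALSE)
    }
  }
  bg <- full$type == "blood_gas"
  if (any(full$pao2[bg] <= 0))
    stop("PaO2 must be positive", call. = FALSE)
  vs <- full$type == "vent_settings"
  full$fio2[vs] <- normalize_fio2(full$fio2[vs])
  for (fld in c("tidal_volume", "peep", "pressure_support")) {
    v <- full[[fld]][vs]
    if (any(!is.na(v) & v < 0))
      stop("`", fld, "` must be nonnegative", call. = FALSE)
  }
  if (any(full$type == "response")) {
    rr <- which(full$type == "response")
    bad_act <- setdiff(unique(full$action[rr]),
                       c("order_protocol", "act_on_instruction", "not_ards",
                         "contraindication"))
    if (length(bad_act))
      stop("unknown response action(s): ", paste(bad_act, collapse = ", "),
           call. = FALSE)
    ci <- rr[full$action[rr] == "contraindication"]
    if (length(ci)) {
      if (anyNA(full$reason[ci]))
        stop("contraindication responses need a `reason`", call. = FALSE)
      other <- ci[full$reason[ci] == "other"]
      if (length(other) &&
          any(is.na(full$reason_text[other]) |
              !nzchar(full$reason_text[other])))
        stop("contraindication reason `other` requires nonempty `reason_text`",
             call. = FALSE)
    }
  }
  dup <- duplicated(full[c("encounter_id", "event_id")])
  if (any(dup))
    stop("duplicate event_id within encounter: ",
         paste(utils::head(sprintf("%s/%d", full$encounter_id[dup],
                                   full$event_id[dup]), 3), collapse = ", "),
         call. = FALSE)
  ord <- order(full$encounter_id, full$time, full$event_id)
  full <- full[ord, , drop = FALSE]
  rownames(full) <- NULL
  class(full) <- c("cds_stream", "data.frame")
  full
}

#' Read an event stream from JSONL or CSV
#'
#' JSONL carries one event object per line with a `schema` tag; the CSV
#' dialect is the same table in long format with ISO-8601 timestamp columns.
#' Malformed lines are reported with their line number.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"jsonl"` or `"csv"`.
#' @return A `cds_stream` data frame (see [as_cds_stream()]).
#' @export
read_event_stream <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$schema <- NULL
    return(as_cds_stream(df))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(as_cds_stream(empty_event_frame(0L)))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop("line ", i, ": invalid JSON (", conditionMessage(e),
                           ")", call. = FALSE))
    if (!is.null(rec$schema) && !identical(rec$schema, CDS_SCHEMA_VERSION))
      stop("line ", i, ": unsupported schema `", rec$schema, "`",
           call. = FALSE)
    rec$schema <- NULL
    if (is.null(rec$type) || !rec$type %in% cds_event_types())
      stop("line ", i, ": unknown payload type `",
           if (is.null(rec$type)) "<missing>" else rec$type, "`",
           call. = FALSE)
    recs[[i]] <- rec
  }
  df <- empty_event_frame(length(recs))
  cols <- cds_event_columns()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    bad <- setdiff(names(rec), cols)
    if (length(bad))
      stop("line ", i, ": unknown field(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in names(rec)) {
      v <- rec[[nm]]
      if (nm %in% time_cols) {
        df[[nm]][i] <- parse_cds_time(as.character(v))
      } else if (nm %in% numeric_cols) df[[nm]][i] <- as.numeric(v)
      else if (nm %in% logical_cols) df[[nm]][i] <- as.logical(v)
      else if (nm == "event_id") df[[nm]][i] <- as.integer(v)
      else df[[nm]][i] <- as.character(v)
    }
  }
  as_cds_stream(df)
}

#' Write an event stream canonically
#'
#' The canonical JSONL form has a fixed field order, omits empty payload
#' fields (except `report_text`, which may legitimately be an empty string)
#' and renders timestamps as ISO-8601 UTC, so `write(read(x))` is
#' byte-identical to a canonical `x`.
#'
#' @param events A `cds_stream` (or coercible data frame).
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(events, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  events <- as_cds_stream(as.data.frame(events))
  if (format == "csv") {
    out <- as.data.frame(events)
    for (tc in time_cols) out[[tc]] <- format_cds_time(out[[tc]])
    out <- cbind(schema = rep(CDS_SCHEMA_VERSION, nrow(out)), out)
    utils::write.csv(out, path, row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  cols <- cds_event_columns()
  lines <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    rec <- list(schema = CDS_SCHEMA_VERSION)
    for (nm in cols) {
      v <- events[[nm]][i]
      if (nm %in% time_cols) {
        if (!is.na(v)) rec[[nm]] <- format_cds_time(v)
      } else if (is.na(v)) {
        if (nm == "report_text" && events$type[i] == "radiograph")
          rec[[nm]] <- ""
      } else rec[[nm]] <- v
    }
    lines[i] <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cds_stream <- function(x, ...) {
  cat(sprintf("<cds_stream> %d events, %d encounter(s)\n",
              nrow(x), length(unique(x$encounter_id))))
  if (nrow(x)) {
    tab <- table(x$type)
    cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = "  "), "\n")
  }
  invisible(x)
}
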