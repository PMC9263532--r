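# Rule-based bilateral-infiltrate classifier for chest-radiograph report
# text. This is a deterministic, auditable stand-in behind a pluggable
# interface: the engine only consumes the DetectionResult, so any substitute
# classifier with the same return shape can be swapped in via the
# `detector` argument of run_cds_engine(). Matching is lexical: a report is
# positive when a non-negated infiltrate term and a non-negated laterality
# term co-occur in one sentence within a token window. Hedged findings
# ("possible", "cannot exclude") keep positive polarity — the tool screens
# for *possible* ARDS, so the rules err toward sensitivity.

#' Load the infiltrate-classifier lexicon
#'
#' @param path YAML lexicon; defaults to the rule set shipped with the
#'   package.
#' @return Object of class `infiltrate_rules`.
#' @export
load_infiltrate_rules <- function(path = system.file("extdata",
                                                     "infiltrate_rules.yaml",
                                                     package = "lpvalert")) {
  raw <- yaml::read_yaml(path)
  rules <- list(
    infiltrate_terms = vapply(raw$target$infiltrate_terms, tolower, ""),
    laterality_terms = vapply(raw$target$laterality_terms, tolower, ""),
    pair_window = as.integer(raw$target$pair_window),
    negation_cues = lapply(raw$negation$cues, function(x)
      list(cue = tolower(x$cue), scope = as.integer(x$scope))),
    terminators = vapply(raw$negation$terminators, tolower, ""),
    uncertainty_cues = vapply(raw$uncertainty$cues, tolower, ""),
    uncertainty_polarity = raw$uncertainty$polarity
  )
  if (rules$pair_window < 1L) stop("pair_window must be >= 1", call. = FALSE)
  if (any(vapply(rules$negation_cues, function(x) x$scope, 1L) < 1L))
    stop("negation scope lengths must be >= 1", call. = FALSE)
  structure(rules, class = "infiltrate_rules")
}

#' Tokenize report text
#'
#' Deterministic whitespace/punctuation tokenization. Sentences break at
#' `.`, `;`, `:`, `!` and `?`.
#'
#' @param text Single character string.
#' @return Data frame with `token` (lower case), `start`, `end` (character
#'   offsets) and `sentence` id.
#' @export
tokenize_report <- function(text) {
  if (is.na(text) || !nzchar(text))
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), sentence = integer(0)))
  m <- gregexpr("[A-Za-z][A-Za-z']*|[0-9]+(\\.[0-9]+)?", text)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), sentence = integer(0)))
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  tokens <- tolower(substring(text, starts, ends))
  # sentence id = number of boundary characters strictly before token start
  chars <- strsplit(text, "")[[1]]
  boundary <- c(0L, cumsum(chars %in% c(".", ";", ":", "!", "?")))
  sentence <- boundary[starts] + 1L
  data.frame(token = tokens, start = starts, end = ends,
             sentence = as.integer(sentence), stringsAsFactors = FALSE)
}

# match a (possibly multi-word) lower-case phrase against the token
# sequence; returns integer matrix with columns first, last (token indices)
match_token_phrase <- function(tokens, phrase) {
  words <- strsplit(phrase, " +")[[1]]
  k <- length(words)
  n <- nrow(tokens)
  if (n < k) return(matrix(integer(0), ncol = 2))
  hits <- which(tokens$token == words[1])
  out <- matrix(integer(0), ncol = 2)
  for (i in hits) {
    if (i + k - 1L > n) next
    if (all(tokens$token[i:(i + k - 1L)] == words) &&
        length(unique(tokens$sentence[i:(i + k - 1L)])) == 1L)
      out <- rbind(out, c(i, i + k - 1L))
  }
  out
}

#' Compute negation scopes over a token sequence
#'
#' Each cue negates up to its scope length of *following* tokens; the scope
#' ends early at a terminator token (e.g. "but", "however") or a sentence
#' boundary.
#'
#' @param tokens Token data frame from [tokenize_report()].
#' @param cues List of `list(cue =, scope =)` entries (multi-word cues
#'   allowed).
#' @param terminators Character vector of scope-terminating tokens.
#' @return Integer matrix with columns `first`, `last`: negated token-index
#'   intervals (possibly zero rows).
#' @export
apply_negation_scopes <- function(tokens, cues,
                                  terminators = character(0)) {
  out <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("first", "last")))
  n <- nrow(tokens)
  if (n == 0L) return(out)
  for (cue in cues) {
    hits <- match_token_phrase(tokens, cue$cue)
    if (!nrow(hits)) next
    for (r in seq_len(nrow(hits))) {
      from <- hits[r, 2] + 1L
      if (from > n) next
      sent <- tokens$sentence[hits[r, 1]]
      last <- hits[r, 2]
      for (j in from:min(n, hits[r, 2] + cue$scope)) {
        if (tokens$sentence[j] != sent) break
        if (tokens$token[j] %in% terminators) break
        last <- j
      }
      if (last >= from) out <- rbind(out, c(from, last))
    }
  }
  colnames(out) <- c("first", "last")
  out
}

in_intervals <- function(idx, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(idx)))
  vapply(idx, function(i)
    any(intervals[, 1] <= i & i <= intervals[, 2]), logical(1))
}

#' Classify a radiograph report for bilateral infiltrates
#'
#' Deterministic lexical classification: positive iff some sentence contains
#' an infiltrate term and a laterality term within `pair_window` tokens of
#' each other, with neither term inside a negation scope. Empty text is
#' negative. Uncertainty cues are recorded but do not flip polarity.
#'
#' @param report_text Character scalar (the report free text).
#' @param rules An `infiltrate_rules` object; defaults to the shipped
#'   lexicon.
#' @return Object of class `detection_result`: list with `positive`,
#'   `matched_spans` (data frame: pattern, first/last token index, start/end
#'   character offsets), `negated_spans` (token-index intervals) and
#'   `uncertain` (logical, a hedge cue was present).
#' @examples
#' detect_bilateral_infiltrates(
#'   "Diffuse bilateral infiltrates consistent with edema.")$positive
#' detect_bilateral_infiltrates(
#'   "No focal infiltrate; lungs clear bilaterally.")$positive
#' @export
detect_bilateral_infiltrates <- function(report_text,
                                         rules = load_infiltrate_rules()) {
  tokens <- tokenize_report(report_text)
  neg <- apply_negation_scopes(tokens, rules$negation_cues,
                               rules$terminators)
  matched <- data.frame(pattern = character(0), first = integer(0),
                        last = integer(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  positive <- FALSE
  if (nrow(tokens)) {
    find_all <- function(terms) {
      hits <- lapply(terms, function(tm) {
        h <- match_token_phrase(tokens, tm)
        if (nrow(h)) cbind(h, rep(match(tm, terms), nrow(h))) else NULL
      })
      do.call(rbind, c(list(matrix(integer(0), ncol = 3)), hits))
    }
    inf_hits <- find_all(rules$infiltrate_terms)
    lat_hits <- find_all(rules$laterality_terms)
    if (nrow(inf_hits) && nrow(lat_hits)) {
      inf_ok <- !in_intervals(inf_hits[, 1], neg)
      lat_ok <- !in_intervals(lat_hits[, 1], neg)
      for (i in which(inf_ok)) {
        for (j in which(lat_ok)) {
          same_sent <- tokens$sentence[inf_hits[i, 1]] ==
            tokens$sentence[lat_hits[j, 1]]
          dist <- min(abs(inf_hits[i, 1] - lat_hits[j, 2]),
                      abs(lat_hits[j, 1] - inf_hits[i, 2]))
          if (same_sent && dist <= rules$pair_window) {
            positive <- TRUE
            matched <- rbind(matched, data.frame(
              pattern = paste0(
                rules$laterality_terms[lat_hits[j, 3]], "+",
                rules$infiltrate_terms[inf_hits[i, 3]]),
              first = min(inf_hits[i, 1], lat_hits[j, 1]),
              last = max(inf_hits[i, 2], lat_hits[j, 2]),
              start = tokens$start[min(inf_hits[i, 1], lat_hits[j, 1])],
              end = tokens$end[max(inf_hits[i, 2], lat_hits[j, 2])],
              stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  uncertain <- any(vapply(rules$uncertainty_cues, function(cu)
    nrow(match_token_phrase(tokens, cu)) > 0, logical(1)))
  structure(list(positive = positive, matched_spans = matched,
                 negated_spans = neg, uncertain = uncertain),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s%s; %d matched span(s), %d negated scope(s)\n",
              if (x$positive) "POSITIVE" else "negative",
              if (x$uncertain) " (hedged)" else "",
              nrow(x$matched_spans), nrow(x$negated_spans)))
  invisible(x)
}

#' Read a labelled report corpus
#'
#' The shipped corpus is a synthetic, hand-labelled set of templated
#' radiograph reports (positive / clear / negated / uncertain variants) used
#' as the classifier's agreement oracle.
#'
#' @param path TSV with columns `id`, `label` (`positive`/`negative`) and
#'   `text`.
#' @return Data frame.
#' @export
read_report_corpus <- function(path = system.file("extdata",
                                                  "infiltrate_corpus.tsv",
                                                  package = "lpvalert")) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}
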