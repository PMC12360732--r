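# Collapses the incremental keystroke snapshot stream into final typed lines.
#
# A keylogger that snapshots the whole text field on every keystroke stores a
# line like "Hello" as the rows "H", "He", "Hel", "Hell", "Hello" — and, with
# autocorrect or mid-line edits, as e.g. "H", "He", "Hel", "Helo", "Hello",
# so an earlier row is not always a substring of the next. Deduplication
# repeats a two-rule sweep until a fixpoint; within a sweep each row is
# tested against its immediate successor:
#   1. remove row i if its text is a (contiguous, case-sensitive) substring
#      of row i+1's text;
#   2. remove row i if the Levenshtein similarity between row i and row i+1
#      is strictly greater than the threshold (default 0.6).
# Rows are only ever compared within a "run": maximal stretches of
# consecutive events from the same participant in the same app, so unrelated
# text fields are never merged.

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, and
#' substitutions needed to turn `a` into `b`. Vectorized elementwise with
#' recycling.
#'
#' @param a,b character vectors.
#' @return integer vector of edit distances.
#' @export
levenshtein_distance <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer())
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  same <- a == b
  out[same] <- 0L
  idx <- which(!same)
  if (length(idx)) {
    out[idx] <- vapply(idx, function(i) as.integer(utils::adist(a[i], b[i])), integer(1))
  }
  out
}

#' Normalized Levenshtein similarity
#'
#' `1 - dist(a, b) / max(nchar(a), nchar(b))`, in `[0, 1]`. Two empty strings
#' are defined to have similarity 1 (they are identical).
#'
#' @param a,b character vectors (recycled elementwise).
#' @return numeric vector of similarities.
#' @export
levenshtein_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(numeric())
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  maxlen <- pmax(nchar(a, type = "chars"), nchar(b, type = "chars"))
  d <- levenshtein_distance(a, b)
  ifelse(maxlen == 0L, 1, 1 - d / maxlen)
}

# internal: one two-rule sweep over a text vector. `adj` has length n-1;
# adj[i] says whether rows i and i+1 belong to the same
# participant-and-package run. Both rules are tested against the same
# immediate successor (the next row at the start of the sweep); removals are
# simultaneous and the caller iterates sweeps to a fixpoint. Testing the
# rules against one pairing is what lets a corrected-typo row be absorbed by
# the very next snapshot rather than being stranded next to a much longer
# final line. Returns a logical keep mask.
dedup_sweep <- function(texts, adj, threshold) {
  n <- length(texts)
  if (n <= 1L) return(rep(TRUE, n))
  remove <- rep(FALSE, n)
  i <- which(adj)
  if (length(i)) {
    cur <- texts[i]
    nxt <- texts[i + 1L]
    # rule 1: row i is a contiguous substring of row i+1
    rm_i <- stringi::stri_detect_fixed(nxt, cur)
    # rule 2: similarity with row i+1 strictly above the threshold
    # (identical rows have similarity 1)
    todo <- which(!rm_i)
    if (length(todo)) {
      sim <- levenshtein_similarity(cur[todo], nxt[todo])
      rm_i[todo] <- sim > threshold
    }
    remove[i[rm_i]] <- TRUE
  }
  !remove
}

#' One deduplication pass over an ordered snapshot run
#'
#' Tests every row against its immediate successor with the substring rule
#' and the similarity rule once, returning the surviving texts in order.
#' [dedup_stream()] iterates this to a fixpoint.
#'
#' @param texts character vector of snapshot texts, in timestamp order.
#' @param threshold similarity above which (strictly) a row is removed.
#' @return character vector of surviving texts.
#' @export
dedup_pass <- function(texts, threshold = 0.6) {
  texts <- as.character(texts)
  n <- length(texts)
  texts[dedup_sweep(texts, rep(TRUE, max(0L, n - 1L)), threshold)]
}

#' Deduplicate a keystroke snapshot stream into message lines
#'
#' Segments each participant's timestamp-sorted events into runs of
#' consecutive same-package events, iterates the two-rule pass within each
#' run until no more rows can be removed, and emits each surviving text as a
#' message line dated by its source event's UTC day. Empty snapshot texts are
#' dropped before deduplication. Every output text equals some input text
#' verbatim.
#'
#' @param events keystroke event `data.table` (`participant_id`, `timestamp`,
#'   `package`, optional `url`, `text`), sorted or sortable by timestamp
#'   within participant.
#' @param threshold similarity threshold, strict `>` (default 0.6).
#' @param domain_map optional curated domain-to-package map used to
#'   canonicalize app keys before run segmentation (see
#'   [canonical_app_key()]); `NULL` leaves package names as recorded.
#' @return a `data.table` of message lines: `participant_id`, `day` (`Date`),
#'   `package`, `text`, with attribute `passes` (sweeps needed to reach the
#'   fixpoint).
#' @export
dedup_stream <- function(events, threshold = 0.6, domain_map = NULL) {
  events <- data.table::as.data.table(events)
  participant_id <- NULL; timestamp <- NULL; text <- NULL
  if (nrow(events) == 0L) {
    out <- data.table::data.table(participant_id = character(),
                                  day = as.Date(character()),
                                  package = character(), text = character())
    data.table::setattr(out, "passes", 0L)
    return(out)
  }
  data.table::setorder(events, participant_id, timestamp)
  key <- if (is.null(domain_map)) {
    events$package
  } else {
    canonical_app_key(events$package, if ("url" %in% names(events)) events$url else NULL,
                      domain_map)
  }
  keep0 <- nzchar(events$text)
  events <- events[keep0]
  key <- key[keep0]
  n <- nrow(events)
  if (n == 0L) {
    out <- data.table::data.table(participant_id = character(),
                                  day = as.Date(character()),
                                  package = character(), text = character())
    data.table::setattr(out, "passes", 0L)
    return(out)
  }

  texts <- events$text
  # eligible[i]: row i and i+1 belong to the same participant-package run
  eligible <- if (n > 1L) {
    events$participant_id[-n] == events$participant_id[-1] & key[-n] == key[-1]
  } else logical(0)

  idx <- seq_len(n)
  passes <- 0L
  repeat {
    keep <- dedup_sweep(texts[idx], eligible_for(idx, eligible), threshold)
    passes <- passes + 1L
    if (all(keep)) break
    idx <- idx[keep]
  }

  out <- data.table::data.table(
    participant_id = events$participant_id[idx],
    day = epoch_ms_to_day(events$timestamp[idx]),
    package = key[idx],
    text = texts[idx]
  )
  data.table::setattr(out, "passes", passes)
  out
}

# internal: adjacency eligibility for a surviving index subset. Rows i < j
# that have become adjacent are comparable iff every original boundary
# between them was within-run (runs are contiguous, so it suffices that the
# original run id matches).
eligible_for <- function(idx, eligible) {
  if (length(idx) <= 1L) return(logical(0))
  run_id <- cumsum(c(1L, as.integer(!eligible)))
  run_id[idx[-length(idx)]] == run_id[idx[-1]]
}
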