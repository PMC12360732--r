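# Shared domain types, on-disk event-log schemas, readers/writers, and
# cohort-level inclusion filtering.
#
# Three event-log kinds are supported, JSONL (one JSON object per line)
# primary and CSV accepted, with these field schemas:
#   keystroke: participant_id, timestamp (epoch ms), package, url (optional),
#              text (full current contents of the active text field)
#   location:  participant_id, timestamp (epoch ms), lat, lon (degrees)
#   survey:    participant_id, question_id, response

.log_schemas <- list(
  keystroke = list(required = c("participant_id", "timestamp", "package", "text"),
                   optional = "url"),
  location  = list(required = c("participant_id", "timestamp", "lat", "lon"),
                   optional = character()),
  survey    = list(required = c("participant_id", "question_id", "response"),
                   optional = character())
)

#' Cohort-level analysis configuration
#'
#' Bundles the pipeline constants in one validated object. Every constant of
#' the underlying study design is surfaced here with its default: the 0.6
#' deduplication similarity threshold, the 30-day inclusion filter, the
#' 5-participant vocabulary floor, the 100 m mean-shift radius, the 5-minute
#' movement-episode gap, the 50-mile travel cutoff, and the 0.05 significance
#' level.
#'
#' @param min_days minimum number of distinct UTC days with keystroke data a
#'   participant must have to enter the analysis.
#' @param similarity_threshold Levenshtein similarity above which a snapshot
#'   row is dropped as a near-duplicate of the next row (strict `>`).
#' @param mean_shift_radius_m flat-kernel window radius for place clustering,
#'   meters.
#' @param gap_max_min maximum silence between consecutive GPS fixes, in
#'   minutes, for them to belong to the same movement episode.
#' @param min_users_vocab a lemma must be used by at least this many distinct
#'   participants to enter the word-frequency vocabulary.
#' @param over_distance_miles cutoff for the "fraction of stay points far from
#'   home" mobility feature.
#' @param alpha two-sided significance level for group contrasts.
#' @return an object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(min_days = 30L,
                          similarity_threshold = 0.6,
                          mean_shift_radius_m = 100,
                          gap_max_min = 5,
                          min_users_vocab = 5L,
                          over_distance_miles = 50,
                          alpha = 0.05) {
  stopifnot_scalar_number(min_days, "min_days", min = 1)
  stopifnot_scalar_number(similarity_threshold, "similarity_threshold")
  if (similarity_threshold <= 0 || similarity_threshold >= 1) {
    stop("`similarity_threshold` must lie strictly between 0 and 1")
  }
  stopifnot_scalar_number(mean_shift_radius_m, "mean_shift_radius_m", min = 1e-6)
  stopifnot_scalar_number(gap_max_min, "gap_max_min", min = 0)
  stopifnot_scalar_number(min_users_vocab, "min_users_vocab", min = 0)
  structure(list(
    min_days = as.integer(min_days),
    similarity_threshold = similarity_threshold,
    mean_shift_radius_m = mean_shift_radius_m,
    gap_max_min = gap_max_min,
    min_users_vocab = as.integer(min_users_vocab),
    over_distance_miles = over_distance_miles,
    alpha = alpha
  ), class = "cohort_config")
}

log_format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl"
  else if (ext %in% c("csv", "tsv")) "csv"
  else stop("cannot infer log format from extension: ", path)
}

#' Read a typed event log
#'
#' Parses a keystroke, location, or survey event log from JSONL (primary) or
#' CSV. Records are typed, validated, and returned sorted by
#' `(participant_id, timestamp)` (survey records by participant and question).
#' Malformed lines are skipped and counted; location records with coordinates
#' out of bounds are rejected and counted.
#'
#' @param path path to the log file; format inferred from the extension
#'   (`.jsonl`/`.ndjson` vs `.csv`).
#' @param kind one of `"keystroke"`, `"location"`, `"survey"`.
#' @return a `data.table` of typed records with attributes `malformed` (lines
#'   that could not be parsed or were missing required fields) and `rejected`
#'   (records violating value constraints).
#' @export
read_event_log <- function(path, kind = c("keystroke", "location", "survey")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("event log not found: ", path)
  schema <- .log_schemas[[kind]]
  fmt <- log_format_from_path(path)
  malformed <- 0L

  if (fmt == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      dt <- empty_log(kind)
    } else {
      parsed <- lapply(lines, function(l) {
        tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
      })
      ok <- !vapply(parsed, is.null, logical(1))
      ok[ok] <- vapply(parsed[ok], function(p) {
        all(schema$required %in% names(p))
      }, logical(1))
      malformed <- sum(!ok)
      if (!any(ok)) {
        dt <- empty_log(kind)
      } else {
        dt <- data.table::rbindlist(
          lapply(parsed[ok], function(p) p[c(schema$required, intersect(schema$optional, names(p)))]),
          fill = TRUE
        )
      }
    }
  } else {
    dt <- data.table::fread(path, colClasses = list(character = "participant_id"),
                            showProgress = FALSE)
    missing_cols <- setdiff(schema$required, names(dt))
    if (length(missing_cols)) {
      stop("CSV log ", path, " is missing required columns: ",
           paste(missing_cols, collapse = ", "))
    }
    bad <- rep(FALSE, nrow(dt))
    for (col in schema$required) bad <- bad | is.na(dt[[col]])
    malformed <- sum(bad)
    dt <- dt[!bad]
  }

  dt <- coerce_log(dt, kind)
  rejected <- 0L
  if (kind == "location" && nrow(dt)) {
    bad <- !is.finite(dt$lat) | !is.finite(dt$lon) |
      dt$lat < -90 | dt$lat > 90 | dt$lon < -180 | dt$lon > 180 |
      dt$timestamp < 0
    rejected <- sum(bad)
    dt <- dt[!bad]
  }
  if (kind == "keystroke" && nrow(dt)) {
    bad <- dt$timestamp < 0 | !nzchar(dt$package)
    rejected <- sum(bad)
    dt <- dt[!bad]
  }

  if (kind == "survey") {
    data.table::setorder(dt, participant_id, question_id)
  } else {
    data.table::setorder(dt, participant_id, timestamp)
  }
  if (malformed > 0L) pr_log("read_event_log(%s): skipped %d malformed line(s)", kind, malformed)
  data.table::setattr(dt, "malformed", as.integer(malformed))
  data.table::setattr(dt, "rejected", as.integer(rejected))
  dt[]
}

empty_log <- function(kind) {
  switch(kind,
    keystroke = data.table::data.table(participant_id = character(), timestamp = numeric(),
                                       package = character(), url = character(),
                                       text = character()),
    location = data.table::data.table(participant_id = character(), timestamp = numeric(),
                                      lat = numeric(), lon = numeric()),
    survey = data.table::data.table(participant_id = character(), question_id = character(),
                                    response = character())
  )
}

coerce_log <- function(dt, kind) {
  tmpl <- empty_log(kind)
  for (col in names(tmpl)) {
    if (!col %in% names(dt)) dt[[col]] <- rep(tmpl[[col]][NA_integer_], nrow(dt))
  }
  dt <- data.table::as.data.table(dt)[, names(tmpl), with = FALSE]
  for (col in names(tmpl)) {
    mode_wanted <- class(tmpl[[col]])[1]
    if (mode_wanted == "character") dt[[col]] <- as.character(dt[[col]])
    if (mode_wanted == "numeric") dt[[col]] <- as.numeric(dt[[col]])
  }
  if (kind == "keystroke") {
    text <- NULL; url <- NULL
    dt[is.na(text), text := ""]
    dt[!is.na(url) & !nzchar(url), url := NA_character_]  # "" and absent are one state
  }
  dt
}

#' Write a typed event log
#'
#' Inverse of [read_event_log()]; the round trip is lossless. Format is
#' chosen from the file extension (JSONL primary, CSV accepted).
#'
#' @param x a `data.table`/`data.frame` of records in the documented schema.
#' @param path output path.
#' @param kind one of `"keystroke"`, `"location"`, `"survey"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(x, path, kind = c("keystroke", "location", "survey")) {
  kind <- match.arg(kind)
  x <- coerce_log(data.table::as.data.table(x), kind)
  fmt <- log_format_from_path(path)
  if (fmt == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(x)) {
      json <- vapply(seq_len(nrow(x)), function(i) {
        rec <- as.list(x[i])
        rec <- rec[!vapply(rec, function(v) length(v) == 1L && is.na(v), logical(1))]
        jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
      }, character(1))
      writeLines(json, con)
    }
  } else {
    data.table::fwrite(x, path)
  }
  invisible(path)
}

#' Apply the minimum-days inclusion filter
#'
#' Keeps exactly the participants whose keystroke stream covers at least
#' `min_days` distinct UTC calendar days (a day counts if it has at least one
#' keystroke event). Keystroke days are used because every feature family
#' depends on the typing stream.
#'
#' @param events a keystroke event `data.table` (multiple participants).
#' @param min_days inclusion threshold (inclusive; default 30).
#' @return sorted character vector of retained participant ids.
#' @export
filter_min_days <- function(events, min_days = 30L) {
  stopifnot_scalar_number(min_days, "min_days", min = 1)
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) return(character())
  day <- NULL; participant_id <- NULL; n_days <- NULL
  counts <- events[, list(n_days = data.table::uniqueN(epoch_ms_to_day(timestamp))),
                   by = participant_id]
  sort(counts[n_days >= min_days, participant_id])
}

#' Write a per-participant feature matrix to CSV
#'
#' One row per participant, one column per feature; feature-group membership
#' is encoded in the column-name prefix (`socapp.`, `app.`, `loc.`, `risky.`,
#' `word.`, `dict.`, `emb.`). Missing features are written as empty cells and
#' come back as `NA` from [read_feature_matrix()]; the round trip is lossless
#' to full double precision.
#'
#' @param rows a `data.frame` with a `participant_id` column plus numeric
#'   feature columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(rows, path) {
  rows <- data.table::as.data.table(rows)
  if (!"participant_id" %in% names(rows)) stop("feature rows need a `participant_id` column")
  if (anyDuplicated(rows$participant_id)) stop("duplicate participant_id in feature rows")
  data.table::fwrite(rows, path, na = "")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"),
                          na.strings = "", showProgress = FALSE)
  data.table::setorder(dt, participant_id)
  dt[]
}
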