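# Independent oracles and tiny fixture builders shared across tests.

# Naive edit-distance recursion (first-character decomposition with
# insert/delete/substitute), memoized so the exhaustive definition stays
# tractable. Kept independent of the package's implementation.
make_lev_oracle <- function() {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (nchar(a) == 0L) {
      nchar(b)
    } else if (nchar(b) == 0L) {
      nchar(a)
    } else {
      ta <- substring(a, 2L)
      tb <- substring(b, 2L)
      if (substring(a, 1L, 1L) == substring(b, 1L, 1L)) {
        rec(ta, tb)
      } else {
        1L + min(rec(ta, b), rec(a, tb), rec(ta, tb))
      }
    }
    memo[[key]] <- res
    res
  }
  rec
}

# all strings of length 0..max_len over an alphabet
enumerate_strings <- function(alphabet, max_len) {
  out <- ""
  cur <- ""
  for (l in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

# keystroke events from one or more (package, texts) runs, timestamps
# spaced 1 s apart
make_keystrokes <- function(..., participant = "p1", t0 = 0) {
  runs <- list(...)
  rows <- list()
  t <- t0
  for (r in runs) {
    n <- length(r$texts)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      participant_id = participant,
      timestamp = t + seq_len(n) * 1000,
      package = r$package,
      url = r$url %||% NA_character_,
      text = r$texts
    )
    t <- t + n * 1000
  }
  data.table::rbindlist(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# message-line table from parallel vectors
make_lines <- function(day, package, text, participant = "p1") {
  data.table::data.table(
    participant_id = participant,
    day = as.Date("2023-01-01") + day,
    package = package,
    text = text
  )
}

# brute-force day-level frequency: days containing the unit / all days
brute_day_freq <- function(day, present) {
  length(unique(day[present])) / length(unique(day))
}
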