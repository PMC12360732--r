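# The four text feature families — per-lemma word-use frequencies,
# risky-phrase frequencies, dictionary (LIWC-style) category scores, and
# day-averaged text embeddings — computed from deduplicated lines typed in
# communication (messaging / social media / dating) apps only.
#
# All word-use frequencies are day-level: the frequency of a unit is the
# number of distinct UTC days on which it occurs divided by the number of
# distinct days with any text data, so a word typed ten times in one day
# counts once.

#' Built-in lemmatizer
#'
#' A deterministic, dependency-light lemmatizer: an exception table of
#' irregular forms (e.g. "better" -> "good", "went" -> "go") followed by
#' regular suffix stripping (plural "-s"/"-ies", "-ing", "-ed", possessive
#' "'s", with consonant undoubling). It approximates a full WordNet-style
#' lemmatizer well enough for frequency features; any
#' `function(tokens) -> lemmas` can be injected in its place.
#'
#' @param exceptions_path CSV `form,lemma` of irregular forms.
#' @return a function mapping a character vector of lowercased tokens to
#'   their lemmas.
#' @export
default_lemmatizer <- function(exceptions_path = pr_extdata("lemma_exceptions.csv")) {
  exc <- data.table::fread(exceptions_path, showProgress = FALSE)
  lookup <- stats::setNames(exc$lemma, exc$form)
  undouble <- function(w) {
    last <- substring(w, nchar(w), nchar(w))
    prev <- substring(w, nchar(w) - 1L, nchar(w) - 1L)
    dbl <- nchar(w) >= 3L & last == prev & !last %in% c("l", "s", "z", "e")
    w[dbl] <- substring(w[dbl], 1L, nchar(w[dbl]) - 1L)
    w
  }
  function(tokens) {
    out <- unname(lookup[tokens])
    todo <- is.na(out)
    w <- tokens[todo]
    w <- sub("'s$", "", w)
    n <- nchar(w)
    r <- n >= 5L & endsWith(w, "ies")
    w[r] <- paste0(substring(w[r], 1L, nchar(w[r]) - 3L), "y")
    n <- nchar(w)
    r <- n >= 5L & endsWith(w, "ing")
    w[r] <- undouble(substring(w[r], 1L, nchar(w[r]) - 3L))
    n <- nchar(w)
    r <- n >= 4L & endsWith(w, "ed") & !endsWith(w, "eed")
    w[r] <- undouble(substring(w[r], 1L, nchar(w[r]) - 2L))
    n <- nchar(w)
    r <- n >= 4L & endsWith(w, "s") & !endsWith(w, "ss") & !endsWith(w, "us") &
      !endsWith(w, "is")
    w[r] <- substring(w[r], 1L, nchar(w[r]) - 1L)
    out[todo] <- w
    out
  }
}

#' Normalize a text line into lemmatized tokens
#'
#' Lowercases, strips punctuation (apostrophes are kept inside tokens),
#' splits on whitespace, and maps each token through the lemmatizer.
#' Duplicate tokens are kept.
#'
#' @param text a character vector of lines.
#' @param lemmatizer `function(tokens) -> lemmas`; `NULL` skips
#'   lemmatization.
#' @return a list (one element per line) of token character vectors.
#' @export
normalize_tokens <- function(text, lemmatizer = default_lemmatizer()) {
  toks <- tokenize_lines(text)
  if (is.null(lemmatizer)) return(toks)
  flat <- unlist(toks, use.names = FALSE)
  if (length(flat) == 0L) return(toks)
  lem <- lemmatizer(flat)
  utils::relist(lem, toks)
}

# internal: lowercase + punctuation-stripped whitespace tokens (apostrophes
# survive inside tokens)
tokenize_lines <- function(text) {
  text <- stringi::stri_trans_tolower(as.character(text))
  text <- stringi::stri_replace_all_regex(text, "[^\\p{L}\\p{N}']+", " ")
  text <- stringi::stri_replace_all_regex(text, "(^| )'+|'+( |$)", " ")
  stringi::stri_split_regex(trimws(text), "\\s+", omit_empty = TRUE)
}

#' English stopword list
#' @param path plain-text file, one stopword per line.
#' @return character vector.
#' @export
default_stopwords <- function(path = pr_extdata("stopwords_en.txt")) {
  readLines(path, warn = FALSE)
}

#' Placeholder texts dropped before featurization
#'
#' Keylogged snapshots sometimes capture UI placeholder strings ("Enter
#' message", "Say something") rather than user text; whole lines equal to a
#' placeholder are discarded.
#'
#' @param path plain-text file, one placeholder per line.
#' @return character vector.
#' @export
default_placeholders <- function(path = pr_extdata("placeholders.txt")) {
  readLines(path, warn = FALSE)
}

#' Build the word-frequency vocabulary
#'
#' The vocabulary is the set of lemmas that survive three filters: stopword
#' removal, placeholder-line removal, and a minimum number of distinct
#' participants ever using the lemma.
#'
#' @param lines message-line `data.table` for the whole cohort
#'   (`participant_id`, `day`, `text`), already restricted to communication
#'   apps.
#' @param min_users minimum distinct participants per lemma (default 5).
#' @param stopwords,placeholders character vectors.
#' @param lemmatizer token lemmatizer.
#' @return sorted character vector of vocabulary lemmas.
#' @export
build_vocab <- function(lines, min_users = 5L,
                        stopwords = default_stopwords(),
                        placeholders = default_placeholders(),
                        lemmatizer = default_lemmatizer()) {
  lines <- drop_placeholder_lines(data.table::as.data.table(lines), placeholders)
  if (nrow(lines) == 0L) return(character())
  toks <- normalize_tokens(lines$text, lemmatizer)
  lens <- lengths(toks)
  dt <- data.table::data.table(
    participant_id = rep(lines$participant_id, lens),
    lemma = unlist(toks, use.names = FALSE)
  )
  lemma <- NULL; participant_id <- NULL; n_users <- NULL
  dt <- dt[!lemma %in% stopwords]
  if (nrow(dt) == 0L) return(character())
  users <- dt[, list(n_users = data.table::uniqueN(participant_id)), by = lemma]
  sort(users[n_users >= min_users, lemma])
}

drop_placeholder_lines <- function(lines, placeholders) {
  if (length(placeholders) == 0L || nrow(lines) == 0L) return(lines)
  lines[!trimws(lines$text) %in% placeholders]
}

# internal: per-day lemmatized token sets for one participant's lines
day_tokens <- function(lines, lemmatizer, placeholders) {
  lines <- drop_placeholder_lines(data.table::as.data.table(lines), placeholders)
  if (nrow(lines) == 0L) return(list())
  toks <- normalize_tokens(lines$text, lemmatizer)
  split(toks, as.character(lines$day))
}

#' Day-level word-use frequency features
#'
#' For each vocabulary lemma, the number of distinct days whose text contains
#' the lemma divided by the number of distinct days with any text data.
#'
#' @param lines one participant's communication-app message lines.
#' @param vocab vocabulary lemmas ([build_vocab()]).
#' @param lemmatizer,placeholders as in [build_vocab()].
#' @return named numeric vector over `vocab` (empty if no text days).
#' @export
word_frequency_features <- function(lines, vocab,
                                    lemmatizer = default_lemmatizer(),
                                    placeholders = default_placeholders()) {
  if (length(vocab) == 0L) return(stats::setNames(numeric(), character()))
  by_day <- day_tokens(lines, lemmatizer, placeholders)
  n_days <- length(by_day)
  if (n_days == 0L) return(stats::setNames(numeric(), character()))
  counts <- integer(length(vocab))
  names(counts) <- vocab
  for (d in by_day) {
    present <- unique(unlist(d, use.names = FALSE))
    hit <- vocab %in% present
    counts[hit] <- counts[hit] + 1L
  }
  counts / n_days
}

#' Load a risky-phrase lexicon
#'
#' CSV with columns `phrase,category` and optionally `subcategory`; phrases
#' may span several tokens. The packaged demonstration lexicon (categories
#' `sex_related`, `drug_related` with finer subcategories) is a small
#' synthetic stand-in for unpublished research lexicons — supply your own
#' for real analyses.
#'
#' @param path lexicon CSV path.
#' @return `data.table` with `phrase`, `category`, `subcategory`.
#' @export
risky_lexicon <- function(path = pr_extdata("risky_phrases_demo.csv")) {
  dt <- data.table::fread(path, showProgress = FALSE)
  stopifnot(all(c("phrase", "category") %in% names(dt)))
  if (!"subcategory" %in% names(dt)) dt$subcategory <- NA_character_
  dt$phrase <- tolower(trimws(dt$phrase))
  dt
}

#' Risky-phrase frequency features
#'
#' A phrase matches a day when its full lemmatized token sequence occurs
#' contiguously within a single line of that day. Per-phrase frequencies and
#' per-(sub)category frequencies (days where at least one member phrase
#' matched) share the text-day denominator of [word_frequency_features()].
#'
#' @param lines one participant's communication-app message lines.
#' @param lexicon phrase lexicon ([risky_lexicon()]).
#' @param lemmatizer,placeholders as in [build_vocab()].
#' @param match_lemmatized match on lemmatized tokens (default) or raw
#'   lowercased tokens.
#' @return named numeric vector: `phrase.<phrase>` entries followed by
#'   `cat.<category>` entries.
#' @export
risky_phrase_features <- function(lines, lexicon = risky_lexicon(),
                                  lemmatizer = default_lemmatizer(),
                                  placeholders = default_placeholders(),
                                  match_lemmatized = TRUE) {
  lexicon <- data.table::as.data.table(lexicon)
  if (nrow(lexicon) == 0L) return(stats::setNames(numeric(), character()))
  lem <- if (match_lemmatized) lemmatizer else NULL
  by_day <- day_tokens(lines, lem, placeholders)
  phrase_tok <- normalize_tokens(lexicon$phrase, lem)
  pad <- function(tok) paste0(" ", paste(tok, collapse = " "), " ")
  phrase_pad <- vapply(phrase_tok, pad, character(1))
  n_days <- length(by_day)
  n_ph <- nrow(lexicon)

  # day_hits[d, p]: phrase p matched (contiguously, within one line) on day d
  day_hits <- matrix(FALSE, nrow = n_days, ncol = n_ph)
  for (i in seq_len(n_days)) {
    line_pad <- vapply(by_day[[i]], pad, character(1))
    day_hits[i, ] <- vapply(phrase_pad,
                            function(p) any(stringi::stri_detect_fixed(line_pad, p)),
                            logical(1))
  }
  denom <- max(n_days, 1L)
  freq <- colSums(day_hits) / denom
  out <- stats::setNames(freq, paste0("phrase.", gsub("\\s+", "_", lexicon$phrase)))

  groups <- split(seq_len(n_ph), lexicon$category)
  sub <- lexicon$subcategory
  if (any(!is.na(sub))) {
    groups <- c(groups, split(seq_len(n_ph)[!is.na(sub)], sub[!is.na(sub)]))
  }
  cat_freq <- vapply(groups, function(ix) {
    sum(apply(day_hits[, ix, drop = FALSE], 1, any)) / denom
  }, numeric(1))
  c(out, stats::setNames(as.numeric(cat_freq), paste0("cat.", names(groups))))
}

#' Load a category dictionary
#'
#' Open LIWC-style dictionary format: a JSON object mapping category names to
#' arrays of lowercase word patterns, where a terminal `*` matches any
#' suffix ("friend*" matches "friends"). The packaged demonstration
#' dictionary covers the categories `social`, `affect`, `drives`, and
#' `cognitive_processes`; licensed LIWC users can export their dictionaries
#' into this format.
#'
#' @param path dictionary JSON path.
#' @return named list of character pattern vectors.
#' @export
category_dictionary <- function(path = pr_extdata("liwc_demo_dictionary.json")) {
  dict <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(dict, tolower)
}

#' Dictionary (LIWC-style) category scores
#'
#' For each day, the category score is the fraction of that day's tokens
#' matching any of the category's patterns; the participant's feature is the
#' unweighted mean of the daily scores over days with at least one token.
#' Matching uses lowercased, punctuation-stripped tokens without
#' lemmatization (dictionaries list surface forms and wildcards).
#'
#' @param lines one participant's communication-app message lines.
#' @param dicts named list of pattern vectors ([category_dictionary()]).
#' @param placeholders placeholder lines to drop.
#' @return named numeric vector, one score per category (`NA` if no tokens).
#' @export
dictionary_scores <- function(lines, dicts = category_dictionary(),
                              placeholders = default_placeholders()) {
  by_day <- day_tokens(lines, NULL, placeholders)
  by_day <- lapply(by_day, function(d) unlist(d, use.names = FALSE))
  by_day <- by_day[lengths(by_day) > 0L]
  if (length(by_day) == 0L) {
    return(stats::setNames(rep(NA_real_, length(dicts)), names(dicts)))
  }
  scores <- vapply(dicts, function(patterns) {
    exact <- patterns[!endsWith(patterns, "*")]
    prefixes <- sub("\\*$", "", patterns[endsWith(patterns, "*")])
    daily <- vapply(by_day, function(tok) {
      hit <- tok %in% exact
      for (p in prefixes) hit <- hit | startsWith(tok, p)
      mean(hit)
    }, numeric(1))
    mean(daily)
  }, numeric(1))
  scores
}

#' Deterministic hashing text embedder (test stub)
#'
#' Embeds a text as a seeded random projection of token-hash counts: tokens
#' are hashed into `buckets` count bins, counts are normalized to relative
#' frequencies, and the bin vector is projected to `dim` dimensions with a
#' fixed Gaussian matrix drawn once from `seed`. Deterministic: the same
#' input and seed always give the identical vector. A transformer-based
#' embedder can be plugged in through the same interface
#' (`function(character vector) -> numeric matrix`).
#'
#' @param dim embedding dimension (default 64).
#' @param buckets number of hash bins (default 256).
#' @param seed integer seed for the projection matrix.
#' @return an embedder `function(texts) -> matrix` (`length(texts)` rows).
#' @export
hash_embedder <- function(dim = 64L, buckets = 256L, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  proj <- matrix(stats::rnorm(buckets * dim, sd = 1 / sqrt(buckets)), buckets, dim)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  hash_token <- function(tok) {
    vapply(tok, function(t) {
      h <- 7
      for (code in utf8ToInt(t)) h <- (h * 31 + code) %% 1048576
      as.integer(h %% buckets) + 1L
    }, integer(1), USE.NAMES = FALSE)
  }
  function(texts) {
    toks <- tokenize_lines(texts)
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(toks)) {
      tok <- toks[[i]]
      if (length(tok) == 0L) next
      counts <- tabulate(hash_token(tok), nbins = buckets) / length(tok)
      out[i, ] <- as.numeric(counts %*% proj)
    }
    out
  }
}

#' Day-averaged participant text embedding
#'
#' Concatenates each day's lines into one text, embeds it, and averages the
#' day vectors elementwise across days (days with no tokens are skipped).
#'
#' @param lines one participant's communication-app message lines.
#' @param embedder embedding function ([hash_embedder()] by default).
#' @param placeholders placeholder lines to drop.
#' @return numeric embedding vector, or `NULL` if the participant has no
#'   text days.
#' @export
embed_days <- function(lines, embedder = hash_embedder(),
                       placeholders = default_placeholders()) {
  lines <- drop_placeholder_lines(data.table::as.data.table(lines), placeholders)
  if (nrow(lines) == 0L) return(NULL)
  day_text <- tapply(lines$text, as.character(lines$day),
                     function(t) paste(t, collapse = " "))
  vecs <- embedder(as.character(day_text))
  keep <- lengths(tokenize_lines(as.character(day_text))) > 0L
  if (!any(keep)) return(NULL)
  colMeans(vecs[keep, , drop = FALSE])
}
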