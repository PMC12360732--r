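# Generates complete synthetic participant datasets — keystroke streams with
# typing artifacts, app/URL usage, GPS traces, and survey answers — with
# planted, configurable class effects, plus ground truth for recovery tests.
#
# Positives on an outcome get elevated dating-app day rates and risky-word
# insertion rates, and (for the many-partners outcome) a larger travel
# radius. Message text comes from a small template grammar mixing a neutral
# vocabulary with lexicon phrases at class-dependent rates: controllable and
# sufficient for day-level frequency features, with no claim of
# natural-language realism.

#' Synthetic cohort configuration
#'
#' Defaults mirror the modeled study population: 80 participants, two months
#' of sensing, outcome prevalences of 0.183 (methamphetamine use), 0.037
#' (injection drug use), 0.50 (6+ partners), 0.744 (condomless receptive
#' sex), and 0 (in treatment), and planted effects of 2.5x dating-app use,
#' 3x risky-word insertion, and 2x travel scale in the respective positive
#' classes.
#'
#' @param n_participants cohort size.
#' @param n_days days of sensing per participant.
#' @param seed integer master seed; every participant derives an independent
#'   substream from `(seed, participant index)`, so cohorts are reproducible.
#' @param prevalence named vector of outcome prevalences.
#' @param missing_rate probability a survey question is answered "Decline to
#'   answer" / "I don't know".
#' @param dating_ratio dating-app day-rate multiplier for positives (meth or
#'   6+ partners).
#' @param risky_word_ratio risky-phrase insertion-rate multiplier for
#'   positives.
#' @param travel_ratio travel-distance multiplier for 6+ partner positives.
#' @param typo_prob per-line probability of an omitted-letter typo later
#'   corrected.
#' @param autocorrect_prob per-line probability of a substituted-letter typo
#'   later corrected.
#' @param n_places planted places per participant (including home).
#' @param base_dating_rate baseline probability a day has dating-app text.
#' @param base_sex_rate,base_drug_rate baseline per-line probabilities of
#'   inserting a sex-/drug-related lexicon phrase.
#' @param start_day calendar date of day 1.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 80L, n_days = 60L, seed = 1L,
                       prevalence = c(meth_use = 0.183, idu = 0.037,
                                      partners_6plus = 0.50,
                                      condomless_receptive = 0.744,
                                      in_treatment = 0),
                       missing_rate = 0.05,
                       dating_ratio = 2.5, risky_word_ratio = 3,
                       travel_ratio = 2,
                       typo_prob = 0.12, autocorrect_prob = 0.08,
                       n_places = 6L,
                       base_dating_rate = 0.15,
                       base_sex_rate = 0.05, base_drug_rate = 0.04,
                       start_day = as.Date("2023-01-01")) {
  stopifnot_scalar_number(n_participants, "n_participants", min = 1)
  stopifnot_scalar_number(n_days, "n_days", min = 1)
  stopifnot(all(prevalence >= 0 & prevalence <= 1))
  for (nm in c("missing_rate", "typo_prob", "autocorrect_prob",
               "base_dating_rate", "base_sex_rate", "base_drug_rate")) {
    stopifnot_scalar_number(get(nm), nm, min = 0, max = 1)
  }
  for (nm in c("dating_ratio", "risky_word_ratio", "travel_ratio")) {
    stopifnot_scalar_number(get(nm), nm, min = 1e-9)
  }
  structure(list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    seed = as.integer(seed), prevalence = prevalence,
    missing_rate = missing_rate, dating_ratio = dating_ratio,
    risky_word_ratio = risky_word_ratio, travel_ratio = travel_ratio,
    typo_prob = typo_prob, autocorrect_prob = autocorrect_prob,
    n_places = as.integer(n_places), base_dating_rate = base_dating_rate,
    base_sex_rate = base_sex_rate, base_drug_rate = base_drug_rate,
    start_day = as.Date(start_day)
  ), class = "sim_config")
}

# neutral message vocabulary: everyday words, including inflected forms and
# words covered by the demonstration dictionary so that dictionary scores
# are non-degenerate
.neutral_vocab <- c(
  "hey", "hi", "yeah", "ok", "cool", "see", "you", "later", "tonight",
  "tomorrow", "weekend", "dinner", "movie", "coffee", "lunch", "home",
  "work", "working", "gym", "tired", "busy", "free", "plans", "maybe",
  "sure", "sounds", "good", "great", "nice", "fun", "happy", "love",
  "miss", "friend", "friends", "talk", "talking", "call", "meet",
  "meeting", "hang", "hanging", "together", "party", "music", "game",
  "watch", "watching", "think", "thinking", "know", "because", "wonder",
  "guess", "remember", "should", "why", "going", "coming", "running",
  "walked", "played", "better", "money", "job", "goal", "plan", "win",
  "time", "day", "night", "week", "soon", "really", "pretty", "kind"
)

# app universe used by the generator: package, category, optional web domain
.sim_apps <- function() {
  data.table::data.table(
    package = c("com.google.android.apps.messaging", "com.whatsapp",
                "org.telegram.messenger", "com.facebook.katana",
                "com.instagram.android", "com.twitter.android",
                "com.grindrapp.android", "com.tinder", "com.a4a.adam4adam",
                "com.spotify.music", "com.google.android.apps.maps",
                "com.amazon.mShop.android.shopping"),
    category = c("messaging", "messaging", "messaging", "social_media",
                 "social_media", "social_media", "dating", "dating",
                 "dating", "other", "other", "other"),
    domain = c(NA, NA, NA, "facebook.com", "instagram.com", "twitter.com",
               "grindr.com", "tinder.com", "adam4adam.com", NA, NA, NA)
  )
}

# one template-grammar sentence; optionally inserts lexicon phrases
sim_sentence <- function(lexicon, sex_rate, drug_rate) {
  words <- sample(.neutral_vocab, sample(3:7, 1), replace = TRUE)
  inserted <- character()
  category <- NULL
  if (stats::runif(1) < sex_rate) {
    ph <- sample(lexicon[category == "sex_related"]$phrase, 1)
    inserted <- c(inserted, ph)
  }
  if (stats::runif(1) < drug_rate) {
    ph <- sample(lexicon[category == "drug_related"]$phrase, 1)
    inserted <- c(inserted, ph)
  }
  for (ph in inserted) {
    pos <- sample(seq_len(length(words) + 1L), 1)
    words <- append(words, ph, after = pos - 1L)
  }
  list(text = paste(words, collapse = " "), risky = inserted)
}

#' Simulate the keystroke snapshot trace of one typed line
#'
#' Emits the prefix sequence of `final_text`; with probability `typo_prob`
#' a letter is omitted and with probability `autocorrect_prob` a letter is
#' substituted partway through, the corrupted prefixes persisting for a few
#' keystrokes before the corrected text resumes — emulating mid-line edits
#' and autocorrect, so that an earlier row is not always a substring of the
#' next. The last row always equals `final_text` exactly, and every trace
#' deduplicates back to exactly `final_text`.
#'
#' @param final_text the intended final line (nonempty).
#' @param typo_prob,autocorrect_prob artifact probabilities (draws use the
#'   current RNG stream).
#' @return character vector of snapshot texts, in typing order.
#' @export
generate_typing_trace <- function(final_text, typo_prob = 0,
                                  autocorrect_prob = 0) {
  stopifnot(is.character(final_text), length(final_text) == 1L,
            nzchar(final_text))
  L <- nchar(final_text)
  prefixes <- substring(final_text, 1L, seq_len(L))
  kind <- "none"
  u <- stats::runif(1)
  if (u < typo_prob) kind <- "omit"
  else if (u < typo_prob + autocorrect_prob) kind <- "substitute"
  if (kind == "none" || L < 6L) return(prefixes)

  chars <- strsplit(final_text, "", fixed = TRUE)[[1]]
  if (kind == "omit") {
    p <- sample(2:(L - 2L), 1)                    # omitted character position
    wrong <- paste(chars[-p], collapse = "")
    c_pt <- sample(p:min(p + 3L, L - 2L), 1)      # correction point (wrong-prefix length)
    c(substring(wrong, 1L, seq_len(c_pt)), substring(final_text, 1L, (c_pt + 1L):L))
  } else {
    # substituted char needs a longer context for the similarity rule to
    # reach across the correction (distance 2)
    c_lo <- 5L
    p <- sample(2:(L - 2L), 1)
    c_pt <- max(p, c_lo)
    if (c_pt > L - 2L) return(prefixes)
    sub_ch <- sample(setdiff(letters, chars[p]), 1)
    wrong_chars <- chars
    wrong_chars[p] <- sub_ch
    wrong <- paste(wrong_chars, collapse = "")
    c(substring(wrong, 1L, seq_len(c_pt)), substring(final_text, 1L, (c_pt + 1L):L))
  }
}

#' Simulate one day of movement-only GPS logging
#'
#' Emits short bursts of in-motion fixes for each leg of the day's travel,
#' each burst ending exactly at the destination (plus a few meters of
#' jitter), with silences longer than the episode gap between legs — so
#' [retain_stationary()] recovers exactly the visited places. Every day ends
#' with a return to home, which therefore stays the most visited place.
#'
#' @param home `c(lat, lon)` of the home place.
#' @param places matrix/data.frame of non-home place coordinates
#'   (`lat`, `lon` columns).
#' @param t0_ms epoch ms of the day's first movement.
#' @param n_extra number of non-home places visited this day (each followed
#'   by a return home).
#' @param place_weights sampling weights over `places`.
#' @param jitter_m per-visit positional jitter, meters.
#' @return list: `fixes` (`data.table`: `timestamp`, `lat`, `lon`),
#'   `visited` (planted place index per stay point, 0 = home).
#' @export
generate_day_track <- function(home, places, t0_ms, n_extra = 0L,
                               place_weights = NULL, jitter_m = 10) {
  places <- as.matrix(places)
  dest_idx <- integer()
  if (n_extra > 0L && nrow(places) > 0L) {
    dest_idx <- sample.int(nrow(places), n_extra, replace = TRUE,
                           prob = place_weights)
  }
  # visit sequence: each outing ends back home; a stay-home day still
  # produces one short burst ending at home
  seq_places <- if (length(dest_idx)) {
    idx <- as.vector(rbind(dest_idx, 0L))
    rbind_coords <- function(i) if (i == 0L) home else places[i, ]
    list(idx = idx, coords = t(vapply(idx, rbind_coords, numeric(2))))
  } else {
    list(idx = 0L, coords = matrix(home, nrow = 1))
  }
  n_legs <- length(seq_places$idx)
  deg_jitter <- jitter_m / 111320
  out <- vector("list", n_legs)
  t <- t0_ms
  origin <- home
  for (k in seq_len(n_legs)) {
    dest <- seq_places$coords[k, ] + stats::runif(2, -deg_jitter, deg_jitter)
    frac <- seq(0.2, 1, length.out = 5L)
    lat <- origin[1] + frac * (dest[1] - origin[1])
    lon <- origin[2] + frac * (dest[2] - origin[2])
    ts <- t + (0:4) * 60000
    out[[k]] <- data.table::data.table(timestamp = ts, lat = lat, lon = lon)
    origin <- dest
    t <- ts[5] + (30 + stats::runif(1, 0, 60)) * 60000  # >= 30 min dwell
  }
  list(fixes = data.table::rbindlist(out), visited = seq_places$idx)
}

# verify that a run of typing traces deduplicates back to exactly the
# intended final lines (given the surviving predecessor of the same run)
run_roundtrips <- function(traces, finals, prev_final, threshold = 0.6) {
  rows <- c(prev_final, unlist(traces, use.names = FALSE))
  fixpoint <- rows
  repeat {
    nxt <- dedup_pass(fixpoint, threshold)
    if (length(nxt) == length(fixpoint)) break
    fixpoint <- nxt
  }
  identical(fixpoint, c(prev_final, finals))
}

#' Generate a complete synthetic cohort
#'
#' Draws outcome labels per configured prevalence, then simulates, for every
#' participant, daily message lines (with keystroke-level typing traces),
#' GPS day tracks anchored at a planted home, and wellness-survey answers
#' with configurable missingness. Positive classes receive the configured
#' dating-app, risky-word, and travel elevations. The same configuration and
#' seed always produce identical output.
#'
#' @param config a [sim_config()].
#' @return list: `keystrokes`, `locations`, `survey` (event-log
#'   `data.table`s in the documented schemas) and `ground_truth` (true
#'   labels, home/place coordinates, intended message lines, per-participant
#'   risky insertions).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  lexicon <- risky_lexicon()
  apps <- .sim_apps()
  category <- NULL
  out_keys <- vector("list", config$n_participants)
  out_locs <- vector("list", config$n_participants)
  out_survey <- vector("list", config$n_participants)
  out_truth <- vector("list", config$n_participants)
  day0_ms <- as.numeric(config$start_day) * 86400000

  for (i in seq_len(config$n_participants)) {
    set.seed(derive_seed(config$seed, i))
    pid <- sprintf("P%03d", i)
    labels <- vapply(names(config$prevalence), function(q) {
      stats::runif(1) < config$prevalence[[q]]
    }, logical(1))

    meth <- labels[["meth_use"]]
    partners <- labels[["partners_6plus"]]
    dating_mult <- if (meth || partners) config$dating_ratio else 1
    sex_rate <- min(0.9, config$base_sex_rate *
                      (if (meth || partners) config$risky_word_ratio else 1))
    drug_rate <- min(0.9, config$base_drug_rate *
                       (if (meth) config$risky_word_ratio else 1))
    travel_scale <- if (partners) config$travel_ratio else 1

    # participant app set (2 apps per category) and day rates per category
    my_apps <- lapply(split(apps, apps$category), function(a) {
      a[sample(nrow(a), min(nrow(a), 2L))]
    })
    day_rate <- c(messaging = 0.75, social_media = 0.5,
                  dating = min(0.9, config$base_dating_rate * dating_mult),
                  other = 0.45)

    # planted places: home + local places + one farther "trip" place
    home <- c(stats::runif(1, 32, 42), stats::runif(1, -120, -80))
    n_other <- max(1L, config$n_places - 1L)
    dist_mi <- c((0.5 + stats::rexp(n_other - 1L, 1 / 4)) * travel_scale,
                 stats::runif(1, 20, 60) * travel_scale)
    bearing <- stats::runif(n_other, 0, 2 * pi)
    places <- cbind(
      lat = home[1] + (dist_mi / 69.093) * cos(bearing),
      lon = home[2] + (dist_mi / (69.093 * cos(home[1] * pi / 180))) * sin(bearing)
    )
    place_weights <- c(rep(1, n_other - 1L), 0.15)

    # vector accumulators (flattened into tables once per participant)
    k_ts <- list(); k_pkg <- list(); k_url <- list(); k_text <- list()
    locs <- list()
    tl_day <- list(); tl_pkg <- list(); tl_text <- list()
    n_risky_sex <- 0L; n_risky_drug <- 0L
    prev_pkg <- ""; prev_final <- character(0)
    sex_phrases <- lexicon$phrase[lexicon$category == "sex_related"]
    drug_phrases <- lexicon$phrase[lexicon$category == "drug_related"]

    for (d in seq_len(config$n_days)) {
      day_ms <- day0_ms + (d - 1L) * 86400000
      # --- location ---
      track <- generate_day_track(home, places, day_ms + 9 * 3600000,
                                  n_extra = stats::rpois(1, 0.8),
                                  place_weights = place_weights)
      locs[[length(locs) + 1L]] <- track$fixes

      # --- messages ---
      used_cats <- names(day_rate)[stats::runif(4) < day_rate]
      t_line <- day_ms + 10 * 3600000
      for (ct in sample(used_cats)) {
        app <- my_apps[[ct]][sample(nrow(my_apps[[ct]]), 1L)]
        n_lines <- 1L + stats::rpois(1, 0.8)
        # websites and apps are one key space: sometimes type on the website
        on_web <- !is.na(app$domain) && stats::runif(1) < 0.2
        pkg_recorded <- if (on_web) "com.android.chrome" else app$package
        url <- if (on_web) paste0("https://www.", app$domain, "/messages") else NA_character_
        for (tries in 1:25) {
          sents <- replicate(n_lines, {
            if (ct == "other") {
              list(text = paste(sample(.neutral_vocab, sample(3:6, 1),
                                       replace = TRUE), collapse = " "),
                   risky = character())
            } else sim_sentence(lexicon, sex_rate, drug_rate)
          }, simplify = FALSE)
          finals <- vapply(sents, `[[`, character(1), "text")
          traces <- lapply(finals, generate_typing_trace,
                           typo_prob = config$typo_prob,
                           autocorrect_prob = config$autocorrect_prob)
          pf <- if (identical(prev_pkg, app$package)) prev_final else character(0)
          if (run_roundtrips(traces, finals, pf)) break
        }
        nrows <- lengths(traces)
        starts <- t_line + cumsum(c(0, (nrows[-n_lines] * 150 + 120000)))
        ts <- rep(starts, nrows) + (sequence(nrows) - 1L) * 150
        t_line <- starts[n_lines] + nrows[n_lines] * 150 + 120000
        j <- length(k_ts) + 1L
        k_ts[[j]] <- ts
        k_pkg[[j]] <- rep(pkg_recorded, sum(nrows))
        k_url[[j]] <- rep(url, sum(nrows))
        k_text[[j]] <- unlist(traces, use.names = FALSE)
        if (ct != "other") {
          risky <- unlist(lapply(sents, `[[`, "risky"), use.names = FALSE)
          n_risky_sex <- n_risky_sex + sum(risky %in% sex_phrases)
          n_risky_drug <- n_risky_drug + sum(risky %in% drug_phrases)
        }
        tl_day[[j]] <- rep(d - 1L, n_lines)
        tl_pkg[[j]] <- rep(app$package, n_lines)
        tl_text[[j]] <- finals
        prev_pkg <- app$package
        prev_final <- finals[n_lines]
      }
    }

    # --- survey ---
    answer <- function(true_answer) {
      if (stats::runif(1) < config$missing_rate) {
        sample(c("decline_to_answer", "dont_know"), 1)
      } else true_answer
    }
    subst <- if (labels[["meth_use"]] && labels[["idu"]]) "methamphetamine_and_injection_drugs"
      else if (labels[["meth_use"]]) "methamphetamine"
      else if (labels[["idu"]]) "injection_drugs" else "none"
    partners_answer <- if (labels[["partners_6plus"]]) sample(c("6_10", "11_plus"), 1)
      else sample(c("0_1", "2_5"), 1)
    out_survey[[i]] <- data.table::data.table(
      participant_id = pid,
      question_id = c("substances_used", "partner_count",
                      "condomless_receptive_sex", "substance_use_treatment"),
      response = c(answer(subst), answer(partners_answer),
                   answer(if (labels[["condomless_receptive"]]) "yes" else "no"),
                   answer(if (labels[["in_treatment"]]) "yes" else "no"))
    )

    out_keys[[i]] <- data.table::data.table(
      participant_id = pid,
      timestamp = unlist(k_ts, use.names = FALSE),
      package = unlist(k_pkg, use.names = FALSE),
      url = unlist(k_url, use.names = FALSE),
      text = unlist(k_text, use.names = FALSE)
    )
    loc_dt <- data.table::rbindlist(locs)
    out_locs[[i]] <- data.table::data.table(
      participant_id = pid, timestamp = loc_dt$timestamp,
      lat = loc_dt$lat, lon = loc_dt$lon
    )
    out_truth[[i]] <- list(
      participant_id = pid, labels = as.list(labels),
      home = home, places = places,
      n_risky_sex = n_risky_sex, n_risky_drug = n_risky_drug,
      lines = data.table::data.table(
        participant_id = pid,
        day = config$start_day + unlist(tl_day, use.names = FALSE),
        package = unlist(tl_pkg, use.names = FALSE),
        text = unlist(tl_text, use.names = FALSE)
      )
    )
  }

  truth_lines_all <- data.table::rbindlist(lapply(out_truth, `[[`, "lines"))
  labels_wide <- data.table::rbindlist(lapply(out_truth, function(tr) {
    c(list(participant_id = tr$participant_id), tr$labels)
  }))
  list(
    keystrokes = data.table::rbindlist(out_keys),
    locations = data.table::rbindlist(out_locs),
    survey = data.table::rbindlist(out_survey),
    ground_truth = list(
      labels = labels_wide,
      participants = lapply(out_truth, function(tr) tr[setdiff(names(tr), "lines")]),
      lines = truth_lines_all
    ),
    config = config
  )
}

#' Write a generated cohort's logs to disk
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"jsonl"`.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- format
  write_event_log(cohort$keystrokes, file.path(dir, paste0("keystrokes.", ext)), "keystroke")
  write_event_log(cohort$locations, file.path(dir, paste0("locations.", ext)), "location")
  write_event_log(cohort$survey, file.path(dir, paste0("survey.", ext)), "survey")
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(labels = gt$labels,
         participants = lapply(gt$participants, function(p) {
           p$places <- as.data.frame(p$places)
           p
         })),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}
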