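# End-to-end orchestration: simulate -> dedup -> featurize -> train ->
# contrast -> report under one JSON config, with per-stage persistence and
# resumability.

#' Compute the per-participant feature matrix
#'
#' Produces the seven feature groups from deduplicated message lines and raw
#' GPS fixes, with group membership encoded in column prefixes (see
#' [feature_group_prefixes()]). Text features (word, risky-phrase,
#' dictionary, embedding) use only lines typed in communication apps
#' (messaging, social media, dating); app-frequency features use all apps.
#' The `social_apps` group additionally carries the three category
#' day-fraction features used in group contrasts
#' (`socapp.catfrac.messaging` / `.social_media` / `.dating`).
#'
#' @param lines deduplicated message lines ([dedup_stream()]), all
#'   participants.
#' @param locations raw location fixes (may be empty).
#' @param config a [cohort_config()].
#' @param participants participant ids to featurize (default: all in
#'   `lines`).
#' @param groups feature groups to compute (default all seven).
#' @param categories,lexicon,dicts,embedder,lemmatizer,stopwords,placeholders
#'   pluggable resources; defaults are the packaged ones.
#' @param vocab_min_users corpus-level user floor applied when building the
#'   word vocabulary. The default 1 keeps all non-stopword lemmas so that
#'   the floor can instead be applied inside cross-validation folds
#'   ([run_grid()]'s `vocab_mode = "fold_internal"`); set it to
#'   `config$min_users_vocab` to freeze the vocabulary on the full corpus.
#' @return feature `data.table`: `participant_id` + prefixed numeric
#'   columns.
#' @export
featurize_cohort <- function(lines, locations, config = cohort_config(),
                             participants = NULL,
                             groups = names(feature_group_prefixes()),
                             categories = app_category_map(),
                             lexicon = risky_lexicon(),
                             dicts = category_dictionary(),
                             embedder = hash_embedder(),
                             lemmatizer = default_lemmatizer(),
                             stopwords = default_stopwords(),
                             placeholders = default_placeholders(),
                             vocab_min_users = 1L) {
  lines <- data.table::as.data.table(lines)
  locations <- data.table::as.data.table(locations)
  participant_id <- NULL
  if (is.null(participants)) participants <- sort(unique(lines$participant_id))
  lines <- lines[participant_id %in% participants]
  comm_cats <- c("messaging", "social_media", "dating")
  line_cat <- app_category_of(lines$package, categories)
  comm_lines <- lines[line_cat %in% comm_cats]

  vocab <- if ("all_words" %in% groups) {
    build_vocab(comm_lines, min_users = vocab_min_users, stopwords = stopwords,
                placeholders = placeholders, lemmatizer = lemmatizer)
  } else character()

  rows <- lapply(participants, function(pid) {
    pl <- lines[participant_id == pid]
    pc <- comm_lines[participant_id == pid]
    feats <- list()

    if (any(c("social_apps", "all_apps") %in% groups)) {
      freq <- app_frequency_features(pl)
      if ("all_apps" %in% groups && length(freq)) {
        feats <- c(feats, stats::setNames(as.list(freq), paste0("app.", names(freq))))
      }
      if ("social_apps" %in% groups) {
        comm <- freq[app_category_of(names(freq), categories) %in% comm_cats]
        if (length(comm)) {
          feats <- c(feats, stats::setNames(as.list(comm), paste0("socapp.", names(comm))))
        }
        for (ct in comm_cats) {
          feats[[paste0("socapp.catfrac.", ct)]] <-
            category_day_fraction(pl, categories, ct)
        }
      }
    }
    if ("location" %in% groups) {
      fixes <- locations[participant_id == pid]
      if (nrow(fixes)) {
        sp <- retain_stationary(fixes, gap_max_s = config$gap_max_min * 60)
        cl <- mean_shift_cluster(sp, r_m = config$mean_shift_radius_m)
        cl$clusters <- assign_home(cl$clusters)
        mf <- mobility_features(sp, cl$assignments, cl$clusters,
                                over_miles = config$over_distance_miles)
      } else {
        mf <- mobility_features(empty_log("location"), integer(), NULL)
      }
      feats <- c(feats, stats::setNames(mf, paste0("loc.", names(mf))))
    }
    if ("risky_words" %in% groups) {
      rf <- risky_phrase_features(pc, lexicon, lemmatizer = lemmatizer,
                                  placeholders = placeholders)
      feats <- c(feats, stats::setNames(as.list(rf), paste0("risky.", names(rf))))
    }
    if ("all_words" %in% groups && length(vocab)) {
      wf <- word_frequency_features(pc, vocab, lemmatizer = lemmatizer,
                                    placeholders = placeholders)
      if (length(wf)) {
        feats <- c(feats, stats::setNames(as.list(wf), paste0("word.", names(wf))))
      }
    }
    if ("dictionary" %in% groups) {
      ds <- dictionary_scores(pc, dicts, placeholders = placeholders)
      feats <- c(feats, stats::setNames(as.list(ds), paste0("dict.", names(ds))))
    }
    if ("embedding" %in% groups) {
      emb <- embed_days(pc, embedder, placeholders = placeholders)
      if (!is.null(emb)) {
        feats <- c(feats, stats::setNames(as.list(emb),
                                          sprintf("emb.%03d", seq_along(emb))))
      }
    }
    c(list(participant_id = pid), feats)
  })
  out <- data.table::rbindlist(rows, fill = TRUE)
  data.table::setcolorder(out, c("participant_id",
                                 sort(setdiff(names(out), "participant_id"))))
  out[]
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "phenorisk_run",
    simulate = list(),       # sim_config() overrides; NULL disables the stage
    inputs = NULL,           # or list(keystrokes=, locations=, survey=)
    cohort = list(),         # cohort_config() overrides
    train = list(models = c("logistic", "gradient_boosting"),
                 combos = NULL, questions = c("meth_use", "partners_6plus",
                                              "condomless_receptive"),
                 vocab_mode = "fold_internal", chance_band = TRUE),
    contrast = list(outcomes = c("meth_use", "partners_6plus"),
                    features = NULL, alpha = NULL)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full pipeline under one configuration
#'
#' Executes simulate -> dedup -> featurize -> train -> contrast -> report,
#' persisting every intermediate under `out_dir` and recording stage-by-stage
#' record counts in `manifest.json`. A stage whose output file already
#' exists is skipped, so a failed or deleted later stage can be re-run
#' without recomputing earlier ones; with an unchanged configuration and
#' seed, re-running reproduces identical outputs.
#'
#' @param config a configuration list, or the path to a JSON file holding
#'   one. Sections: `seed`, `out_dir`, `simulate` ([sim_config()] overrides,
#'   or `NULL` when `inputs` supplies recorded logs), `inputs`
#'   (paths to `keystrokes`/`locations`/`survey` logs), `cohort`
#'   ([cohort_config()] overrides), `train`, `contrast`.
#' @param out_dir overrides `config$out_dir` when given.
#' @return the run manifest (named list), invisibly; all stage outputs are
#'   on disk under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$out_dir, f)
  ccfg <- do.call(cohort_config, cfg$cohort)
  manifest <- list(seed = cfg$seed,
                   version = as.character(utils::packageVersion("phenorisk")),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())

  # --- stage 1: simulate (or ingest recorded logs) ---
  key_path <- path("keystrokes.csv"); loc_path <- path("locations.csv")
  sur_path <- path("survey.csv")
  if (!is.null(cfg$inputs)) {
    for (nm in c("keystrokes", "locations", "survey")) {
      if (is.null(cfg$inputs[[nm]]) || !file.exists(cfg$inputs[[nm]])) {
        stop("missing input log: ", nm, " (", cfg$inputs[[nm]] %||% "unset", ")")
      }
    }
    key_path <- cfg$inputs$keystrokes; loc_path <- cfg$inputs$locations
    sur_path <- cfg$inputs$survey
  } else if (!file.exists(key_path)) {
    sim <- do.call(sim_config, merge_config(list(seed = cfg$seed), cfg$simulate))
    cohort <- generate_cohort(sim)
    write_cohort(cohort, cfg$out_dir, format = "csv")
  }
  keystrokes <- read_event_log(key_path, "keystroke")
  locations <- read_event_log(loc_path, "location")
  survey <- read_event_log(sur_path, "survey")
  manifest$stages$ingest <- list(
    keystroke_events = nrow(keystrokes), location_fixes = nrow(locations),
    survey_answers = nrow(survey),
    malformed = attr(keystrokes, "malformed") + attr(locations, "malformed") +
      attr(survey, "malformed"),
    rejected = attr(keystrokes, "rejected") + attr(locations, "rejected")
  )

  # --- stage 2: dedup + inclusion filter ---
  lines_path <- path("lines.csv")
  if (!file.exists(lines_path)) {
    lines <- dedup_stream(keystrokes, threshold = ccfg$similarity_threshold,
                          domain_map = domain_package_map())
    data.table::fwrite(lines, lines_path)
  }
  lines <- data.table::fread(lines_path,
                             colClasses = list(character = "participant_id", Date = "day"),
                             showProgress = FALSE)
  retained <- filter_min_days(keystrokes, min_days = ccfg$min_days)
  manifest$stages$dedup <- list(
    lines = nrow(lines),
    reduction = if (nrow(keystrokes)) 1 - nrow(lines) / nrow(keystrokes) else NA,
    participants_in = data.table::uniqueN(keystrokes$participant_id),
    participants_retained = length(retained)
  )

  # --- stage 3: featurize + labels ---
  feat_path <- path("features.csv"); lab_path <- path("labels.csv")
  if (!file.exists(feat_path)) {
    features <- featurize_cohort(lines, locations, ccfg, participants = retained)
    write_feature_matrix(features, feat_path)
  }
  features <- read_feature_matrix(feat_path)
  if (!file.exists(lab_path)) {
    participant_id <- NULL
    labels <- derive_labels(survey)[participant_id %in% retained]
    data.table::fwrite(labels, lab_path, na = "")
  }
  labels <- data.table::fread(lab_path, colClasses = list(character = c("participant_id", "question_id", "value")),
                              na.strings = "", showProgress = FALSE)
  manifest$stages$featurize <- list(participants = nrow(features),
                                    features = ncol(features) - 1L)

  # --- stage 4: train ---
  res_path <- path("results.csv")
  if (!file.exists(res_path)) {
    combos <- default_combos()
    if (!is.null(cfg$train$combos)) combos <- combos[unlist(cfg$train$combos)]
    results <- run_grid(features, labels, combos = combos,
                        models = unlist(cfg$train$models),
                        questions = unlist(cfg$train$questions),
                        seed = cfg$seed,
                        vocab_mode = cfg$train$vocab_mode,
                        min_users_vocab = ccfg$min_users_vocab,
                        chance_band = isTRUE(cfg$train$chance_band))
    data.table::fwrite(results, res_path)
  }
  results <- data.table::fread(res_path, showProgress = FALSE)
  manifest$stages$train <- list(cells = nrow(results))

  # --- stage 5: contrast ---
  con_path <- path("contrasts.csv")
  if (!file.exists(con_path)) {
    cfeats <- cfg$contrast$features
    if (is.null(cfeats)) {
      nm <- setdiff(names(features), "participant_id")
      cfeats <- nm[startsWith(nm, "socapp.catfrac.") | startsWith(nm, "risky.cat.") |
                     startsWith(nm, "loc.") | startsWith(nm, "dict.")]
    }
    contrasts <- data.table::rbindlist(lapply(unlist(cfg$contrast$outcomes), function(oc) {
      contrast_suite(features, labels, oc, feature_names = cfeats,
                     alpha = cfg$contrast$alpha %||% ccfg$alpha)
    }))
    data.table::fwrite(contrasts, con_path)
  }
  contrasts <- data.table::fread(con_path, showProgress = FALSE)
  manifest$stages$contrast <- list(tests = nrow(contrasts))

  # --- stage 6: report ---
  rep_path <- path("report.md")
  if (!file.exists(rep_path)) {
    writeLines(report(results, contrasts), rep_path)
  }
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a human-readable run report
#'
#' A Markdown summary: the F1 grid (rows = feature combinations, columns =
#' question x model, logistic/gradient-boosting pairs), the best combination
#' per question, the permutation chance bands when present, and the
#' significant group contrasts.
#'
#' @param results results table from [run_grid()].
#' @param contrasts contrast table from [contrast_suite()] (may be empty).
#' @return character vector of Markdown lines.
#' @export
report <- function(results, contrasts = NULL) {
  results <- data.table::as.data.table(results)
  out <- c("# phenorisk run report", "")
  if (nrow(results)) {
    questions <- unique(results$question)
    combos <- unique(results$combo)
    out <- c(out, "## Minority-class F1 (logistic / gradient boosting)", "",
             paste0("| Feature set | ", paste(questions, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(questions) + 1L), collapse = "|"), "|"))
    for (cb in combos) {
      cells <- vapply(questions, function(q) {
        r <- results[results$question == q & results$combo == cb]
        fmt <- function(m) {
          v <- r$f1[r$model == m]
          if (length(v)) sprintf("%.2f", v) else "-"
        }
        paste0(fmt("logistic"), "/", fmt("gradient_boosting"))
      }, character(1))
      out <- c(out, paste0("| ", cb, " | ", paste(cells, collapse = " | "), " |"))
    }
    out <- c(out, "", "## Best feature set per question", "")
    for (q in questions) {
      r <- results[results$question == q]
      best <- r[which.max(r$f1)]
      band <- if ("chance_upper" %in% names(best)) {
        sprintf(" (chance band [%.2f, %.2f])", best$chance_lower, best$chance_upper)
      } else ""
      out <- c(out, sprintf("- %s: F1 = %.2f with %s + %s%s", q, best$f1,
                            best$combo, best$model, band))
    }
  } else {
    out <- c(out, "No model results.")
  }
  out <- c(out, "", "## Significant group contrasts", "")
  if (!is.null(contrasts) && nrow(contrasts) &&
      any(contrasts$significant %in% TRUE)) {
    sig <- data.table::as.data.table(contrasts)[significant %in% TRUE]
    for (i in seq_len(nrow(sig))) {
      out <- c(out, sprintf("- %s | %s: mean(yes) = %.4g, mean(no) = %.4g, p = %.3g",
                            sig$outcome[i], sig$feature[i], sig$mean_yes[i],
                            sig$mean_no[i], sig$p[i]))
    }
  } else {
    out <- c(out, "None significant.")
  }
  out
}
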