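# Derives binary outcome labels from wellness-survey answers and evaluates
# classifier x feature-set combinations with leave-one-out cross-validation
# scored by minority-class F1.

#' Feature-group column prefixes
#'
#' Feature-group membership is encoded in column-name prefixes of the
#' feature matrix. The seven groups are: per-app use frequencies restricted
#' to communication apps (`social_apps`), all per-app frequencies
#' (`all_apps`), mobility features (`location`), risky-phrase frequencies
#' (`risky_words`), vocabulary word frequencies (`all_words`), dictionary
#' category scores (`dictionary`), and day-averaged text embeddings
#' (`embedding`).
#'
#' @return named character vector: group name -> column prefix.
#' @export
feature_group_prefixes <- function() {
  c(social_apps = "socapp.", all_apps = "app.", location = "loc.",
    risky_words = "risky.", all_words = "word.", dictionary = "dict.",
    embedding = "emb.")
}

#' Registry of evaluated feature-set combinations
#'
#' The thirteen combinations evaluated by the pipeline: each single feature
#' group, the pairings and stacks of communication-app, risky-word, mobility
#' and dictionary features, and an `all` combination (all groups except
#' `social_apps`, which is a subset of `all_apps`).
#'
#' @return named list of character vectors of feature-group names.
#' @export
default_combos <- function() {
  list(
    social_apps = "social_apps",
    all_apps = "all_apps",
    location = "location",
    risky_words = "risky_words",
    all_words = "all_words",
    dictionary = "dictionary",
    embedding = "embedding",
    `risky_words+dictionary` = c("risky_words", "dictionary"),
    `social_apps+risky_words` = c("social_apps", "risky_words"),
    `social_apps+risky_words+dictionary` =
      c("social_apps", "risky_words", "dictionary"),
    `social_apps+risky_words+location` =
      c("social_apps", "risky_words", "location"),
    `social_apps+risky_words+location+dictionary` =
      c("social_apps", "risky_words", "location", "dictionary"),
    all = c("all_apps", "location", "risky_words", "all_words",
            "dictionary", "embedding")
  )
}

# raw survey answer codes -> derived binary questions
.survey_codebook <- list(
  substances_used = list(
    none = c(meth_use = "no", idu = "no"),
    methamphetamine = c(meth_use = "yes", idu = "no"),
    injection_drugs = c(meth_use = "no", idu = "yes"),
    methamphetamine_and_injection_drugs = c(meth_use = "yes", idu = "yes")
  ),
  partner_count = list(
    `0_1` = c(partners_6plus = "no"),
    `2_5` = c(partners_6plus = "no"),
    `6_10` = c(partners_6plus = "yes"),
    `11_plus` = c(partners_6plus = "yes")
  ),
  condomless_receptive_sex = list(
    yes = c(condomless_receptive = "yes"),
    no = c(condomless_receptive = "no")
  ),
  substance_use_treatment = list(
    yes = c(in_treatment = "yes"),
    no = c(in_treatment = "no")
  )
)

.missing_answers <- c("decline_to_answer", "dont_know")

#' Derive binary outcome labels from raw survey answers
#'
#' Compound answer options are decomposed into independent binary questions:
#' a single substance-use answer yields both `meth_use` and `idu`, the
#' partner-count answer yields `partners_6plus`, and so on. "Decline to
#' answer" / "I don't know" become missing for that question only — the
#' participant's other answers are kept. Unknown answer codes become missing
#' with a warning.
#'
#' @param survey survey `data.table` (`participant_id`, `question_id`,
#'   `response`) in the raw wellness-survey schema.
#' @return `data.table` with `participant_id`, `question_id` (derived binary
#'   outcome key), `value` (`"yes"`, `"no"`, or `NA`).
#' @export
derive_labels <- function(survey) {
  survey <- data.table::as.data.table(survey)
  rows <- vector("list", nrow(survey))
  unknown <- character()
  for (i in seq_len(nrow(survey))) {
    q <- survey$question_id[i]
    r <- survey$response[i]
    book <- .survey_codebook[[q]]
    if (is.null(book)) next  # not a label-bearing question
    derived_qs <- unique(unlist(lapply(book, names)))
    if (r %in% .missing_answers) {
      vals <- stats::setNames(rep(NA_character_, length(derived_qs)), derived_qs)
    } else if (!is.null(book[[r]])) {
      vals <- stats::setNames(rep(NA_character_, length(derived_qs)), derived_qs)
      vals[names(book[[r]])] <- book[[r]]
    } else {
      unknown <- c(unknown, paste0(q, "=", r))
      vals <- stats::setNames(rep(NA_character_, length(derived_qs)), derived_qs)
    }
    rows[[i]] <- data.table::data.table(
      participant_id = survey$participant_id[i],
      question_id = names(vals),
      value = unname(vals)
    )
  }
  if (length(unknown)) {
    warning("unknown survey answer code(s) treated as missing: ",
            paste(unique(unknown), collapse = ", "))
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    return(data.table::data.table(participant_id = character(),
                                  question_id = character(),
                                  value = character()))
  }
  participant_id <- NULL; question_id <- NULL
  if (anyDuplicated(out[, list(participant_id, question_id)])) {
    stop("multiple answers for the same (participant, question)")
  }
  data.table::setorder(out, participant_id, question_id)
  out[]
}

# internal: map labels/predictions to 1 = "yes", 0 = "no"
as_binary01 <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    return(as.integer(y))
  }
  y <- as.character(y)
  stopifnot(all(y %in% c("yes", "no")))
  as.integer(y == "yes")
}

# internal: precision / recall / F1 with the minority true class positive
minority_scores <- function(y_true, y_pred) {
  yt <- as_binary01(y_true)
  yp <- as_binary01(y_pred)
  stopifnot(length(yt) == length(yp))
  if (length(unique(yt)) < 2L) {
    warning("minority-class F1 undefined: only one class present in y_true")
    return(list(f1 = NA_real_, precision = NA_real_, recall = NA_real_,
                positive = NA_integer_))
  }
  # ties in class frequency: "yes" (1) is the positive class
  positive <- if (sum(yt == 1) <= sum(yt == 0)) 1L else 0L
  tp <- sum(yt == positive & yp == positive)
  fp <- sum(yt != positive & yp == positive)
  fn <- sum(yt == positive & yp != positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall, positive = positive)
}

#' Minority-class F1 score
#'
#' F1 computed with the less frequent class of `y_true` as the positive
#' class (ties treat `"yes"` as positive). Returns 0 when no true positive
#' is predicted, `NA` (with a warning) when `y_true` has only one class.
#'
#' @param y_true,y_pred equal-length label vectors (`"yes"`/`"no"`, logical,
#'   or 0/1).
#' @return a fraction in `[0, 1]`.
#' @export
f1_minority <- function(y_true, y_pred) {
  minority_scores(y_true, y_pred)$f1
}

#' Permutation chance band for the minority-class F1
#'
#' Estimates the distribution of the minority-class F1 under no association
#' by scoring `n_perm` random permutations of the prediction vector against
#' the fixed true labels, and returns its empirical 95% band.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels (the pooled out-of-fold predictions).
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed.
#' @return list with `lower`, `upper` (2.5% and 97.5% order statistics) and
#'   `scores` (the permuted F1 values).
#' @export
f1_chance_band <- function(y_true, y_pred, n_perm = 200L, seed = 1L) {
  yt <- as_binary01(y_true)
  yp <- as_binary01(y_pred)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  scores <- vapply(seq_len(n_perm), function(i) {
    minority_scores(yt, sample(yp))$f1
  }, numeric(1))
  qs <- stats::quantile(scores, c(0.025, 0.975), type = 1, names = FALSE)
  list(lower = qs[1], upper = qs[2], scores = scores)
}

# internal model fits ---------------------------------------------------

# L2-regularized logistic regression, matching a default scikit-learn-style
# specification: ridge penalty equivalent to C = 1 (lambda = 1/n), iteration
# cap 1000. Features are z-scored by the caller using training-fold
# statistics.
fit_predict_logistic <- function(Xtr, ytr, Xte) {
  if (min(tabulate(ytr + 1L, 2L)) < 2L) {
    # glmnet refuses singleton classes; fall back to a plain ML logistic fit
    df <- as.data.frame(Xtr)
    fit <- suppressWarnings(stats::glm(ytr ~ ., data = cbind(ytr = ytr, df),
                                       family = stats::binomial()))
    p <- suppressWarnings(stats::predict(fit, newdata = as.data.frame(Xte),
                                         type = "response"))
    return(as.integer(p > 0.5))
  }
  if (ncol(Xtr) < 2L) {  # glmnet requires >= 2 predictors
    Xtr <- cbind(Xtr, .pad = 0)
    Xte <- cbind(Xte, .pad = 0)
  }
  # glmnet warns about small class counts on tiny folds; that is the
  # expected regime for leave-one-out on small cohorts
  fit <- suppressWarnings(
    glmnet::glmnet(Xtr, factor(ytr, levels = c(0, 1)), family = "binomial",
                   alpha = 0, lambda = 1 / nrow(Xtr),
                   standardize = FALSE, maxit = 1000L)
  )
  p <- stats::predict(fit, newx = Xte, type = "response")
  as.integer(p > 0.5)
}

# 80-tree gradient-boosted classifier (learning rate 0.1, depth 3), the
# package's analogue of a default gradient-boosting classifier with
# n_estimators = 80.
fit_predict_gbt <- function(Xtr, ytr, Xte, seed = 1L) {
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1),
    nrounds = 80L, verbose = 0
  )
  p <- stats::predict(fit, newdata = xgboost::xgb.DMatrix(Xte, nthread = 1))
  as.integer(p > 0.5)
}

#' Leave-one-out cross-validated evaluation
#'
#' Each participant is predicted by a model trained on all others; the
#' minority-class F1 is computed on the pooled out-of-fold predictions. All
#' per-feature preprocessing (median imputation of missing values;
#' z-scoring for the logistic model; any fold-internal column filter) is fit
#' on the training fold only — nothing from the held-out participant leaks
#' into training. A degenerate training fold containing a single class
#' predicts the majority class with a warning.
#'
#' @param X numeric feature matrix (participants x features, rownames =
#'   participant ids).
#' @param y labels (`"yes"`/`"no"` or 0/1), no missing values.
#' @param model `"logistic"` or `"gradient_boosting"`.
#' @param seed RNG seed forwarded to the classifier.
#' @param fold_filter optional `function(X_train) -> logical column mask`
#'   applied per fold (used for fold-internal vocabulary construction).
#' @return list: `f1`, `precision`, `recall`, `n_used`, `predictions`
#'   (integer 0/1 per participant), `minority` (the positive class).
#' @export
loocv_evaluate <- function(X, y, model = c("logistic", "gradient_boosting"),
                           seed = 1L, fold_filter = NULL) {
  model <- match.arg(model)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y01 <- as_binary01(y)
  n <- nrow(X)
  stopifnot(length(y01) == n)
  if (min(table(factor(y01, levels = c(0, 1)))) < 2L) {
    stop("loocv_evaluate needs at least 2 examples of each class")
  }
  preds <- integer(n)
  degenerate <- 0L
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y01[-i]
    Xte <- X[i, , drop = FALSE]
    if (!is.null(fold_filter)) {
      keep <- fold_filter(Xtr)
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    if (length(unique(ytr)) < 2L) {
      degenerate <- degenerate + 1L
      preds[i] <- as.integer(names(which.max(table(ytr))))
      next
    }
    # median imputation from training-fold statistics
    med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in which(colSums(is.na(Xtr)) > 0L | is.na(Xte))) {
      Xtr[is.na(Xtr[, j]), j] <- med[j]
      Xte[is.na(Xte[, j]), j] <- med[j]
    }
    if (model == "logistic") {
      mu <- colMeans(Xtr)
      sdev <- apply(Xtr, 2, stats::sd)
      sdev[sdev == 0 | !is.finite(sdev)] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdev, "/")
      preds[i] <- fit_predict_logistic(Xtr, ytr, Xte)
    } else {
      preds[i] <- fit_predict_gbt(Xtr, ytr, Xte, seed = seed)
    }
  }
  if (degenerate > 0L) {
    warning(degenerate, " degenerate training fold(s): predicted the majority class")
  }
  sc <- minority_scores(y01, preds)
  list(f1 = sc$f1, precision = sc$precision, recall = sc$recall,
       n_used = n, predictions = preds, minority = sc$positive)
}

# internal: columns of the feature matrix belonging to a set of groups
combo_columns <- function(feature_names, groups) {
  prefixes <- feature_group_prefixes()[groups]
  if (anyNA(prefixes)) stop("unknown feature group(s): ",
                            paste(groups[is.na(prefixes)], collapse = ", "))
  keep <- rep(FALSE, length(feature_names))
  for (p in prefixes) keep <- keep | startsWith(feature_names, p)
  feature_names[keep]
}

#' Evaluate every question x feature-combination x model cell
#'
#' Runs [loocv_evaluate()] for each derived question, each feature-set
#' combination in the registry, and each model, producing a long results
#' table. Participants missing a question's label are excluded from that
#' question only. With `vocab_mode = "fold_internal"` (default) the
#' word-frequency vocabulary's minimum-user filter is applied inside each
#' training fold; `"full_corpus"` reproduces a vocabulary frozen on the full
#' cohort before cross-validation (a mild leak some study designs accept).
#'
#' @param features feature matrix `data.table` (`participant_id` + prefixed
#'   feature columns, see [feature_group_prefixes()]).
#' @param labels derived label `data.table` ([derive_labels()]).
#' @param combos named list of feature-group vectors ([default_combos()]).
#' @param models character subset of `c("logistic", "gradient_boosting")`.
#' @param questions question ids to evaluate (default: all in `labels` with
#'   at least 2 of each class).
#' @param seed RNG seed.
#' @param vocab_mode `"fold_internal"` or `"full_corpus"`.
#' @param min_users_vocab vocabulary user floor for `fold_internal` mode.
#' @param chance_band add 95% permutation chance-band columns
#'   (`chance_lower`, `chance_upper`) per cell.
#' @return `data.table`: `question`, `combo`, `model`, `f1`, `precision`,
#'   `recall`, `n_used` (+ band columns).
#' @export
run_grid <- function(features, labels, combos = default_combos(),
                     models = c("logistic", "gradient_boosting"),
                     questions = NULL, seed = 1L,
                     vocab_mode = c("fold_internal", "full_corpus"),
                     min_users_vocab = 5L, chance_band = FALSE) {
  vocab_mode <- match.arg(vocab_mode)
  features <- data.table::as.data.table(features)
  labels <- data.table::as.data.table(labels)
  question_id <- NULL; value <- NULL; participant_id <- NULL
  if (is.null(questions)) questions <- sort(unique(labels$question_id))

  fmat <- as.matrix(features[, setdiff(names(features), "participant_id"), with = FALSE])
  rownames(fmat) <- features$participant_id
  if (vocab_mode == "full_corpus") {
    word_cols <- startsWith(colnames(fmat), "word.")
    drop <- word_cols & colSums(fmat > 0, na.rm = TRUE) < min_users_vocab
    fmat <- fmat[, !drop, drop = FALSE]
  }

  out <- list()
  for (q in questions) {
    lab <- labels[question_id == q & !is.na(value)]
    lab <- lab[participant_id %in% rownames(fmat)]
    y <- stats::setNames(lab$value, lab$participant_id)
    if (length(y) == 0L || min(table(factor(y, levels = c("no", "yes")))) < 2L) {
      warning("question ", q, " skipped: fewer than 2 examples per class")
      next
    }
    Xq <- fmat[names(y), , drop = FALSE]
    for (cname in names(combos)) {
      cols <- combo_columns(colnames(Xq), combos[[cname]])
      if (length(cols) == 0L) {
        warning("combo ", cname, " skipped: no columns for its feature groups")
        next
      }
      Xc <- Xq[, cols, drop = FALSE]
      filt <- NULL
      if (vocab_mode == "fold_internal" && any(startsWith(cols, "word."))) {
        filt <- function(Xtr) {
          w <- startsWith(colnames(Xtr), "word.")
          !w | colSums(Xtr > 0, na.rm = TRUE) >= min_users_vocab
        }
      }
      for (m in models) {
        res <- loocv_evaluate(Xc, y, model = m, seed = seed, fold_filter = filt)
        row <- data.table::data.table(
          question = q, combo = cname, model = m,
          f1 = res$f1, precision = res$precision, recall = res$recall,
          n_used = res$n_used
        )
        if (chance_band) {
          band <- f1_chance_band(as_binary01(y), res$predictions, seed = seed)
          row$chance_lower <- band$lower
          row$chance_upper <- band$upper
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  data.table::rbindlist(out)
}
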