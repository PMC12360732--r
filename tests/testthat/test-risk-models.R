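test_that("compound survey answers decompose into independent binary labels", {
  survey <- data.table::data.table(
    participant_id = c("a", "a", "b", "b", "c"),
    question_id = c("substances_used", "partner_count",
                    "substances_used", "condomless_receptive_sex",
                    "substances_used"),
    response = c("methamphetamine_and_injection_drugs", "11_plus",
                 "none", "decline_to_answer",
                 "what_is_this"))
  expect_warning(labs <- derive_labels(survey), "unknown")
  get <- function(p, q) labs$value[labs$participant_id == p & labs$question_id == q]
  expect_identical(get("a", "meth_use"), "yes")
  expect_identical(get("a", "idu"), "yes")
  expect_identical(get("a", "partners_6plus"), "yes")
  expect_identical(get("b", "meth_use"), "no")
  expect_identical(get("b", "idu"), "no")
  # decline makes only that question missing; other answers survive
  expect_true(is.na(get("b", "condomless_receptive")))
  expect_true(is.na(get("c", "meth_use")))  # unknown code
})

test_that("minority-class F1 matches confusion-matrix enumeration", {
  # frozen: TP=1, FP=1, FN=1 -> P=R=0.5 -> F1=0.5
  expect_identical(f1_minority(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 1)), 0.5)
  expect_identical(f1_minority(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0)), 1)
  expect_identical(f1_minority(c(1, 1, 0, 0, 0), c(0, 0, 0, 0, 0)), 0)
  expect_warning(out <- f1_minority(c(1, 1, 1), c(1, 0, 1)), "one class")
  expect_true(is.na(out))
  # property: equals an independent confusion-matrix computation
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    yt <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(yt)) < 2) next
    yp <- rbinom(n, 1, 0.5)
    pos <- if (sum(yt == 1) <= sum(yt == 0)) 1 else 0
    tp <- sum(yt == pos & yp == pos); fp <- sum(yt != pos & yp == pos)
    fn <- sum(yt == pos & yp != pos)
    expected <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(f1_minority(yt, yp), expected)
  }
})

test_that("frequency ties make the yes class positive", {
  yt <- c("yes", "yes", "no", "no")
  yp <- c("yes", "no", "no", "no")
  # with yes positive: TP=1, FP=0, FN=1 -> F1 = 2/3
  expect_equal(f1_minority(yt, yp), 2 / 3)
})

test_that("LOOCV recovers a planted signal and stays at chance on permuted labels", {
  set.seed(33)
  n <- 60
  y <- rep(c(1, 0), c(18, 42))
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("p%02d", 1:n), paste0("risky.f", 1:6)))
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 2.5   # planted separation
  res <- loocv_evaluate(X, y, model = "logistic", seed = 1)
  band <- f1_chance_band(y, res$predictions, seed = 1)
  expect_gt(res$f1, band$upper)
  yperm <- sample(y)
  resp <- loocv_evaluate(X, yperm, model = "logistic", seed = 1)
  bandp <- f1_chance_band(yperm, resp$predictions, seed = 1)
  expect_lte(resp$f1, bandp$upper)
  expect_gte(resp$f1, bandp$lower)
})

test_that("duplicating a feature column leaves the tree model unchanged", {
  set.seed(8)
  n <- 40
  y <- rep(c(1, 0), each = 20)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[y == 1, 1] <- X[y == 1, 1] + 2
  base <- loocv_evaluate(X, y, model = "gradient_boosting", seed = 1)
  dup <- loocv_evaluate(cbind(X, a2 = X[, 1]), y, model = "gradient_boosting",
                        seed = 1)
  expect_identical(dup$predictions, base$predictions)
})

test_that("LOOCV is deterministic and the grid enumerates question x combo x model", {
  set.seed(19)
  n <- 30
  feats <- data.table::data.table(
    participant_id = sprintf("p%02d", 1:n),
    socapp.a = rnorm(n), socapp.b = rnorm(n),
    loc.mean_dist_home = rnorm(n), risky.cat.sex_related = runif(n))
  labels <- data.table::rbindlist(lapply(1:n, function(i) data.table::data.table(
    participant_id = sprintf("p%02d", i),
    question_id = c("meth_use", "partners_6plus", "condomless_receptive"),
    value = sample(c("yes", "no"), 3, replace = TRUE))))
  combos <- default_combos()[c("social_apps", "social_apps+risky_words+location")]
  g1 <- run_grid(feats, labels, combos = combos,
                 questions = c("meth_use", "partners_6plus", "condomless_receptive"),
                 seed = 5)
  g2 <- run_grid(feats, labels, combos = combos,
                 questions = c("meth_use", "partners_6plus", "condomless_receptive"),
                 seed = 5)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_identical(nrow(g1), 3L * 2L * 2L)
  expect_true(all(g1$f1 >= 0 & g1$f1 <= 1))
})

test_that("a combo whose feature group is absent is skipped with a warning", {
  feats <- data.table::data.table(participant_id = c("a", "b", "c", "d"),
                                  socapp.x = c(1, 0, 1, 0))
  labels <- data.table::data.table(participant_id = c("a", "b", "c", "d"),
                                   question_id = "meth_use",
                                   value = c("yes", "no", "yes", "no"))
  expect_warning(
    g <- run_grid(feats, labels, combos = default_combos()["location"],
                  models = "logistic"),
    "no columns")
  expect_identical(nrow(g), 0L)
})

test_that("missing labels are excluded per question, not per participant", {
  set.seed(40)
  n <- 24L
  feats <- data.table::data.table(participant_id = sprintf("p%02d", 1:n),
                                  risky.a = rnorm(n), risky.b = rnorm(n))
  labels <- data.table::rbindlist(lapply(1:n, function(i) data.table::data.table(
    participant_id = sprintf("p%02d", i),
    question_id = c("meth_use", "partners_6plus"),
    value = c(if (i <= 4) NA_character_ else sample(c("yes", "no"), 1),
              sample(c("yes", "no"), 1)))))
  g <- run_grid(feats, labels, combos = default_combos()["risky_words"],
                models = "logistic", seed = 2)
  expect_identical(g$n_used[g$question == "meth_use"], n - 4L)
  expect_identical(g$n_used[g$question == "partners_6plus"], n)
})

test_that("fold-internal vocabulary filtering drops rare word columns per fold", {
  set.seed(50)
  n <- 20
  X <- matrix(runif(n * 3), n, 3,
              dimnames = list(sprintf("p%02d", 1:n),
                              c("word.common", "word.rare", "risky.x")))
  X[3:n, "word.rare"] <- 0  # used by 2 participants only
  feats <- data.table::data.table(participant_id = rownames(X), X)
  labels <- data.table::data.table(participant_id = rownames(X),
                                   question_id = "meth_use",
                                   value = rep(c("yes", "no"), each = n / 2))
  expect_silent({
    g_fold <- run_grid(feats, labels, combos = default_combos()["all_words"],
                       models = "logistic", seed = 3, vocab_mode = "fold_internal",
                       min_users_vocab = 5)
    g_full <- run_grid(feats, labels, combos = default_combos()["all_words"],
                       models = "logistic", seed = 3, vocab_mode = "full_corpus",
                       min_users_vocab = 5)
  })
  expect_identical(nrow(g_fold), 1L)
  expect_identical(nrow(g_full), 1L)
})
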