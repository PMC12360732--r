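test_that("token normalization lowercases, strips punctuation, and lemmatizes", {
  lem <- default_lemmatizer()
  expect_identical(normalize_tokens("Walking better!", lem)[[1]], c("walk", "good"))
  expect_identical(normalize_tokens("", lem)[[1]], character())
  expect_identical(normalize_tokens("hello hello", lem)[[1]], c("hello", "hello"))
  expect_identical(normalize_tokens("don't stop", NULL)[[1]], c("don't", "stop"))
  expect_identical(lem(c("parties", "running", "walked", "friends", "went")),
                   c("party", "run", "walk", "friend", "go"))
})

test_that("vocabulary excludes stopwords, placeholders, and rare-user lemmas", {
  lines <- data.table::rbindlist(lapply(1:6, function(i) {
    make_lines(day = 0, package = "com.whatsapp",
               text = if (i <= 4) "the zebra word alpha" else "the zebra word",
               participant = paste0("p", i))
  }))
  lines <- rbind(lines, make_lines(0, "com.whatsapp", "Enter message", "p1"))
  vocab <- build_vocab(lines, min_users = 5)
  expect_true(all(c("zebra", "word") %in% vocab))    # used by 6 participants
  expect_false("alpha" %in% vocab)                   # only 4 users
  expect_false("the" %in% vocab)                     # stopword
  expect_false("enter" %in% vocab)                   # placeholder line dropped
  vocab4 <- build_vocab(lines, min_users = 4)
  expect_true("alpha" %in% vocab4)                   # inclusive boundary
  expect_identical(build_vocab(lines[0]), character())
})

test_that("word frequencies are day-level and match brute-force recounts", {
  lines <- make_lines(day = c(0, 0, 1, 2, 3, 4, 5, 6, 7),
                      package = "com.whatsapp",
                      text = c("cat dog", "cat cat cat", "dog", "bird", "dog",
                               "fish", "fish", "fish", "fish"))
  f <- word_frequency_features(lines, vocab = c("cat", "dog", "fish", "absent"))
  expect_identical(f[["cat"]], 1 / 8)   # twice in one day counts once
  expect_identical(f[["dog"]], 3 / 8)
  expect_identical(f[["fish"]], 0.5)
  expect_identical(f[["absent"]], 0)
  toks <- normalize_tokens(lines$text, NULL)
  for (w in c("cat", "dog", "fish")) {
    expect_identical(f[[w]], brute_day_freq(lines$day,
                                            vapply(toks, function(t) w %in% t, logical(1))))
  }
})

test_that("phrase matching is contiguous within a line; categories use day unions", {
  lex <- data.table::data.table(
    phrase = c("hook up", "no condom", "tina"),
    category = c("sex_related", "sex_related", "drug_related"),
    subcategory = c("hookup_seeking", "condomless", "stimulant_use"))
  lines <- rbind(
    make_lines(0, "a", "wanna hook up tonight"),
    make_lines(1, "a", "hook me before you up"),       # split: no match
    make_lines(2, "a", "no condom here"),
    make_lines(c(3, 4, 5, 6, 7, 8, 9), "a", "nothing here"))
  f <- risky_phrase_features(lines, lex)
  expect_identical(f[["phrase.hook_up"]], 0.1)
  expect_identical(f[["phrase.no_condom"]], 0.1)
  expect_identical(f[["phrase.tina"]], 0)
  # category: union of disjoint day sets {0} and {2} over 10 text days
  expect_identical(f[["cat.sex_related"]], 0.2)
  expect_identical(f[["cat.drug_related"]], 0)
  expect_identical(f[["cat.hookup_seeking"]], 0.1)
  # two-token phrase split across two lines of the same day: no match
  split2 <- rbind(make_lines(0, "a", "wanna hook"), make_lines(0, "a", "up tonight"))
  f2 <- risky_phrase_features(split2, lex)
  expect_identical(f2[["phrase.hook_up"]], 0)
})

test_that("dictionary scores are daily token proportions averaged over days", {
  dicts <- list(social = c("friend*", "talk"), affect = c("happy"))
  lines <- rbind(
    make_lines(0, "a", "my friends are here"),      # 1 of 4 tokens social
    make_lines(1, "a", "talk to me talk loud"))     # 2 of 5 tokens social
  s <- dictionary_scores(lines, dicts)
  expect_equal(s[["social"]], mean(c(1 / 4, 2 / 5)))
  expect_identical(s[["affect"]], 0)
  expect_true(is.na(dictionary_scores(lines[0], dicts)[["social"]]))
})

test_that("the stub embedder is deterministic and day-averaging is elementwise", {
  emb <- hash_embedder(dim = 16, seed = 9)
  v1 <- emb("hello world")
  v2 <- hash_embedder(dim = 16, seed = 9)("hello world")
  expect_identical(v1, v2)
  expect_identical(dim(v1), c(1L, 16L))
  expect_false(isTRUE(all.equal(v1, emb("different text"))))
  one <- make_lines(0, "a", "hello world")
  two <- rbind(one, make_lines(1, "a", "other things"))
  e1 <- embed_days(one, emb)
  e2 <- embed_days(two, emb)
  expect_equal(e1, as.numeric(emb("hello world")))
  expect_equal(e2, (as.numeric(emb("hello world")) + as.numeric(emb("other things"))) / 2)
  expect_null(embed_days(one[0], emb))
})

test_that("adding a day of text leaves previously counted day sets consistent", {
  lines <- make_lines(day = 0:3, package = "a",
                      text = c("cat", "cat dog", "dog", "cat"))
  more <- rbind(lines, make_lines(4, "a", "cat"))
  f1 <- word_frequency_features(lines, c("cat", "dog"))
  f2 <- word_frequency_features(more, c("cat", "dog"))
  # numerator and denominator recomputed together: 3/4 -> 4/5
  expect_identical(f1[["cat"]], 3 / 4)
  expect_identical(f2[["cat"]], 4 / 5)
  expect_identical(f2[["dog"]], 2 / 5)
})

test_that("non-communication app lines contribute to no text feature", {
  cats <- app_category_map()
  lines <- rbind(
    make_lines(0, "com.whatsapp", "tina crystal here"),
    make_lines(1, "com.spotify.music", "tina crystal there"))
  feats <- featurize_cohort(lines, locations = data.table::data.table(),
                            groups = c("risky_words", "dictionary"),
                            categories = cats)
  # only the whatsapp day counts: frequency 1/1, not 2/2 nor 1/2
  expect_identical(feats[["risky.phrase.tina"]], 1)
  drop_music <- featurize_cohort(lines[1], locations = data.table::data.table(),
                                 groups = c("risky_words", "dictionary"),
                                 categories = cats)
  expect_identical(feats[["risky.cat.drug_related"]],
                   drop_music[["risky.cat.drug_related"]])
})
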