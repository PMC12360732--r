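# One small shared cohort keeps these tests fast; individual behaviors are
# exercised on it plus targeted micro-cases.
sim_small <- sim_config(n_participants = 12, n_days = 8, seed = 101)
cohort <- generate_cohort(sim_small)

test_that("typing traces reproduce the worked prefix examples", {
  set.seed(1)
  expect_identical(generate_typing_trace("Hello"),
                   c("H", "He", "Hel", "Hell", "Hello"))
  # with a forced omission typo the trace deviates mid-way and ends
  # corrected; distinct letters make the corrupted prefix a non-substring
  set.seed(4)
  tr <- generate_typing_trace("wordplay", typo_prob = 1)
  expect_identical(tr[length(tr)], "wordplay")
  expect_true(any(!stringi::stri_detect_fixed(tr[-1], tr[-length(tr)])))
})

test_that("every generated trace deduplicates back to its final text", {
  set.seed(9)
  for (rep in 1:60) {
    txt <- paste(sample(letters, sample(6:20, 1), replace = TRUE), collapse = "")
    tr <- generate_typing_trace(txt, typo_prob = 0.5, autocorrect_prob = 0.5)
    ev <- make_keystrokes(list(package = "p", texts = tr))
    expect_identical(dedup_stream(ev)$text, txt)
  }
})

test_that("the full keystroke log deduplicates to exactly the intended lines", {
  lines <- dedup_stream(cohort$keystrokes, domain_map = domain_package_map())
  truth <- cohort$ground_truth$lines
  data.table::setorder(lines, participant_id, day, package, text)
  truth <- data.table::copy(truth)
  data.table::setorder(truth, participant_id, day, package, text)
  expect_identical(nrow(lines), nrow(truth))
  expect_identical(lines$text, truth$text)
  expect_identical(lines$package, truth$package)
  expect_identical(as.character(lines$day), as.character(truth$day))
})

test_that("generation is deterministic: same config and seed, identical output", {
  again <- generate_cohort(sim_small)
  expect_identical(as.data.frame(cohort$keystrokes), as.data.frame(again$keystrokes))
  expect_identical(as.data.frame(cohort$locations), as.data.frame(again$locations))
  expect_identical(as.data.frame(cohort$survey), as.data.frame(again$survey))
  other <- generate_cohort(sim_config(n_participants = 12, n_days = 8, seed = 102))
  expect_false(identical(as.data.frame(cohort$keystrokes),
                         as.data.frame(other$keystrokes)))
})

test_that("generated logs validate against the readers with zero rejects", {
  dir <- tempfile()
  write_cohort(cohort, dir, format = "csv")
  for (spec in list(c("keystrokes.csv", "keystroke"),
                    c("locations.csv", "location"),
                    c("survey.csv", "survey"))) {
    got <- read_event_log(file.path(dir, spec[1]), spec[2])
    expect_identical(attr(got, "malformed"), 0L)
    expect_identical(attr(got, "rejected") %||% 0L, 0L)
    expect_gt(nrow(got), 0L)
  }
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  unlink(dir, recursive = TRUE)
})

test_that("day tracks resolve to the visited places via stay-point detection", {
  set.seed(70)
  home <- c(40, -100)
  places <- cbind(lat = c(40.1, 40.5), lon = c(-100.2, -99.5))
  tr <- generate_day_track(home, places, t0_ms = 0, n_extra = 2)
  fixes <- data.table::data.table(participant_id = "p", tr$fixes)
  sp <- retain_stationary(fixes, gap_max_s = 300)
  expect_identical(nrow(sp), length(tr$visited))  # one stay point per leg
  coords <- rbind(home, places)
  planted <- coords[tr$visited + 1L, , drop = FALSE]
  expect_lt(max(haversine_miles(sp$lat, sp$lon, planted[, 1], planted[, 2])), 0.05)
  # a stay-home day still yields one stay point at home
  tr0 <- generate_day_track(home, places, t0_ms = 0, n_extra = 0)
  sp0 <- retain_stationary(data.table::data.table(participant_id = "p", tr0$fixes))
  expect_identical(nrow(sp0), 1L)
  expect_lt(haversine_miles(sp0$lat, sp0$lon, home[1], home[2]), 0.05)
})

test_that("label prevalence tracks the configured rates", {
  big <- generate_cohort(sim_config(n_participants = 80, n_days = 2, seed = 7))
  gt <- big$ground_truth$labels
  # binomial 95% interval around 0.183 at n = 80
  p <- mean(gt$meth_use)
  expect_gte(p, 0.183 - 1.96 * sqrt(0.183 * 0.817 / 80))
  expect_lte(p, 0.183 + 1.96 * sqrt(0.183 * 0.817 / 80))
  p2 <- mean(gt$partners_6plus)
  expect_gte(p2, 0.5 - 1.96 * sqrt(0.25 / 80))
  expect_lte(p2, 0.5 + 1.96 * sqrt(0.25 / 80))
  # survey answers encode the drawn labels up to missingness
  labs <- derive_labels(big$survey)
  merged <- merge(labs[labs$question_id == "meth_use"],
                  gt[, c("participant_id", "meth_use")], by = "participant_id")
  ok <- !is.na(merged$value)
  expect_identical(merged$value[ok] == "yes", merged$meth_use[ok])
})

test_that("planted class effects move the intended feature families", {
  big <- generate_cohort(sim_config(n_participants = 60, n_days = 12, seed = 55))
  gt <- big$ground_truth$labels
  lines <- dedup_stream(big$keystrokes, domain_map = domain_package_map())
  cats <- app_category_map()
  dating <- vapply(gt$participant_id, function(pid) {
    category_day_fraction(lines[lines$participant_id == pid], cats, "dating")
  }, numeric(1))
  pos <- gt$meth_use | gt$partners_6plus
  expect_gt(mean(dating[pos]), mean(dating[!pos]))
  risky_sex <- vapply(big$ground_truth$participants, `[[`, integer(1), "n_risky_sex")
  expect_gt(mean(risky_sex[pos]) / max(mean(risky_sex[!pos]), 1e-9), 1.5)
  # travel scale doubles mean distance from home for partner-positives
  far <- vapply(seq_along(gt$participant_id), function(i) {
    p <- big$ground_truth$participants[[i]]
    sp <- retain_stationary(big$locations[big$locations$participant_id == p$participant_id])
    mean(haversine_miles(sp$lat, sp$lon, p$home[1], p$home[2]))
  }, numeric(1))
  expect_gt(mean(far[gt$partners_6plus]), mean(far[!gt$partners_6plus]))
})

test_that("effect ratios of one plant no signal (null pipeline sanity)", {
  null_cfg <- sim_config(n_participants = 40, n_days = 6, seed = 77,
                         dating_ratio = 1, risky_word_ratio = 1, travel_ratio = 1)
  nc <- generate_cohort(null_cfg)
  gt <- nc$ground_truth$labels
  risky_sex <- vapply(nc$ground_truth$participants, `[[`, integer(1), "n_risky_sex")
  pos <- gt$meth_use | gt$partners_6plus
  # with no planted effect the groups should not separate cleanly
  p <- t_test_feature(risky_sex[pos], risky_sex[!pos])$p
  expect_gt(p, 0.01)
})

test_that("invalid configurations fail fast", {
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(dating_ratio = 0), "dating_ratio")
  expect_error(generate_typing_trace(""), "nzchar")
})
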