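---
title: "From passive phone sensing to behavioral risk prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From passive phone sensing to behavioral risk prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorisk)
```

## The problem

Digital-phenotyping studies of behavioral health recruit a consented cohort,
install a sensing app on participants' phones, and collect three passive
event streams: a snapshot of the active text field at every keystroke, the
app (or website) the text was typed in, and GPS fixes recorded while the
phone moves. Periodic self-report surveys provide the outcome labels —
here, substance-use and sexual-risk behaviors relevant to STI/HIV
prevention, such as methamphetamine use, having six or more sexual partners
in a quarter, and condomless receptive sex. The analytic question is
whether the passive stream alone predicts those labels, and which parts of
it carry the signal.

The regime is unusual for machine learning: cohorts of a few dozen
participants, raw logs with millions of near-duplicate rows, outcome
prevalences from 4% to 74%, and privacy constraints that rule out sharing
any raw data. `phenorisk` implements the full analysis chain for this
regime, together with a synthetic-cohort generator that stands in for the
unpublishable participant data in every test.

## Keystroke deduplication

Snapshot logging stores each typed line many times (`"H"`, `"He"`, ...,
`"Hello"`), and mid-line edits or autocorrect mean an earlier row is not
always a prefix — or even a substring — of the next (`"Helo"` before
`"Hello"`). Deduplication repeats a sweep over each run of consecutive
same-app events until nothing more can be removed. Within a sweep, each row
is tested against its immediate successor and removed if either

1. its text is a contiguous, case-sensitive substring of the successor's
   text, or
2. the Levenshtein similarity `sim(a,b) = 1 − dist(a,b)/max(len(a),len(b))`
   is strictly greater than 0.6 (configurable),

where `dist` is the unit-cost edit distance, `sim(∅,∅) = 1` by convention.
Three choices here were genuinely open and are worth recording:

* **Both rules are tested against the same successor within a sweep.** The
  alternative — removing substring rows first and then re-pairing survivors
  for the similarity rule — strands corrupted intermediate rows: a typo row
  like `"hey wha "` would be compared against the much longer final line
  (similarity far below threshold) instead of against the very next
  snapshot that corrects it, and would survive forever. Testing both rules
  on one pairing makes every artifact within one edit of its successor
  reducible, which is exactly the reach the similarity rule is meant to
  have.
* **Runs are bounded by app changes.** Consecutive events in different apps
  are different text fields; comparing across the boundary could delete an
  unrelated short line. Within an app, runs continue across day boundaries.
* **Strict inequality at the threshold.** Two five-character rows at
  distance 2 (similarity exactly 0.6) are both kept.

The similarity threshold, like every other pipeline constant, is surfaced
in `cohort_config()`.

## Apps, websites, and use frequencies

Online services are reachable both natively and through a browser, so both
are mapped into one key space: the domain is extracted from the URL
(lowercased hostname, `www.` stripped, no collapsing to the registrable
domain), curated domains map to their package name
(`inst/extdata/domain_package_map.csv`, user-overridable), and uncurated
domains stand as their own key. "Using an app" on a day means producing at
least one deduplicated text line in it that day; the per-app feature is
`freq(app) = #days using app / #days using any app`. Categories
(messaging, social media, dating; everything else `other`) come from an
editable CSV; the packaged map covers widely used apps but is a
reconstruction — any real study should supply its own curated list.

## Mobility

Because the logger records only while the phone moves, a burst of fixes
followed by silence means the participant stopped somewhere: fixes are
split into movement episodes wherever the inter-fix gap exceeds 5 minutes
(a speed threshold is available but off by default, since gaps — not
speeds — are what the logging model guarantees), and the last fix of each
episode is kept as a stay point.

Stay points are clustered with a flat-kernel mean shift: every point moves
iteratively to the mean of all *original* points within radius `r` until
displacement falls below `r/100` (at most 200 iterations); modes closer
than `r/2` merge; a point belongs to its mode's cluster. Coordinates are
projected to local planar meters before clustering (an equirectangular
projection around the centroid — adequate at place scale), and distances
for features use the spherical haversine formula (Earth radius 3958.8
miles) because the far-from-home feature spans geographic scales. The
radius default is 100 m — building-scale place separation; the original
choice of window size in studies of this kind is made by visual inspection,
so the parameter is explicit and configurable. The most visited cluster is
declared home (ties broken by earliest first visit). Features: mean and max
distance from home, fraction of stay points more than 50 miles out, stay
points per day, mean distinct places per day, distinct places, and fraction
of days with any stay point outside the home cluster.

## Text features

Only lines from communication apps (messaging, social media, dating) are
featurized; text typed elsewhere (product names in shopping apps, queries
in navigation) is noise for these outcomes. All frequency features are
day-level — a word typed ten times in one day counts once — because days,
not tokens, are the stable unit when daily text volume varies wildly.

* **Word frequencies.** Tokens are lowercased, punctuation-stripped
  (apostrophes kept inside tokens), and lemmatized. The built-in lemmatizer
  is an exception table plus regular suffix rules — deterministic and
  dependency-light; any `function(tokens) -> lemmas` can be injected. The
  vocabulary excludes stopwords, placeholder lines (`"Enter message"`,
  ...), and lemmas used by fewer than 5 participants;
  `freq(w) = #days with w / #days with text`.
* **Risky phrases.** A lexicon CSV (`phrase,category,subcategory`) with
  categories `sex_related` and `drug_related`; a phrase matches a day if
  its full lemmatized token sequence occurs contiguously within one line
  that day (matching on raw tokens is a flag, since either convention is
  defensible); category features use the day-union of member phrases. The
  packaged lexicon is a small synthetic demonstration — research lexicons
  of this kind are not freely redistributable, so the file is an input.
* **Dictionary scores.** An open LIWC-style format: JSON mapping category
  names to lowercase patterns with an optional terminal wildcard
  (`friend*`). Daily score = matched tokens / all tokens that day,
  averaged over days with at least one token; matching uses unlemmatized
  surface forms, as word-count dictionaries enumerate them. The packaged
  dictionary demonstrates the format for `social`, `affect`, `drives`, and
  `cognitive_processes`; licensed LIWC users export their own.
* **Embeddings.** A day's lines are concatenated, embedded, and the day
  vectors averaged elementwise (token-free days are skipped). The default
  embedder is a deterministic hashing projection (token-hash counts over
  256 bins, a fixed seeded Gaussian projection to 64 dimensions) — a test
  stub with the right interface; a transformer encoder plugs in through
  the same `function(texts) -> matrix` contract.

## Labels, models, evaluation

Survey answers decompose into independent binary questions (a compound
substance-use option yields both `meth_use` and `idu`); "Decline to
answer" and "I don't know" make that question missing for that participant
without touching their other answers. Participants enter the analysis only
with at least 30 distinct days of keystroke data; keystroke days are used
because every feature family depends on the typing stream (the inclusion
stream is configurable).

Two models are evaluated: an L2-regularized logistic regression (ridge
logistic via glmnet with penalty `λ = 1/n`, the classical `C = 1`
equivalent, iteration cap 1000; features z-scored inside each training
fold — scaling is necessary for stable penalized estimation even though
survey-scale pipelines rarely state it) and an 80-tree gradient-boosted
classifier (xgboost, learning rate 0.1, depth 3, remaining settings at
library defaults — the R analogue of a default scikit-learn-style
gradient-boosting classifier; xgboost's additional leaf regularization is a
minor specification difference, documented rather than disabled). On folds
where glmnet cannot fit (a singleton class), a plain maximum-likelihood
logistic fit substitutes.

Evaluation is leave-one-out cross-validation — the honest choice at n ≈ 80
— scored by the F1 of the minority class of each question (ties treat
"yes" as positive), computed on the pooled out-of-fold predictions. All
preprocessing that could leak — imputation medians, z-scoring statistics,
and the rare-user vocabulary filter — is fit inside training folds. The
full-corpus vocabulary variant (`vocab_mode = "full_corpus"`) reproduces
designs that freeze the vocabulary before cross-validation; it is a mild
leak and not the default. The chance level of the F1 is estimated by
scoring 200 permutations of the pooled prediction vector against the fixed
labels; re-fitting the entire LOOCV per permutation would estimate the same
null at hundreds of times the cost, which matters at the scale of a
13-combination × 2-model grid. The 13 feature-set combinations
(`default_combos()`) cover each single group, the risky-word/dictionary
and communication-app stacks, and an `all` combination that excludes
`social_apps` (a subset of `all_apps`, and stacking both would duplicate
columns).

Group contrasts are Welch t tests by default — the unequal-variance form is
the safer default when group sizes differ fivefold; the pooled-variance
Student form is a flag, as is Benjamini–Hochberg adjustment (off by
default: these contrasts are exploratory, and the package reports raw
two-sided p values at α = .05).

## The synthetic cohort

`generate_cohort()` draws, per participant, outcome labels at the
configured prevalences (defaults 0.183 meth use, 0.037 injection drug use,
0.50 six-plus partners, 0.744 condomless receptive sex, 0 in treatment —
the composition of the population the pipeline targets), then simulates:

* **Typing.** Message lines from a template grammar over a neutral
  vocabulary, with lexicon phrases inserted at class-dependent per-line
  rates (base 0.05 sex / 0.04 drug; multiplied by `risky_word_ratio`,
  default 3, in positive classes). Each line becomes a keystroke-snapshot
  trace: its prefix sequence, with an omitted-letter typo (probability
  0.12) or substituted-letter autocorrect artifact (0.08) that persists
  for a few keystrokes before the corrected text resumes. Artifact
  positions are constrained so every corrupted row stays within one edit
  of its successor — i.e., within the deduplication rules' reach — and the
  generator verifies each run's round trip as it emits it, regenerating
  the rare sentence pair that would alias under the rules. Typed-on-web
  lines (recorded under the browser package with a URL) exercise the
  domain mapping.
* **App mix.** Two apps per category per participant; per-category day
  rates (messaging 0.75, social 0.5, other 0.45, dating 0.15 ×
  `dating_ratio` — default 2.5 — for meth- or partner-positives).
* **Movement.** A planted home, local places, and one farther "trip"
  place per participant (distances scaled by `travel_ratio`, default 2,
  for partner-positives); each day emits short in-motion bursts ending at
  each visited place, with every outing returning home — so stay-point
  detection recovers the visit sequence exactly and home stays the most
  visited place.
* **Survey.** True labels encoded into the raw answer codes, with
  "Decline"/"don't know" substituted at the configured missingness rate
  (default 0.05).

Each participant draws from an independent RNG substream derived from
`(seed, index)`, so cohorts are byte-reproducible. What the generator does
*not* emulate: natural language (frequency features see realistic day
rates; embeddings see only bag-of-tokens structure), within-day temporal
patterns, phone-off gaps, or correlated outcomes (a conditional-rate
option plants meth×partners correlation but is off by default). Passing
tests therefore certify the pipeline's mechanics and statistical behavior
under the planted model, not performance on real language or real
mobility.

## Numerical and testing choices

Days are fixed UTC calendar days derived from epoch milliseconds — device
timezones are unrecorded, and a fixed boundary keeps results reproducible.
Degenerate inputs are defined, not special-cased: empty-vs-empty similarity
is 1; a participant with no stay points gets missing mobility features; a
day with no tokens is excluded from dictionary averaging; an all-zero
vector passes through display scaling unchanged.

The test suite checks the edit distance against an exhaustive
first-character recursion (memoized, 10,000 random pairs of length ≤ 6 over
a 3-letter alphabet), frequency arithmetic against brute-force day
recounts, mean-shift against planted configurations (100 instances,
k ∈ 1..5 places separated by thousands of radii), t-test calibration
against its nominal level (1000 null replicates) and power at the
generator's default day-level rates (100 replicates), leakage by requiring
permuted-label LOOCV scores to fall inside the 200-permutation chance
range for all 26 combo × model cells, and signal recovery by requiring the
gradient-boosted F1 to clear the band's upper edge for both headline
outcomes in ≥ 90% of 20 seeded cohorts at the default effect ratios.
Replicate-heavy checks run cohorts of 80 participants at 60 sensing days
(the generator default) for signal recovery and 30 days for the
permutation check; the end-to-end determinism check uses 20 participants ×
32 days. These sizes are the package's chosen test conditions and are
stated here so results can be reproduced exactly.

## Known limitations

* The edit distance is ASCII/Unicode-character based with unit costs; no
  keyboard-aware costs.
* The lemmatizer is rule-based and will over- or under-stem rare English
  forms ("hoping" → "hop"); inject a WordNet-backed lemmatizer for
  linguistic fidelity.
* Mean shift is O(n²) per iteration; fine for per-participant stay points
  (hundreds), not for raw fix streams — which is why clustering runs on
  stay points.
* The permutation band conditions on the realized prediction vector; it is
  a score-level null, not a refit null (see above for why).
* `condomless_receptive` has no planted passive-data effect in the
  generator (prevalence 0.744 but no behavioral elevation), so models
  should — and do — score near chance on it; this mirrors how weakly that
  outcome is expressed in passive streams.
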