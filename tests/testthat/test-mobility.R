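test_that("haversine distance matches the closed-form arc length and is symmetric", {
  expect_identical(haversine_miles(10, 20, 10, 20), 0)
  # one degree along the equator = 2*pi*R/360
  expect_equal(haversine_miles(0, 0, 0, 1), 2 * pi * 3958.8 / 360, tolerance = 1e-6)
  set.seed(3)
  a <- cbind(runif(20, -80, 80), runif(20, -170, 170))
  b <- cbind(runif(20, -80, 80), runif(20, -170, 170))
  expect_equal(haversine_miles(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_miles(b[, 1], b[, 2], a[, 1], a[, 2]))
})

test_that("stationary-point retention keeps the last fix of each movement episode", {
  fx <- function(ts) data.table::data.table(
    participant_id = "p1", timestamp = ts, lat = as.numeric(seq_along(ts)), lon = 0)
  # 5 fixes 1 min apart then 2 h silence -> one stay point, the 5th fix
  got <- retain_stationary(fx(c(0:4 * 60000, 2 * 3600000 + 0:1 * 60000)))
  expect_identical(got$lat, c(5, 7))
  # single fix is its own episode
  expect_identical(nrow(retain_stationary(fx(0))), 1L)
  # two bursts separated by more than the gap -> 2 stay points
  got <- retain_stationary(fx(c(0, 60000, 120000, 1e7, 1e7 + 60000)))
  expect_identical(got$lat, c(3, 5))
  # brute-force oracle on a random trace: episode ends where gap > gap_max
  set.seed(9)
  ts <- cumsum(sample(c(60000, 120000, 600000), 40, replace = TRUE))
  got <- retain_stationary(fx(ts), gap_max_s = 300)
  ends <- which(diff(ts) > 300000)
  expect_identical(got$timestamp, ts[sort(unique(c(ends, length(ts))))])
})

test_that("mean shift recovers well-separated blobs and degenerate inputs", {
  set.seed(4)
  jitter_deg <- 20 / 111320  # ~20 m
  blob <- function(lat, lon, n, t0) data.table::data.table(
    timestamp = t0 + seq_len(n) * 3600000,
    lat = lat + runif(n, -jitter_deg, jitter_deg),
    lon = lon + runif(n, -jitter_deg, jitter_deg))
  pts <- rbind(blob(40, -100, 5, 0), blob(40.2, -100, 5, 1e9))  # ~14 mi apart
  ms <- mean_shift_cluster(pts, r_m = 100)
  expect_identical(nrow(ms$clusters), 2L)
  expect_identical(sum(ms$clusters$visit_count), 10L)
  # centroids within r/10 of the blob means
  i1 <- ms$assignments[1]
  expect_lt(haversine_miles(ms$clusters$lat[i1], ms$clusters$lon[i1],
                            mean(pts$lat[1:5]), mean(pts$lon[1:5])) * 1609.34, 10)
  # all points identical -> one cluster at that point
  same <- data.table::data.table(timestamp = 1:4, lat = 40, lon = -100)
  ms1 <- mean_shift_cluster(same, r_m = 100)
  expect_identical(nrow(ms1$clusters), 1L)
  expect_equal(ms1$clusters$lat, 40)
  # a single point is its own cluster with one visit
  ms2 <- mean_shift_cluster(same[1], r_m = 100)
  expect_identical(ms2$clusters$visit_count, 1L)
})

test_that("mean shift is invariant to point order and small global translation", {
  set.seed(14)
  jd <- 30 / 111320
  pts <- data.table::data.table(
    timestamp = 1:12,
    lat = rep(c(35, 35.05, 35.1), each = 4) + runif(12, -jd, jd),
    lon = rep(c(-90, -90.05, -90.02), each = 4) + runif(12, -jd, jd))
  base <- mean_shift_cluster(pts, r_m = 100)
  perm <- sample(12)
  shuf <- mean_shift_cluster(pts[perm], r_m = 100)
  expect_identical(nrow(shuf$clusters), nrow(base$clusters))
  expect_equal(sort(shuf$clusters$lat), sort(base$clusters$lat), tolerance = 1e-9)
  moved <- data.table::copy(pts)[, `:=`(lat = lat + 0.3, lon = lon + 0.4)]
  trans <- mean_shift_cluster(moved, r_m = 100)
  expect_identical(nrow(trans$clusters), nrow(base$clusters))
  expect_equal(sort(trans$clusters$lat) - 0.3, sort(base$clusters$lat),
               tolerance = 1e-5)
})

test_that("cluster count is non-increasing in the radius", {
  set.seed(25)
  for (rep in 1:5) {
    pts <- data.table::data.table(
      timestamp = 1:30,
      lat = 40 + runif(30, 0, 0.02),
      lon = -100 + runif(30, 0, 0.02))
    ks <- vapply(c(50, 100, 200, 400, 1000), function(r) {
      nrow(mean_shift_cluster(pts, r_m = r)$clusters)
    }, integer(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("home is the most visited cluster with earliest-visit tie-break", {
  cl <- data.table::data.table(cluster_id = 1:3, lat = 1:3, lon = 1:3,
                               visit_count = c(10L, 3L, 2L),
                               first_visit = c(5, 1, 2), is_home = FALSE)
  expect_identical(assign_home(cl)$is_home, c(TRUE, FALSE, FALSE))
  tie <- data.table::data.table(cluster_id = 1:2, lat = 1:2, lon = 1:2,
                                visit_count = c(5L, 5L),
                                first_visit = c(9, 2), is_home = FALSE)
  expect_identical(assign_home(tie)$is_home, c(FALSE, TRUE))
  one <- tie[1]
  expect_true(assign_home(one)$is_home)
})

test_that("mobility features match a hand-tallied three-day trace", {
  day_ms <- 86400000
  # home at (40, -100); far place ~60 mi east; near place ~7 mi north
  home <- c(40, -100)
  far <- c(40, -100 + 60 / (69.093 * cos(40 * pi / 180)))
  near <- c(40 + 7 / 69.093, -100)
  sp <- data.table::data.table(
    participant_id = "p1",
    timestamp = c(0, 3600000, 7200000,                    # day 1: home, far, home
                  day_ms, day_ms + 3600000,               # day 2: home, near
                  2 * day_ms),                            # day 3: home
    lat = c(home[1], far[1], home[1], home[1], near[1], home[1]),
    lon = c(home[2], far[2], home[2], home[2], near[2], home[2]))
  ms <- mean_shift_cluster(sp, r_m = 100)
  cl <- assign_home(ms$clusters)
  expect_identical(cl$cluster_id[cl$is_home], 1L)  # 4 home visits, most visited
  mf <- mobility_features(sp, ms$assignments, cl)
  d <- haversine_miles(sp$lat, sp$lon, home[1], home[2])
  expect_equal(mf$mean_dist_home, mean(d), tolerance = 1e-9)
  expect_equal(mf$max_dist_home, max(d), tolerance = 1e-9)
  expect_identical(mf$frac_over_50mi, 1 / 6)     # one of six stay points
  expect_identical(mf$places_per_day, 2)         # 6 stay points / 3 days
  expect_identical(mf$n_unique_places, 3L)
  expect_identical(mf$unique_places_per_day, mean(c(2, 2, 1)))
  expect_identical(mf$frac_days_away, 2 / 3)
  # all stay points at home -> zero distances and away fractions
  athome <- sp[c(1, 4, 6)]
  msh <- mean_shift_cluster(athome, r_m = 100)
  mfh <- mobility_features(athome, msh$assignments, assign_home(msh$clusters))
  expect_identical(mfh$frac_over_50mi, 0)
  expect_identical(mfh$frac_days_away, 0)
})

test_that("planted places are recovered and the most visited flagged home", {
  set.seed(31)
  ok <- 0L
  n_inst <- 40L
  for (inst in seq_len(n_inst)) {
    k <- sample(1:5, 1)
    home <- c(runif(1, 30, 45), runif(1, -120, -80))
    places <- cbind(home[1] + runif(k - 1, 0.05, 0.5) * sample(c(-1, 1), max(k - 1, 0), TRUE),
                    home[2] + runif(k - 1, 0.05, 0.5) * sample(c(-1, 1), max(k - 1, 0), TRUE))
    coords <- rbind(home, places)
    visits <- c(10, rep(3, k - 1))
    jd <- 15 / 111320
    sp <- data.table::data.table(
      timestamp = seq_len(sum(visits)) * 3.6e6,
      lat = rep(coords[, 1], visits) + runif(sum(visits), -jd, jd),
      lon = rep(coords[, 2], visits) + runif(sum(visits), -jd, jd))
    ms <- mean_shift_cluster(sp, r_m = 100)
    cl <- assign_home(ms$clusters)
    home_cl <- cl[cl$is_home]
    if (nrow(ms$clusters) == k &&
        haversine_miles(home_cl$lat, home_cl$lon, home[1], home[2]) * 1609.34 < 50) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_inst, 0.95)
})
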