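# Converts raw GPS fixes into stay points, clusters them into places with a
# flat-kernel mean shift, infers the home place, and computes mobility
# features.
#
# The location logger records fixes only while the phone is moving, so a
# movement episode appears as a burst of fixes followed by silence. Only the
# last fix of each episode — the place where movement ended and the
# participant stayed — is retained as a "stay point".

#' Great-circle distance in miles
#'
#' Haversine distance with Earth radius 3958.8 miles. Symmetric; zero iff
#' the points coincide.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @return numeric vector of distances in miles.
#' @export
haversine_miles <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  if (n == 0L) return(numeric())
  geosphere::distHaversine(
    cbind(rep_len(lon1, n), rep_len(lat1, n)),
    cbind(rep_len(lon2, n), rep_len(lat2, n)),
    r = 3958.8
  )
}

#' Retain stationary points from a movement-only GPS stream
#'
#' Partitions each participant's timestamp-sorted fixes into movement
#' episodes — maximal stretches of consecutive fixes with inter-fix gaps of
#' at most `gap_max_s` seconds — and emits the last fix of each episode as a
#' stay point. An isolated fix forms its own episode. An optional minimum
#' speed `v_min_mph` (off by default) additionally drops fixes whose speed
#' from the previous fix is below the threshold before episode splitting.
#'
#' @param fixes location `data.table` (`participant_id`, `timestamp`, `lat`,
#'   `lon`).
#' @param gap_max_s maximum within-episode gap, seconds (default 300).
#' @param v_min_mph optional minimum speed filter in miles/hour; `NULL`
#'   disables it.
#' @return `data.table` of stay points in the same schema.
#' @export
retain_stationary <- function(fixes, gap_max_s = 300, v_min_mph = NULL) {
  fixes <- data.table::as.data.table(fixes)
  participant_id <- NULL; timestamp <- NULL
  if (nrow(fixes) == 0L) return(fixes)
  data.table::setorder(fixes, participant_id, timestamp)
  if (!is.null(v_min_mph) && nrow(fixes) > 1L) {
    n <- nrow(fixes)
    dt_h <- (fixes$timestamp[-1] - fixes$timestamp[-n]) / 3.6e6
    d_mi <- haversine_miles(fixes$lat[-n], fixes$lon[-n], fixes$lat[-1], fixes$lon[-1])
    speed <- ifelse(dt_h > 0, d_mi / dt_h, Inf)
    same <- fixes$participant_id[-n] == fixes$participant_id[-1]
    slow <- c(FALSE, same & speed < v_min_mph)
    fixes <- fixes[!slow]
  }
  n <- nrow(fixes)
  if (n == 1L) return(fixes)
  gap_ms <- gap_max_s * 1000
  same <- fixes$participant_id[-n] == fixes$participant_id[-1]
  within <- same & (fixes$timestamp[-1] - fixes$timestamp[-n]) <= gap_ms
  last_of_episode <- c(!within, TRUE)
  fixes[last_of_episode]
}

# internal: equirectangular projection to planar meters around the centroid
project_local <- function(lat, lon) {
  lat0 <- mean(lat)
  lon0 <- mean(lon)
  m_per_deg_lat <- 111132.95
  m_per_deg_lon <- 111319.49 * cos(lat0 * pi / 180)
  cbind(x = (lon - lon0) * m_per_deg_lon, y = (lat - lat0) * m_per_deg_lat)
}

#' Mean-shift place clustering of stay points
#'
#' Flat-kernel mean shift over the original-point neighborhoods: every point
#' is iteratively replaced by the mean of all *original* points within radius
#' `r_m` of it until its displacement falls below `tol` (default `r_m / 100`)
#' or `max_iter` iterations. Converged modes closer than `r_m / 2` are
#' merged; each stay point is assigned to its mode's cluster. Coordinates are
#' projected to local planar meters for clustering; centroids are the mean
#' lat/lon of the member stay points. Cluster ids are ordered by decreasing
#' visit count (ties by earliest first visit).
#'
#' @param staypoints stay-point `data.table` for one participant
#'   (`timestamp`, `lat`, `lon`).
#' @param r_m window radius in meters (default 100).
#' @param tol convergence displacement in meters.
#' @param max_iter iteration cap.
#' @return list with `assignments` (integer cluster id per stay point) and
#'   `clusters` (`data.table`: `cluster_id`, `lat`, `lon`, `visit_count`,
#'   `first_visit`, `is_home` initialized `FALSE`).
#' @export
mean_shift_cluster <- function(staypoints, r_m = 100, tol = r_m / 100,
                               max_iter = 200L) {
  staypoints <- data.table::as.data.table(staypoints)
  n <- nrow(staypoints)
  if (n == 0L) stop("mean_shift_cluster needs at least one stay point")
  stopifnot_scalar_number(r_m, "r_m", min = 1e-9)
  P <- project_local(staypoints$lat, staypoints$lon)
  modes <- P
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    # squared distances from active modes to all original points
    d2 <- outer(modes[idx, 1], P[, 1], "-")^2 + outer(modes[idx, 2], P[, 2], "-")^2
    inside <- d2 <= r_m^2
    cnt <- rowSums(inside)
    empty <- cnt == 0           # no original point in reach: freeze the mode
    cnt[empty] <- 1
    newx <- (inside %*% P[, 1]) / cnt
    newy <- (inside %*% P[, 2]) / cnt
    newx[empty] <- modes[idx, 1][empty]
    newy[empty] <- modes[idx, 2][empty]
    shift <- sqrt((newx - modes[idx, 1])^2 + (newy - modes[idx, 2])^2)
    modes[idx, 1] <- newx
    modes[idx, 2] <- newy
    active[idx] <- shift >= tol
  }
  # merge modes within r/2 of each other (single-linkage by greedy seeding)
  centers <- matrix(numeric(0), ncol = 2)
  assign <- integer(n)
  for (i in seq_len(n)) {
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - modes[i, 1])^2 + (centers[, 2] - modes[i, 2])^2)
      j <- which.min(d)
    }
    if (nrow(centers) && d[j] <= r_m / 2) {
      assign[i] <- j
    } else {
      centers <- rbind(centers, modes[i, , drop = FALSE])
      assign[i] <- nrow(centers)
    }
  }
  lat <- NULL; lon <- NULL; timestamp <- NULL; cl <- NULL
  members <- data.table::data.table(cl = assign,
                                    lat = staypoints$lat, lon = staypoints$lon,
                                    timestamp = staypoints$timestamp)
  clusters <- members[, list(lat = mean(lat), lon = mean(lon),
                             visit_count = .N,
                             first_visit = min(timestamp)), by = cl]
  data.table::setorder(clusters, -visit_count, first_visit)
  relabel <- stats::setNames(seq_len(nrow(clusters)), clusters$cl)
  clusters[, cl := NULL]
  clusters[, `:=`(cluster_id = seq_len(.N), is_home = FALSE)]
  data.table::setcolorder(clusters, c("cluster_id", "lat", "lon",
                                      "visit_count", "first_visit", "is_home"))
  list(assignments = unname(relabel[as.character(assign)]),
       clusters = clusters[])
}

#' Flag the home cluster
#'
#' The most visited place is taken to be the participant's home; ties are
#' broken by the earliest first-visit timestamp.
#'
#' @param clusters cluster `data.table` from [mean_shift_cluster()].
#' @return the same `data.table` with exactly one `is_home = TRUE` row.
#' @export
assign_home <- function(clusters) {
  clusters <- data.table::copy(data.table::as.data.table(clusters))
  if (nrow(clusters) == 0L) stop("assign_home needs at least one cluster")
  ord <- order(-clusters$visit_count, clusters$first_visit)
  clusters$is_home <- FALSE
  clusters$is_home[ord[1]] <- TRUE
  clusters[]
}

#' Mobility feature summary
#'
#' Distances are stay-point-to-home great-circle miles (home = centroid of
#' the home cluster). `n_days` is the number of distinct UTC days with at
#' least one stay point.
#'
#' @param staypoints stay-point `data.table` for one participant.
#' @param assignments integer cluster id per stay point.
#' @param clusters cluster table with home flagged ([assign_home()]).
#' @param over_miles cutoff for the far-from-home fraction (default 50).
#' @return named list: `mean_dist_home`, `max_dist_home`, `frac_over_50mi`,
#'   `places_per_day`, `unique_places_per_day`, `n_unique_places`,
#'   `frac_days_away`; all `NA` when there are no stay points.
#' @export
mobility_features <- function(staypoints, assignments, clusters,
                              over_miles = 50) {
  nm <- c("mean_dist_home", "max_dist_home", "frac_over_50mi",
          "places_per_day", "unique_places_per_day", "n_unique_places",
          "frac_days_away")
  staypoints <- data.table::as.data.table(staypoints)
  if (nrow(staypoints) == 0L) {
    return(stats::setNames(as.list(rep(NA_real_, length(nm))), nm))
  }
  clusters <- data.table::as.data.table(clusters)
  home <- clusters[clusters$is_home == TRUE]
  if (nrow(home) != 1L) stop("exactly one home cluster required; call assign_home()")
  d <- haversine_miles(staypoints$lat, staypoints$lon, home$lat, home$lon)
  days <- epoch_ms_to_day(staypoints$timestamp)
  n_days <- data.table::uniqueN(days)
  per_day_unique <- tapply(assignments, as.character(days),
                           function(a) length(unique(a)))
  away_day <- tapply(assignments, as.character(days),
                     function(a) any(a != home$cluster_id))
  list(
    mean_dist_home = mean(d),
    max_dist_home = max(d),
    frac_over_50mi = mean(d > over_miles),
    places_per_day = nrow(staypoints) / n_days,
    unique_places_per_day = mean(per_day_unique),
    n_unique_places = data.table::uniqueN(assignments),
    frac_days_away = mean(away_day)
  )
}
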