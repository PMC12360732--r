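# Canonicalizes apps and websites into a single app key space, assigns
# communication categories, and computes app-use frequency features.
#
# Many services are reachable both as an Android app (a package name such as
# "com.instagram.android") and as a website. The two are unified by
# extracting the domain from the URL and mapping curated domains to the
# corresponding package; uncurated domains stand as their own app key, so
# apps and websites are treated identically downstream.

#' Load the app category map
#'
#' Communication apps are grouped into three categories — `messaging`,
#' `social_media`, and `dating` — with everything unmapped defaulting to
#' `other`. The packaged default covers widely used apps (Messages, WhatsApp,
#' Telegram, Facebook, Instagram, Twitter/X, Grindr, Tinder, Adam4Adam, ...);
#' it is a reconstruction, and studies should supply their own curated CSV
#' (`package,category`).
#'
#' @param path CSV with columns `package,category`; default = packaged map.
#' @return named character vector: canonical app key -> category.
#' @export
app_category_map <- function(path = pr_extdata("app_categories.csv")) {
  dt <- data.table::fread(path, showProgress = FALSE)
  stopifnot(all(c("package", "category") %in% names(dt)))
  bad <- setdiff(unique(dt$category), c("messaging", "social_media", "dating", "other"))
  if (length(bad)) stop("unknown app categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(dt$package)) stop("duplicate package in category map")
  stats::setNames(dt$category, dt$package)
}

#' Load the curated domain-to-package map
#'
#' @param path CSV with columns `domain,package`; default = packaged map.
#' @return named character vector: domain -> package name.
#' @export
domain_package_map <- function(path = pr_extdata("domain_package_map.csv")) {
  dt <- data.table::fread(path, showProgress = FALSE)
  stopifnot(all(c("domain", "package") %in% names(dt)))
  stats::setNames(dt$package, tolower(dt$domain))
}

#' Extract the domain name from a URL
#'
#' Lowercased hostname with scheme, credentials, port, path, query, and
#' fragment stripped, and a leading `"www."` removed. The full remaining
#' hostname is kept (no collapsing to the registrable domain). Empty or
#' unparseable input yields `""`.
#'
#' @param url character vector of URLs.
#' @return character vector of domains.
#' @export
extract_domain <- function(url) {
  url <- as.character(url)
  out <- character(length(url))
  nz <- !is.na(url) & nzchar(url)
  u <- tolower(trimws(url[nz]))
  u <- sub("^[a-z][a-z0-9+.-]*://", "", u)        # scheme
  u <- sub("^[^/?#]*@", "", u)                    # credentials
  u <- sub("[/?#].*$", "", u)                     # path / query / fragment
  u <- sub(":[0-9]*$", "", u)                     # port
  u <- sub("^www\\.", "", u)
  u[!grepl("^[a-z0-9._-]+$", u)] <- ""
  out[nz] <- u
  out
}

#' Canonical app key for an event
#'
#' If a URL is present and its domain is on the curated list, the mapped
#' package name is used; an uncurated domain stands as its own key; with no
#' URL the recorded package name is the key. Canonicalization is idempotent.
#'
#' @param package character vector of recorded package names.
#' @param url optional character vector of URLs (`NA`/`""` = none).
#' @param map curated domain-to-package map ([domain_package_map()]).
#' @return character vector of canonical app keys.
#' @export
canonical_app_key <- function(package, url = NULL,
                              map = domain_package_map()) {
  package <- as.character(package)
  n <- length(package)
  if (is.null(url)) url <- rep(NA_character_, n)
  url <- rep_len(as.character(url), n)
  has_url <- !is.na(url) & nzchar(url)
  key <- package
  if (any(has_url)) {
    dom <- extract_domain(url[has_url])
    mapped <- unname(map[dom])
    key[has_url] <- ifelse(!is.na(mapped), mapped,
                           ifelse(nzchar(dom), dom, package[has_url]))
  }
  if (any(!nzchar(key) | is.na(key))) {
    stop("record with neither a usable package name nor a usable URL")
  }
  key
}

#' Per-app use-day frequency features
#'
#' For one participant, the frequency of an app is the number of distinct UTC
#' days with at least one deduplicated text line in that app divided by the
#' number of distinct days with a line in any app ("using an app" = typing in
#' it that day).
#'
#' @param lines message-line `data.table` for one participant
#'   (`day`, `package`, ...).
#' @return named numeric vector of frequencies in `[0, 1]` (one per app key);
#'   empty if the participant has no active days.
#' @export
app_frequency_features <- function(lines) {
  lines <- data.table::as.data.table(lines)
  if (nrow(lines) == 0L) return(stats::setNames(numeric(), character()))
  day <- NULL; package <- NULL
  dd <- unique(lines[, list(package, day)])
  total_days <- data.table::uniqueN(dd$day)
  if (total_days == 0L) return(stats::setNames(numeric(), character()))
  counts <- dd[, list(n = .N), by = package]
  stats::setNames(counts$n / total_days, counts$package)
}

#' Fraction of active days using a category of communication apps
#'
#' Distinct days with at least one line in any app of the category divided by
#' distinct days with at least one line overall.
#'
#' @param lines message-line `data.table` for one participant.
#' @param categories named category map ([app_category_map()]).
#' @param category one of `"messaging"`, `"social_media"`, `"dating"`,
#'   `"other"`.
#' @return a fraction in `[0, 1]` (0 when no active days).
#' @export
category_day_fraction <- function(lines, categories, category) {
  lines <- data.table::as.data.table(lines)
  if (nrow(lines) == 0L) return(0)
  cat_of <- app_category_of(lines$package, categories)
  total_days <- data.table::uniqueN(lines$day)
  if (total_days == 0L) return(0)
  data.table::uniqueN(lines$day[cat_of == category]) / total_days
}

# internal: category lookup with "other" default
app_category_of <- function(key, categories) {
  out <- unname(categories[key])
  out[is.na(out)] <- "other"
  out
}
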