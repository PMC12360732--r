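#' @import data.table
#' @importFrom stats quantile rnorm runif rbinom rpois sd setNames predict
#' @importFrom utils adist head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert epoch milliseconds to a UTC calendar date
#'
#' All day attribution in the pipeline uses a fixed UTC day boundary so that
#' results do not depend on the analyst's locale or on unrecorded device
#' timezones.
#'
#' @param ms numeric vector of epoch timestamps in milliseconds.
#' @return a `Date` vector.
#' @export
epoch_ms_to_day <- function(ms) {
  as.Date(floor(as.numeric(ms) / 86400000), origin = "1970-01-01")
}

# internal: derive a reproducible 32-bit sub-seed from (seed, index)
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483587L) + 1L
}

pr_log <- function(fmt, ..., verbose = getOption("phenorisk.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

pr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phenorisk")
  if (!nzchar(path)) stop("packaged resource not found: ", file)
  path
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
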