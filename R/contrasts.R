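# Feature analysis: independent two-sample t tests on features between
# outcome groups ("yes" vs "no"), with optional display scaling.

#' Independent two-sample t test on one feature
#'
#' Welch's unequal-variance t test by default (a `var_equal = TRUE` flag
#' gives the pooled-variance Student variant); two-sided p value,
#' significance called at `alpha` without multiplicity correction.
#'
#' @param values_yes,values_no numeric feature values in the two outcome
#'   groups.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance Student t instead of Welch.
#' @return one-row `data.frame`: `mean_yes`, `mean_no`, `t`, `df`, `p`,
#'   `significant`, `testable`.
#' @export
t_test_feature <- function(values_yes, values_no, alpha = 0.05,
                           var_equal = FALSE) {
  values_yes <- values_yes[is.finite(values_yes)]
  values_no <- values_no[is.finite(values_no)]
  testable <- length(values_yes) >= 2L && length(values_no) >= 2L &&
    (stats::var(values_yes) + stats::var(values_no)) > 0
  if (!testable) {
    return(data.frame(mean_yes = if (length(values_yes)) mean(values_yes) else NA_real_,
                      mean_no = if (length(values_no)) mean(values_no) else NA_real_,
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      significant = NA, testable = FALSE))
  }
  ht <- stats::t.test(values_yes, values_no, var.equal = var_equal)
  data.frame(mean_yes = mean(values_yes), mean_no = mean(values_no),
             t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, significant = ht$p.value < alpha,
             testable = TRUE)
}

#' Group contrasts for a set of features
#'
#' Splits participants into `"yes"` and `"no"` groups on one derived outcome
#' (missing labels excluded) and runs [t_test_feature()] on each requested
#' feature column. Unknown feature names are skipped with a warning. An
#' optional Benjamini-Hochberg adjustment (`p_adjust = "BH"`, off by
#' default) adds an adjusted p column.
#'
#' @param features feature matrix `data.table` (`participant_id` + feature
#'   columns).
#' @param labels derived label `data.table` ([derive_labels()]).
#' @param outcome derived question id (e.g. `"meth_use"`).
#' @param feature_names columns to test (default: all feature columns).
#' @param alpha significance level.
#' @param var_equal use Student instead of Welch.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return `data.table` with one row per tested feature.
#' @export
contrast_suite <- function(features, labels, outcome,
                           feature_names = NULL, alpha = 0.05,
                           var_equal = FALSE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  features <- data.table::as.data.table(features)
  labels <- data.table::as.data.table(labels)
  question_id <- NULL; value <- NULL; participant_id <- NULL
  lab <- labels[question_id == outcome & !is.na(value)]
  lab <- lab[participant_id %in% features$participant_id]
  all_feats <- setdiff(names(features), "participant_id")
  if (is.null(feature_names)) feature_names <- all_feats
  unknown <- setdiff(feature_names, all_feats)
  if (length(unknown)) {
    warning("unknown feature(s) skipped: ", paste(unknown, collapse = ", "))
    feature_names <- intersect(feature_names, all_feats)
  }
  idx <- match(lab$participant_id, features$participant_id)
  yes <- idx[lab$value == "yes"]
  no <- idx[lab$value == "no"]
  rows <- lapply(feature_names, function(f) {
    v <- features[[f]]
    cbind(data.frame(feature = f, outcome = outcome,
                     n_yes = length(yes), n_no = length(no)),
          t_test_feature(v[yes], v[no], alpha = alpha, var_equal = var_equal))
  })
  out <- data.table::rbindlist(rows)
  if (p_adjust == "BH" && nrow(out)) {
    p <- NULL
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  }
  out[]
}

#' Scale values for joint display
#'
#' Divides every value by the maximum absolute value so that the largest
#' individual value becomes 1, letting features of different units share one
#' axis. All-zero input is returned unchanged.
#'
#' @param values numeric vector (at least one finite value).
#' @return scaled numeric vector.
#' @export
scale_for_display <- function(values) {
  stopifnot(any(is.finite(values)))
  m <- max(abs(values[is.finite(values)]))
  if (m == 0) return(values)
  values / m
}
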