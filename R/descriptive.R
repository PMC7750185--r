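#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (e.g. 29.55 -> 29.6 at one
#' decimal), the convention used for all reported percentages so printed
#' tables match hand-computed values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

.pct <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

#' Threshold rule for failure classification
#'
#' Conventional contamination thresholds: a sample fails when its total
#' bacterial count strictly exceeds 100,000 cfu/ml or its coliform count
#' strictly exceeds 10,000 cfu/ml.
#'
#' @param tbc_threshold,cc_threshold Positive thresholds (cfu/ml).
#' @return A `threshold_rule` list.
#' @export
threshold_rule <- function(tbc_threshold = 1e5, cc_threshold = 1e4) {
  stopifnot(tbc_threshold > 0, cc_threshold > 0)
  structure(list(tbc_threshold = tbc_threshold, cc_threshold = cc_threshold,
                 comparison = "strictly-greater"),
            class = "threshold_rule")
}

#' Classify samples against contamination thresholds
#'
#' @param tbc,cc Non-negative counts (cfu/ml), equal length.
#' @param rule A [threshold_rule()].
#' @return Data frame with logical columns `tbc_fail`, `cc_fail` and
#'   `either_fail` (`tbc_fail | cc_fail`).
#' @export
#' @examples
#' classify_failure(c(100000, 100001), c(10000, 10001))
classify_failure <- function(tbc, cc, rule = threshold_rule()) {
  if (length(tbc) != length(cc)) stop("`tbc` and `cc` must have equal length")
  if (any(tbc < 0, na.rm = TRUE) || any(cc < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  tbc_fail <- tbc > rule$tbc_threshold
  cc_fail <- cc > rule$cc_threshold
  data.frame(tbc_fail = tbc_fail, cc_fail = cc_fail,
             either_fail = tbc_fail | cc_fail)
}

#' Group summaries of contamination
#'
#' One row per level of the grouping variable: group size, mean and median
#' TBC and CC, percentage of samples above threshold for TBC, CC and either,
#' and the percentage of zero coliform counts. Percentages are reported to
#' one decimal place, rounding halves up; empty groups report `NA`
#' percentages.
#'
#' @param data Sample table with `tbc` and `cc` columns.
#' @param by Name of the grouping variable (default: the collection point).
#' @param rule A [threshold_rule()].
#' @return Data frame of class `group_summary`.
#' @export
summarize_by_group <- function(data, by = "collection_point",
                               rule = threshold_rule()) {
  if (!by %in% names(data)) stop("grouping variable `", by, "` not found")
  g <- data[[by]]
  levels_g <- if (is.factor(g)) levels(g) else sort(unique(as.character(g)))
  fails <- classify_failure(data$tbc, data$cc, rule)
  rows <- lapply(levels_g, function(lv) {
    i <- which(as.character(g) == lv)
    n <- length(i)
    data.frame(
      group = lv, n = n,
      mean_tbc = if (n) mean(data$tbc[i]) else NA_real_,
      median_tbc = if (n) stats::median(data$tbc[i]) else NA_real_,
      mean_cc = if (n) mean(data$cc[i]) else NA_real_,
      median_cc = if (n) stats::median(data$cc[i]) else NA_real_,
      pct_tbc_fail = .pct(sum(fails$tbc_fail[i]), n),
      pct_cc_fail = .pct(sum(fails$cc_fail[i]), n),
      pct_either_fail = .pct(sum(fails$either_fail[i]), n),
      pct_zero_cc = .pct(sum(data$cc[i] == 0), n),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Per-farm failure rates
#'
#' Percentage of each farm's samples failing the TBC, CC and either
#' threshold. The sample-count-weighted mean of the per-farm rates equals
#' the dataset-level failure rate.
#'
#' @param data Sample table with `farm_id`, `tbc` and `cc`.
#' @param rule A [threshold_rule()].
#' @return Data frame with one row per farm: `farm_id`, `n`,
#'   `pct_tbc_fail`, `pct_cc_fail`, `pct_either_fail`.
#' @export
farm_failure_rates <- function(data, rule = threshold_rule()) {
  fails <- classify_failure(data$tbc, data$cc, rule)
  farms <- unique(as.character(data$farm_id))
  rows <- lapply(farms, function(f) {
    i <- which(as.character(data$farm_id) == f)
    data.frame(farm_id = f, n = length(i),
               pct_tbc_fail = .pct(sum(fails$tbc_fail[i]), length(i)),
               pct_cc_fail = .pct(sum(fails$cc_fail[i]), length(i)),
               pct_either_fail = .pct(sum(fails$either_fail[i]), length(i)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
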