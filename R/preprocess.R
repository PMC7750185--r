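#' Log-transform a bacterial count
#'
#' Natural log transform after addition of 1, the outcome transform used for
#' both total bacterial counts and coliform counts: a zero count maps to a
#' zero log value and the transform is strictly increasing.
#'
#' @param count Numeric vector of counts (cfu/ml), all finite and `>= 0`.
#' @return `log(count + 1)`, natural-log cfu/ml.
#' @export
#' @examples
#' log_cfu(c(0, 99999))
log_cfu <- function(count) {
  if (!is.numeric(count)) stop("`count` must be numeric")
  if (any(!is.finite(count))) stop("`count` must be finite")
  if (any(count < 0)) stop("`count` must be non-negative")
  log1p(count)
}

#' Centre and scale a continuous variable
#'
#' Centres to mean zero and divides by one sample standard deviation
#' (denominator n − 1). The centre/scale pair is returned so the transform
#' can be inverted and reapplied to new data.
#'
#' @param x Numeric vector, length `>= 2`, finite, non-constant.
#' @param name Variable name used in error messages.
#' @return List with `values` (standardized vector), `mean` and `sd`.
#' @export
#' @examples
#' standardize_continuous(c(1, 2, 3))$values
standardize_continuous <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("`", name, "` must be a numeric vector of length >= 2")
  }
  if (any(!is.finite(x))) stop("`", name, "` contains non-finite values")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize constant variable `", name, "` (sd = 0)")
  list(values = (x - m) / s, mean = m, sd = s)
}

#' Invert a standardization
#'
#' @param z Standardized values.
#' @param mean,sd Centre and scale returned by [standardize_continuous()].
#' @return Values on the original measurement scale.
#' @export
unstandardize <- function(z, mean, sd) z * sd + mean

#' Recategorise cleaning-frequency levels
#'
#' Equipment-cleaning frequencies recorded as "Daily" or "Less than daily"
#' are collapsed into "Less than each use" so that frequency variables keep
#' as few relevant categories as possible; all other recognised levels pass
#' through unchanged.
#'
#' @param raw_level Character vector of raw frequency levels.
#' @return Character vector of canonical levels.
#' @export
#' @examples
#' relevel_frequency(c("Daily", "Each use"))
relevel_frequency <- function(raw_level) {
  known <- c("Each use", "Each calf", "Daily", "Less than daily",
             "Less than each use", "Less than each calf", "Not applicable")
  bad <- setdiff(unique(raw_level), known)
  if (length(bad)) {
    stop("unknown cleaning-frequency level(s): ",
         paste(shQuote(bad), collapse = ", "))
  }
  out <- raw_level
  out[out %in% c("Daily", "Less than daily")] <- "Less than each use"
  out
}

#' Enforce structural applicability
#'
#' Applies the questionnaire's applicability logic: for samples collected
#' directly from the cow's teat every milking-system, collection-equipment
#' and feeding-equipment variable is set to "Not applicable"; for samples
#' collected from the colostrum collection bucket the feeding-equipment
#' variables are set to "Not applicable". Other records are unchanged.
#'
#' @param data Data frame with a `collection_point` column and (a subset of)
#'   the schema's management variables.
#' @return The data frame with structural levels enforced.
#' @export
apply_structural_na <- function(data) {
  if (!"collection_point" %in% names(data)) {
    stop("`data` must contain a `collection_point` column")
  }
  for (rule in .colstab_schema$structural_rules) {
    hit <- data$collection_point == rule$when[["collection_point"]]
    hit[is.na(hit)] <- FALSE
    for (var in intersect(rule$set_not_applicable, names(data))) {
      if (is.factor(data[[var]])) {
        if (!"Not applicable" %in% levels(data[[var]])) {
          levels(data[[var]]) <- c(levels(data[[var]]), "Not applicable")
        }
      }
      data[[var]][hit] <- "Not applicable"
    }
  }
  data
}

#' Remove incomplete records
#'
#' Applies named exclusion rules in order, tallying how many records each
#' rule removes; a record is counted against the first rule it fails. The
#' defaults mirror a typical submission workflow: samples with no laboratory
#' result (missing or damaged in transit) and samples with missing or
#' incomplete collection data.
#'
#' @param data Per-sample data frame.
#' @param rules Named list of functions; each takes the data frame and
#'   returns a logical vector marking records to drop.
#' @return List with `data` (the retained records) and `report`, a
#'   `preprocess_report` with `n_received`, `n_removed`, `n_final` and the
#'   per-rule exclusion counts.
#' @export
filter_complete <- function(data, rules = default_exclusion_rules()) {
  stopifnot(is.data.frame(data), is.list(rules))
  n_received <- nrow(data)
  removed <- integer(length(rules))
  names(removed) <- names(rules)
  keep <- rep(TRUE, n_received)
  for (r in seq_along(rules)) {
    drop <- rules[[r]](data)
    if (!is.logical(drop) || length(drop) != n_received) {
      stop("rule `", names(rules)[r], "` must return one logical per record")
    }
    drop[is.na(drop)] <- TRUE
    drop <- drop & keep          # only count records not already excluded
    removed[r] <- sum(drop)
    keep <- keep & !drop
  }
  report <- structure(
    list(n_received = n_received,
         n_removed = sum(removed),
         n_final = sum(keep),
         removed_by_rule = as.list(removed)),
    class = "preprocess_report")
  list(data = data[keep, , drop = FALSE], report = report)
}

#' Default exclusion rules
#'
#' @return Named list of rule functions for [filter_complete()].
#' @export
default_exclusion_rules <- function() {
  covars <- candidate_terms()
  list(
    missing_or_damaged = function(d) {
      out <- rep(FALSE, nrow(d))
      for (col in c("tbc", "cc")) if (col %in% names(d)) out <- out | is.na(d[[col]])
      out
    },
    incomplete_collection_data = function(d) {
      out <- rep(FALSE, nrow(d))
      for (col in intersect(covars, names(d))) out <- out | is.na(d[[col]])
      if ("farm_id" %in% names(d)) out <- out | is.na(d$farm_id)
      out
    }
  )
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat("  records received:", x$n_received, "\n")
  for (nm in names(x$removed_by_rule)) {
    cat("  removed (", nm, "): ", x$removed_by_rule[[nm]], "\n", sep = "")
  }
  cat("  final records:   ", x$n_final, "\n")
  invisible(x)
}

#' Validate a colostrum sample table against the schema
#'
#' @param data Data frame to check.
#' @return Character vector of problems (empty when valid).
#' @export
validate_colostrum <- function(data) {
  problems <- character()
  if (!"farm_id" %in% names(data)) problems <- c(problems, "missing column `farm_id`")
  for (var in intersect(.categorical_vars(), names(data))) {
    vals <- as.character(data[[var]])
    bad <- setdiff(unique(vals[!is.na(vals)]), .schema_levels(var))
    if (length(bad)) {
      problems <- c(problems, paste0("`", var, "` has values outside its level set: ",
                                     paste(shQuote(bad), collapse = ", ")))
    }
  }
  for (col in c("tbc", "cc")) {
    if (col %in% names(data)) {
      v <- data[[col]]
      if (any(v < 0, na.rm = TRUE)) {
        problems <- c(problems, paste0("`", col, "` has negative counts"))
      }
    }
  }
  for (rule in .colstab_schema$structural_rules) {
    if (!"collection_point" %in% names(data)) break
    hit <- data$collection_point == rule$when[["collection_point"]]
    hit[is.na(hit)] <- FALSE
    for (var in intersect(rule$set_not_applicable, names(data))) {
      off <- hit & !is.na(data[[var]]) & data[[var]] != "Not applicable"
      if (any(off)) {
        problems <- c(problems, paste0(
          "`", var, "` must be \"Not applicable\" when collection_point is \"",
          rule$when[["collection_point"]], "\" (", sum(off), " record(s))"))
      }
    }
  }
  problems
}

#' Read a colostrum sample CSV
#'
#' Reads the canonical comma-separated sample table (UTF-8, header row with
#' snake_case column names as in [colostrum_schema()]), coerces categorical
#' columns to schema factors with the reference level first, validates level
#' vocabularies and structural applicability, and derives `log_tbc` and
#' `log_cc` when absent. Unknown columns are preserved but ignored by the
#' modelling functions.
#'
#' @param path Path to the CSV file.
#' @param validate Error on schema violations? Default `TRUE`.
#' @return A data frame.
#' @export
read_colostrum_csv <- function(path, validate = TRUE) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (validate) {
    problems <- validate_colostrum(data)
    if (length(problems)) {
      stop("invalid colostrum table:\n  ", paste(problems, collapse = "\n  "))
    }
  }
  as_colostrum_data(data)
}

#' Coerce a data frame to the canonical sample-table representation
#'
#' @param data Data frame with schema columns.
#' @return Data frame with schema factors and derived log outcomes.
#' @export
as_colostrum_data <- function(data) {
  for (var in intersect(.categorical_vars(), names(data))) {
    data[[var]] <- factor(as.character(data[[var]]), levels = .schema_levels(var))
  }
  if ("tbc" %in% names(data) && is.null(data$log_tbc)) {
    ok <- !is.na(data$tbc)
    data$log_tbc <- NA_real_
    data$log_tbc[ok] <- log_cfu(data$tbc[ok])
  }
  if ("cc" %in% names(data) && is.null(data$log_cc)) {
    ok <- !is.na(data$cc)
    data$log_cc <- NA_real_
    data$log_cc[ok] <- log_cfu(data$cc[ok])
  }
  data
}

#' Write a colostrum sample CSV
#'
#' @param data Sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colostrum_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Standardize the continuous model covariates of a dataset
#'
#' Centres and scales each continuous covariate once on the full analysis
#' dataset; the parameters are stored as the `"standardization"` attribute
#' and the same transform is reused unchanged inside every bootstrap
#' replicate (scaling happens prior to modelling, before any resampling).
#' Calling it twice is a no-op.
#'
#' @param data Sample table.
#' @param vars Continuous variables to standardize (default: the schema's).
#' @return The data frame with standardized columns.
#' @export
standardize_dataset <- function(data, vars = .continuous_vars()) {
  std <- attr(data, "standardization")
  if (is.null(std)) std <- list()
  for (var in intersect(vars, names(data))) {
    if (!is.null(std[[var]])) next
    s <- standardize_continuous(data[[var]], name = var)
    data[[var]] <- s$values
    std[[var]] <- list(mean = s$mean, sd = s$sd)
  }
  attr(data, "standardization") <- std
  data
}
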