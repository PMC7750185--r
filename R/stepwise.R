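#' Backward elimination of fixed-effect terms by AIC
#'
#' Greedy whole-term backward selection on the random-intercept model: fit
#' the current model, refit it once per remaining candidate with that term
#' removed, and commit the single deletion that most lowers the AIC;
#' repeat until no deletion strictly lowers it. Categorical terms leave as a
#' whole block of indicator columns, never level by level, and the farm
#' random intercept is never a deletion candidate. When two deletions tie
#' within `1e-9` AIC units the term later in the declared candidate order is
#' dropped, which makes the path deterministic.
#'
#' Candidate terms with no variation in `data` (for bootstrap resamples: a
#' factor collapsed to a single observed level) are not selectable and are
#' recorded in `unestimable`. Aliased design columns are dropped with a
#' record; their coefficients are absent, not zero.
#'
#' @param data Per-sample data frame.
#' @param outcome Name of the (log-scale) outcome column.
#' @param terms Character vector of candidate fixed-effect terms, in the
#'   declared order used for tie-breaking.
#' @param group Clustering column, default `"farm_id"`.
#' @return Object of class `aic_step`: `final_terms`, `path` (data frame of
#'   committed deletions with the AIC before and after each), `fit` (final
#'   model record with coefficients, variances, log-likelihood, AIC),
#'   `full_aic`, `unestimable`, `candidates`.
#' @export
#' @examples
#' d <- simulate_colostrum(n_farms = 12, seed = 42)
#' st <- backward_aic(d, "log_tbc", c("feeding_hot_water", "teat_dry_wiped"))
#' st$final_terms
backward_aic <- function(data, outcome, terms, group = "farm_id") {
  design <- .make_design(data, outcome, terms, group)
  current <- design$terms              # usable candidates, declared order
  fit <- .fit_design(design, current)
  if (!isTRUE(fit$converged)) stop("full-model fit did not converge")
  full_aic <- fit$aic
  path <- list()

  repeat {
    if (!length(current)) break
    best_term <- NULL
    best_aic <- Inf
    # scan in declared order; a candidate whose AIC ties the incumbent
    # within 1e-9 replaces it, so the term later in the candidate order is
    # the one dropped on ties
    for (i in seq_along(current)) {
      f_i <- tryCatch(.fit_design(design, setdiff(current, current[i])),
                      error = function(e) NULL)
      if (is.null(f_i) || !isTRUE(f_i$converged)) next  # deletion unavailable
      if (f_i$aic <= best_aic + 1e-9) {
        best_term <- current[i]
        best_aic <- min(best_aic, f_i$aic)
        best_fit <- f_i
      }
    }
    if (is.null(best_term) || !(best_aic < fit$aic)) break
    path[[length(path) + 1L]] <- data.frame(
      dropped = best_term, aic_before = fit$aic, aic_after = best_aic,
      stringsAsFactors = FALSE)
    current <- setdiff(current, best_term)
    fit <- best_fit
  }

  structure(
    list(final_terms = current,
         path = if (length(path)) do.call(rbind, path) else
           data.frame(dropped = character(), aic_before = numeric(),
                      aic_after = numeric(), stringsAsFactors = FALSE),
         fit = fit, full_aic = full_aic,
         unestimable = design$unusable, candidates = terms,
         outcome = outcome, group = group),
    class = "aic_step")
}

#' @export
print.aic_step <- function(x, ...) {
  cat("AIC backward elimination (", x$outcome, ")\n", sep = "")
  cat("  candidates:", length(x$candidates),
      " retained:", length(x$final_terms), "\n")
  if (nrow(x$path)) {
    cat("  elimination path:\n")
    for (i in seq_len(nrow(x$path))) {
      cat(sprintf("    -%s  (AIC %.2f -> %.2f)\n", x$path$dropped[i],
                  x$path$aic_before[i], x$path$aic_after[i]))
    }
  } else cat("  no deletion lowered the AIC\n")
  cat("  final AIC:", format(x$fit$aic, digits = 7), "\n")
  if (length(x$unestimable)) {
    cat("  unestimable terms:", paste(x$unestimable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Record the selection outcome of a stepwise run
#'
#' @param step_result An [backward_aic()] result.
#' @return List with `selected` (named logical over the candidate terms) and
#'   `coefficients` (data frame `term`, `column`, `estimate`: one row per
#'   estimated non-reference design column of each selected term; aliased or
#'   empty columns are absent, not zero).
#' @export
record_selection <- function(step_result) {
  stopifnot(inherits(step_result, "aic_step"))
  fit <- step_result$fit
  selected <- stats::setNames(
    step_result$candidates %in% step_result$final_terms,
    step_result$candidates)
  cols <- names(fit$beta)
  term_of <- .column_term(cols, step_result$final_terms)
  keep <- !is.na(term_of)
  list(selected = selected,
       coefficients = data.frame(term = term_of[keep], column = cols[keep],
                                 estimate = unname(fit$beta[keep]),
                                 stringsAsFactors = FALSE))
}

# Map model-matrix column names back to their source term: columns are named
# `<term><level>` for factors and `<term>` for continuous terms. The longest
# matching term wins so that e.g. `collection_hot_waterYes` resolves
# correctly even though another term is its prefix.
.column_term <- function(columns, terms) {
  out <- rep(NA_character_, length(columns))
  ord <- terms[order(nchar(terms), decreasing = TRUE)]
  for (i in seq_along(columns)) {
    if (columns[i] == "(Intercept)") next
    for (t in ord) {
      if (startsWith(columns[i], t)) { out[i] <- t; break }
    }
  }
  out
}
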