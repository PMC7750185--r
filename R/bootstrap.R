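# Bootstrap stability selection: resample the sample table with replacement,
# run AIC backward elimination on every resample, and summarise per variable
# how often it survives (stability), the mean coefficient over the selecting
# replicates, the 2.5th/97.5th percentile bootstrap confidence interval and
# a bootstrap p-value.

#' One bootstrap replicate of the stepwise model build
#'
#' Draws a resample of the same size as the original dataset (record-level
#' with replacement by default; farm-level cluster resampling as an option),
#' runs [backward_aic()] on it and records which terms were selected with
#' their per-level coefficients. A resample with fewer than two distinct
#' farms is redrawn from the next substream seed (logged in `n_redraws`);
#' after 20 failed attempts the replicate is marked non-converged.
#'
#' @param data Per-sample data frame.
#' @param outcome Log-scale outcome column name.
#' @param terms Candidate terms in declared order.
#' @param replicate_seed Integer seed driving this replicate's resample.
#' @param group Clustering column, default `"farm_id"`.
#' @param mode `"record"` (default; the resample has exactly `nrow(data)`
#'   records) or `"farm"` (cluster bootstrap: farms drawn with replacement).
#' @return List of class `replicate_result`: `seed`, `selected` (character
#'   vector of selected terms), `coefficients` (data frame `term`, `column`,
#'   `estimate`), `converged`, `n_redraws`, `n_resample`.
#' @export
bootstrap_replicate <- function(data, outcome, terms, replicate_seed,
                                group = "farm_id",
                                mode = c("record", "farm")) {
  mode <- match.arg(mode)
  n <- nrow(data)
  farms <- as.character(data[[group]])
  idx <- NULL
  n_redraws <- 0L
  for (attempt in 0:20) {
    seed_used <- (replicate_seed + attempt * 1000003L) %% .Machine$integer.max
    set.seed(seed_used)
    cand <- if (mode == "record") {
      sample.int(n, n, replace = TRUE)
    } else {
      uf <- unique(farms)
      picked <- sample(uf, length(uf), replace = TRUE)
      unlist(lapply(picked, function(f) which(farms == f)), use.names = FALSE)
    }
    if (length(unique(farms[cand])) >= 2L) { idx <- cand; break }
    n_redraws <- n_redraws + 1L
  }
  if (is.null(idx)) {
    return(structure(list(seed = replicate_seed, selected = character(),
                          coefficients = data.frame(term = character(),
                                                    column = character(),
                                                    estimate = numeric(),
                                                    stringsAsFactors = FALSE),
                          converged = FALSE, n_redraws = n_redraws,
                          n_resample = 0L),
                     class = "replicate_result"))
  }
  resample <- droplevels(data[idx, , drop = FALSE])
  st <- tryCatch(backward_aic(resample, outcome, terms, group),
                 error = function(e) NULL)
  if (is.null(st)) {
    return(structure(list(seed = replicate_seed, selected = character(),
                          coefficients = data.frame(term = character(),
                                                    column = character(),
                                                    estimate = numeric(),
                                                    stringsAsFactors = FALSE),
                          converged = FALSE, n_redraws = n_redraws,
                          n_resample = length(idx)),
                     class = "replicate_result"))
  }
  rec <- record_selection(st)
  structure(list(seed = replicate_seed,
                 selected = names(rec$selected)[rec$selected],
                 coefficients = rec$coefficients,
                 converged = TRUE, n_redraws = n_redraws,
                 n_resample = length(idx)),
            class = "replicate_result")
}

#' Run the bootstrap replicates
#'
#' Repeats [bootstrap_replicate()] `B` times with independent substream
#' seeds derived from `master_seed`; downstream summaries are invariant to
#' replicate order.
#'
#' @inheritParams bootstrap_replicate
#' @param B Number of replicates (default 1000).
#' @param master_seed Integer master seed.
#' @return List of `replicate_result` objects.
#' @export
run_stability <- function(data, outcome, terms, B = 1000, master_seed = 1,
                          group = "farm_id", mode = c("record", "farm")) {
  stopifnot(B >= 1)
  mode <- match.arg(mode)
  set.seed(master_seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  lapply(rep_seeds, function(s) {
    bootstrap_replicate(data, outcome, terms, s, group = group, mode = mode)
  })
}

#' Selection stability of a term
#'
#' Percentage of bootstrap replicates in which the term survived backward
#' elimination. The denominator is all `B` replicates, including any
#' non-converged ones.
#'
#' @param replicates List of `replicate_result`s.
#' @param term A candidate term name.
#' @param candidates Candidate set used for validation (default: inferred
#'   union over replicates plus selected terms).
#' @return Stability percentage in `[0, 100]`.
#' @export
stability_pct <- function(replicates, term, candidates = NULL) {
  if (is.null(candidates)) candidates <- attr(replicates, "candidates")
  if (!is.null(candidates) && !term %in% candidates) {
    stop("unknown term `", term, "`")
  }
  100 * mean(vapply(replicates, function(r) term %in% r$selected, logical(1)))
}

#' Mean coefficient and percentile bootstrap confidence interval
#'
#' Computed over only the replicates in which the level's term was selected
#' and the level's coefficient was estimable. The 2.5th and 97.5th
#' percentiles use the linear-interpolation quantile rule
#' (`stats::quantile` type 7).
#'
#' @param replicates List of `replicate_result`s.
#' @param column Design-column name (variable + level).
#' @return List `mean_coef`, `bci_low`, `bci_high`, `n_selected`, or `NULL`
#'   when the level was never selected (an absent row, not zeros).
#' @export
summarize_coefficients <- function(replicates, column) {
  vals <- unlist(lapply(replicates, function(r) {
    i <- which(r$coefficients$column == column)
    if (length(i)) r$coefficients$estimate[i] else NULL
  }), use.names = FALSE)
  if (!length(vals)) return(NULL)
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean_coef = mean(vals), bci_low = q[1], bci_high = q[2],
       n_selected = length(vals))
}

#' Bootstrap p-value
#'
#' One minus the proportion of coefficient estimates on the majority side of
#' zero: the proportion on the minority side, with exact zeros counted
#' toward the minority (conservative) and an even split giving 0.5.
#'
#' @param coefficients Numeric vector of selected-replicate coefficients
#'   (length >= 1).
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' bootstrap_p(c(3, 1, 2, -1))  # 0.25
bootstrap_p <- function(coefficients) {
  if (!length(coefficients)) stop("at least one coefficient is required")
  n <- length(coefficients)
  pos <- sum(coefficients > 0)
  neg <- sum(coefficients < 0)
  1 - max(pos, neg) / n
}

#' Bootstrapped stability selection for colostrum contamination models
#'
#' The package's core estimator. Standardizes the continuous covariates once
#' on the full analysis dataset, then draws `B` bootstrap resamples of the
#' sample table, runs AIC backward elimination of the candidate management
#' terms on each (farm always retained as the random intercept), and
#' summarises, per variable level: the descriptive sample count, selection
#' stability (%), mean coefficient (log cfu/ml), 95% percentile bootstrap
#' confidence interval and bootstrap p-value. Stability and the p-values'
#' selection denominator are shared across all levels of a categorical term;
#' coefficients differ by level.
#'
#' @param data Per-sample data frame (complete cases; see
#'   [filter_complete()]).
#' @param outcome `"log_tbc"` or `"log_cc"` (any numeric column is
#'   accepted).
#' @param terms Candidate fixed-effect terms in declared order (default:
#'   the thirteen schema variables).
#' @param B Number of bootstrap replicates, default 1000.
#' @param seed Master seed driving all resampling.
#' @param group Clustering column, default `"farm_id"`.
#' @param mode `"record"` (default) or `"farm"` cluster bootstrap.
#' @param standardize Standardize continuous candidate terms on the full
#'   dataset before resampling? Default `TRUE`; a no-op if already done.
#' @return Object of class `colstab` with elements `summary` (the per-level
#'   stability table), `replicates`, `archive` (long-format replicate
#'   records), `term_stability`, `B`, `seed`, `n_nonconverged`, plus
#'   `print`, `summary` and `plot` methods.
#' @seealso [select_influential()], [plot_stability_vs_p()]
#' @export
boot_stability <- function(data, outcome = "log_tbc", terms = candidate_terms(),
                           B = 1000, seed = 1, group = "farm_id",
                           mode = c("record", "farm"), standardize = TRUE) {
  mode <- match.arg(mode)
  terms <- intersect(terms, names(data))
  if (!length(terms)) stop("no candidate terms present in `data`")
  if (standardize) data <- standardize_dataset(data, intersect(terms, .continuous_vars()))
  replicates <- run_stability(data, outcome, terms, B = B, master_seed = seed,
                              group = group, mode = mode)
  attr(replicates, "candidates") <- terms

  n_nonconv <- sum(!vapply(replicates, `[[`, logical(1), "converged"))

  # map every possible design column of the full data to its variable/level
  full_design <- .make_design(data, outcome, terms, group)
  cols <- colnames(full_design$X)
  col_term <- .column_term(cols, full_design$terms)
  rows <- list()
  for (term in terms) {
    stab <- stability_pct(replicates, term, candidates = terms)
    term_cols <- cols[!is.na(col_term) & col_term == term]
    for (cn in term_cols) {
      cs <- summarize_coefficients(replicates, cn)
      if (is.null(cs)) next   # never selected/estimable: absent row
      level <- if (cn == term) NA_character_ else sub(term, "", cn, fixed = TRUE)
      coefs <- unlist(lapply(replicates, function(r) {
        i <- which(r$coefficients$column == cn)
        if (length(i)) r$coefficients$estimate[i] else NULL
      }), use.names = FALSE)
      n_level <- if (is.na(level)) nrow(data) else
        sum(as.character(data[[term]]) == level)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, level = level, column = cn, n = n_level,
        stability = stab, n_selected = cs$n_selected,
        mean_coef = cs$mean_coef, bci_low = cs$bci_low,
        bci_high = cs$bci_high, boot_p = bootstrap_p(coefs),
        stringsAsFactors = FALSE)
    }
  }
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), level = character(), column = character(),
               n = integer(), stability = numeric(), n_selected = integer(),
               mean_coef = numeric(), bci_low = numeric(),
               bci_high = numeric(), boot_p = numeric(),
               stringsAsFactors = FALSE)
  term_stab <- vapply(terms, function(t) stability_pct(replicates, t, terms),
                      numeric(1))

  archive <- do.call(rbind, lapply(seq_along(replicates), function(b) {
    r <- replicates[[b]]
    if (nrow(r$coefficients)) {
      data.frame(replicate = b, seed = r$seed, term = r$coefficients$term,
                 column = r$coefficients$column,
                 estimate = r$coefficients$estimate,
                 converged = r$converged, stringsAsFactors = FALSE)
    } else {
      data.frame(replicate = b, seed = r$seed, term = NA_character_,
                 column = NA_character_, estimate = NA_real_,
                 converged = r$converged, stringsAsFactors = FALSE)
    }
  }))

  structure(list(summary = summary_df, term_stability = term_stab,
                 replicates = replicates, archive = archive,
                 outcome = outcome, terms = terms, B = B, seed = seed,
                 mode = mode, group = group,
                 n = nrow(data), n_farms = length(unique(data[[group]])),
                 n_nonconverged = n_nonconv,
                 standardization = attr(data, "standardization"),
                 call = match.call()),
            class = "colstab")
}

#' Filter the stability table to the influential variables
#'
#' Keeps the terms that are both relatively stable and of reasonable effect
#' size: selection stability strictly above `stability_min` percent and a
#' bootstrap p-value strictly below `p_max` for at least one of the term's
#' levels. All levels of a kept term are kept together.
#'
#' @param rows Stability summary data frame (from `fit$summary`) or a
#'   `colstab` object.
#' @param stability_min Stability threshold (%), default 10.
#' @param p_max Bootstrap p-value threshold, default 0.025.
#' @return The filtered summary rows.
#' @export
select_influential <- function(rows, stability_min = 10, p_max = 0.025) {
  if (inherits(rows, "colstab")) rows <- rows$summary
  if (!nrow(rows)) return(rows)
  keep_term <- vapply(split(rows, rows$term), function(d) {
    d$stability[1] > stability_min && any(d$boot_p < p_max)
  }, logical(1))
  kept <- names(keep_term)[keep_term]
  out <- rows[rows$term %in% kept, , drop = FALSE]
  out[order(-out$stability, out$term), , drop = FALSE]
}

#' @export
print.colstab <- function(x, ...) {
  cat("Bootstrap stability selection (", x$outcome, ")\n", sep = "")
  cat("  ", x$B, " replicates (", x$mode, " resampling), ",
      x$n, " samples on ", x$n_farms, " farms\n", sep = "")
  if (x$n_nonconverged) {
    cat("  non-converged replicates:", x$n_nonconverged, "\n")
  }
  cat("\n")
  print(summary(x), ...)
  invisible(x)
}

#' Display-formatted stability table
#'
#' The per-level summary with the display precision of the reported tables:
#' stability to one decimal, coefficients and interval endpoints to two.
#'
#' @param object A `colstab` fit.
#' @param ... Unused.
#' @return Data frame with columns `variable`, `n`, `stability`,
#'   `mean_coefficient`, `bci_95` and `bootstrap_p`.
#' @export
summary.colstab <- function(object, ...) {
  s <- object$summary
  if (!nrow(s)) {
    return(data.frame(variable = character(), n = integer(),
                      stability = numeric(), mean_coefficient = numeric(),
                      bci_95 = character(), bootstrap_p = character(),
                      stringsAsFactors = FALSE))
  }
  s <- s[order(-s$stability, s$term, s$column), , drop = FALSE]
  lab <- ifelse(is.na(s$level), s$term, paste0(s$term, ": ", s$level))
  data.frame(
    variable = lab,
    n = s$n,
    stability = round_half_up(s$stability, 1),
    mean_coefficient = round_half_up(s$mean_coef, 2),
    bci_95 = sprintf("(%.2f to %.2f)", round_half_up(s$bci_low, 2),
                     round_half_up(s$bci_high, 2)),
    bootstrap_p = ifelse(s$boot_p < 0.01, "<0.01", sprintf("%.2f", s$boot_p)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Coefficient-distribution plot
#'
#' One horizontal strip of replicate coefficients per selected variable
#' level, label carrying the selection stability within brackets, and a
#' vertical reference line at zero.
#'
#' @param x A `colstab` fit.
#' @param stability_min Only levels of terms above this stability (%) are
#'   drawn, default 10.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly. Warns and draws an empty frame when nothing is
#'   selected.
#' @export
plot.colstab <- function(x, stability_min = 10, ...) {
  s <- x$summary[x$summary$stability > stability_min, , drop = FALSE]
  if (!nrow(s)) {
    warning("no terms above ", stability_min, "% stability; empty plot")
    plot(0, 0, type = "n", xlab = "coefficient (log cfu/ml)", ylab = "",
         axes = FALSE, ...)
    return(invisible(x))
  }
  s <- s[order(s$stability, s$term, s$column), , drop = FALSE]
  labels <- sprintf("%s (%s%%)",
                    ifelse(is.na(s$level), s$term,
                           paste0(s$term, ": ", s$level)),
                    formatC(round_half_up(s$stability, 1), format = "fg"))
  vals <- lapply(s$column, function(cn) {
    x$archive$estimate[!is.na(x$archive$column) & x$archive$column == cn]
  })
  xlim <- range(c(0, unlist(vals)), finite = TRUE)
  old <- graphics::par(mar = c(4.5, 14, 2, 1))
  on.exit(graphics::par(old))
  plot(NA, xlim = xlim, ylim = c(0.5, nrow(s) + 0.5),
       xlab = "coefficient (log cfu/ml)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(s)), labels = labels, las = 1,
                 cex.axis = 0.7)
  graphics::abline(v = 0, lty = 1, col = "grey40")
  for (i in seq_len(nrow(s))) {
    v <- vals[[i]]
    graphics::points(v, jitter(rep(i, length(v)), amount = 0.18),
                     pch = 16, cex = 0.3,
                     col = grDevices::adjustcolor("steelblue", 0.35))
    graphics::points(s$mean_coef[i], i, pch = 18, cex = 1.1, col = "black")
  }
  invisible(x)
}

#' Stability against bootstrap p-value
#'
#' Scatter of each variable's bootstrap p-value against its selection
#' stability, with a dashed vertical line at the stability threshold and a
#' dotted horizontal line at the p-value threshold; the selected quadrant is
#' bottom-right.
#'
#' @param x A `colstab` fit or its summary data frame.
#' @param stability_min,p_max Threshold lines (defaults 10 and 0.025).
#' @param ... Passed to [graphics::plot()].
#' @return The plotted data frame (one row per term), invisibly.
#' @export
plot_stability_vs_p <- function(x, stability_min = 10, p_max = 0.025, ...) {
  s <- if (inherits(x, "colstab")) x$summary else x
  if (!nrow(s)) stop("empty stability summary")
  per_term <- do.call(rbind, lapply(split(s, s$term), function(d) {
    data.frame(term = d$term[1], stability = d$stability[1],
               boot_p = min(d$boot_p), stringsAsFactors = FALSE)
  }))
  plot(per_term$stability, per_term$boot_p,
       xlab = "stability (%)", ylab = "bootstrap p-value",
       pch = 16, xlim = c(0, 100), ylim = c(0, max(0.5, per_term$boot_p)), ...)
  graphics::abline(v = stability_min, lty = 2)
  graphics::abline(h = p_max, lty = 3)
  graphics::text(per_term$stability, per_term$boot_p, per_term$term,
                 pos = 4, cex = 0.6, xpd = NA)
  invisible(per_term)
}
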