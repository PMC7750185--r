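# Model-checking utilities for the full (non-bootstrapped) model: repeated
# k-fold cross-validation, a predictor correlation screen, likelihood-ratio
# interaction screening, and a conventional detectable-difference power
# calculation.

#' Repeated k-fold cross-validation of the full model
#'
#' Record-level folds: per repeat, every record is assigned to exactly one
#' of `k` folds; the model is refitted on the training folds and the
#' held-out records are predicted with the fixed effects plus the farm
#' intercept of farms present in training (zero for unseen farms). Internal
#' metrics come from the full-data fit. R-squared is `1 - SSE/SST` on the
#' assessed records (it can be negative for a badly overfit model); MAE is
#' on the log cfu/ml scale.
#'
#' @param data Per-sample data frame.
#' @param outcome Log-scale outcome column.
#' @param terms Fixed-effect terms of the full model.
#' @param group Clustering column, default `"farm_id"`.
#' @param k Number of folds, default 10 (must not exceed `nrow(data)`).
#' @param repeats Number of repeats, default 10.
#' @param seed Seed for the fold assignments.
#' @return List of class `cv_result`: `internal_r2`, `cv_r2`,
#'   `internal_mae`, `cv_mae`, `per_repeat` (data frame), `k`, `repeats`,
#'   `seed`.
#' @export
repeated_kfold_cv <- function(data, outcome, terms, group = "farm_id",
                              k = 10, repeats = 10, seed = 1) {
  n <- nrow(data)
  if (k > n) stop("`k` (", k, ") exceeds the number of records (", n, ")")
  if (k < 2) stop("`k` must be at least 2")
  data <- standardize_dataset(data, intersect(terms, .continuous_vars()))
  design <- .make_design(data, outcome, terms, group)
  y <- design$y
  full <- .fit_design(design, design$terms)
  fitted_full <- full$fitted            # includes the farm intercepts
  internal_r2 <- 1 - sum((y - fitted_full)^2) / sum((y - mean(y))^2)
  internal_mae <- mean(abs(y - fitted_full))

  gi <- as.integer(design$g)
  set.seed(seed)
  per_repeat <- lapply(seq_len(repeats), function(r) {
    fold <- sample(rep_len(seq_len(k), n))
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- fold == f
      Xtr <- design$X[!test, , drop = FALSE]
      # refit on the training folds only; aliased columns re-evaluated there
      q <- qr(Xtr)
      keep <- sort(q$pivot[seq_len(q$rank)])
      gtr <- droplevels(design$g[!test])
      fit <- .lmm_profile_fit(Xtr[, keep, drop = FALSE], y[!test], gtr)
      if (!isTRUE(fit$converged)) stop("cross-validation fold fit failed")
      fixed <- drop(design$X[test, keep, drop = FALSE] %*% fit$beta)
      u <- fit$u[as.character(design$g[test])]
      u[is.na(u)] <- 0
      pred[test] <- fixed + unname(u)
    }
    c(r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
      mae = mean(abs(y - pred)))
  })
  per_repeat <- as.data.frame(do.call(rbind, per_repeat))
  structure(list(internal_r2 = internal_r2, internal_mae = internal_mae,
                 cv_r2 = mean(per_repeat$r2), cv_mae = mean(per_repeat$mae),
                 per_repeat = per_repeat, k = k, repeats = repeats,
                 seed = seed, n = n),
            class = "cv_result")
}

#' @rdname repeated_kfold_cv
#' @export
cv_lmm <- repeated_kfold_cv

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat("Repeated ", x$k, "-fold cross-validation (", x$repeats,
      " repeats, n = ", x$n, ")\n", sep = "")
  cat("  internal R2:", format(x$internal_r2, digits = digits),
      " MAE:", format(x$internal_mae, digits = digits), "\n")
  cat("  cross-val R2:", format(x$cv_r2, digits = digits),
      " MAE:", format(x$cv_mae, digits = digits), "\n")
  invisible(x)
}

#' Predictor correlation screen
#'
#' Pearson correlations over the numeric design encoding of the candidate
#' predictors (indicator columns for non-reference factor levels,
#' standardized continuous variables) and the maximum absolute off-diagonal
#' correlation across distinct variables.
#'
#' @param data Per-sample data frame.
#' @param terms Predictors to screen (default: the schema variables present).
#' @return List with `correlations` (matrix), `max_abs` (across distinct
#'   variables) and `pairs` (data frame of cross-variable column pairs
#'   ordered by absolute correlation).
#' @export
predictor_correlations <- function(data, terms = intersect(candidate_terms(),
                                                           names(data))) {
  if (length(terms) < 2) stop("at least 2 predictors are required")
  data <- droplevels(standardize_dataset(data,
                                         intersect(terms, .continuous_vars())))
  f <- stats::reformulate(terms)
  X <- stats::model.matrix(f, data)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(f), "term.labels")
  X <- X[, assign > 0L, drop = FALSE]
  col_term <- labels[assign[assign > 0L]]
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  col_term <- col_term[keep]
  cors <- stats::cor(X)
  cross <- outer(col_term, col_term, "!=")
  off <- abs(cors) * cross
  diag(off) <- 0
  idx <- which(upper.tri(cors) & cross, arr.ind = TRUE)
  pairs <- data.frame(col_a = colnames(cors)[idx[, 1]],
                      col_b = colnames(cors)[idx[, 2]],
                      correlation = cors[idx], stringsAsFactors = FALSE)
  pairs <- pairs[order(-abs(pairs$correlation)), , drop = FALSE]
  rownames(pairs) <- NULL
  list(correlations = cors, max_abs = max(off), pairs = pairs)
}

#' Likelihood-ratio screen for pairwise interactions
#'
#' For each pair of the given terms, compares the model holding all the
#' terms with the same model plus the pairwise interaction, by a
#' maximum-likelihood likelihood-ratio test against a chi-square reference
#' with degrees of freedom equal to the number of (estimable) added design
#' columns. Pairs whose interaction adds no estimable column are skipped and
#' reported.
#'
#' @param data Per-sample data frame.
#' @param outcome Log-scale outcome column.
#' @param terms Selected terms (length >= 1; a single term yields an empty
#'   screen).
#' @param group Clustering column, default `"farm_id"`.
#' @param alpha Significance threshold, default 0.05.
#' @return Data frame with one row per testable pair: `term_a`, `term_b`,
#'   `df`, `chisq`, `p_value`, `significant`; skipped pairs carry `NA`
#'   statistics.
#' @export
interaction_screen <- function(data, outcome, terms, group = "farm_id",
                               alpha = 0.05) {
  data <- standardize_dataset(data, intersect(terms, .continuous_vars()))
  out <- list()
  if (length(terms) < 2) {
    return(data.frame(term_a = character(), term_b = character(),
                      df = integer(), chisq = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  base_design <- .make_design(data, outcome, terms, group)
  base_fit <- .fit_design(base_design, base_design$terms)
  combs <- utils::combn(terms, 2)
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    inter <- paste0(a, ":", b)
    row <- data.frame(term_a = a, term_b = b, df = NA_integer_,
                      chisq = NA_real_, p_value = NA_real_,
                      significant = NA, stringsAsFactors = FALSE)
    fit_i <- tryCatch({
      d_i <- .make_design(data, outcome, c(terms, inter), group)
      .fit_design(d_i, d_i$terms)
    }, error = function(e) NULL)
    if (!is.null(fit_i) && isTRUE(fit_i$converged)) {
      df <- fit_i$p - base_fit$p
      if (df >= 1) {
        chisq <- max(0, 2 * (fit_i$loglik - base_fit$loglik))
        p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
        row$df <- df; row$chisq <- chisq; row$p_value <- p
        row$significant <- p < alpha
      }
    }
    out[[j]] <- row
  }
  do.call(rbind, out)
}

#' Power to detect a shift in log bacterial count
#'
#' Conventional two-sample normal-approximation power for detecting a mean
#' difference `delta` (log cfu/ml) between two equal groups of `total_n / 2`
#' samples each, at a two-sided significance level `alpha`:
#' `power = pnorm(|delta| / (sd * sqrt(2 / (total_n / 2))) - z_{1 - alpha/2})`.
#' At `delta = 0` this one-tail approximation returns `alpha / 2`.
#'
#' @param sd Outcome standard deviation (log cfu/ml), > 0.
#' @param delta Detectable difference (log cfu/ml).
#' @param total_n Total sample size (equal allocation), >= 4.
#' @param alpha Two-sided significance level in (0, 1), default 0.05.
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_detectable_difference(sd = 3.3, delta = 1.0, total_n = 328)
power_detectable_difference <- function(sd, delta, total_n, alpha = 0.05) {
  if (sd <= 0) stop("`sd` must be positive")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (total_n < 4) stop("`total_n` must be at least 4")
  n_per <- total_n / 2
  se <- sd * sqrt(2 / n_per)
  stats::pnorm(abs(delta) / se - stats::qnorm(1 - alpha / 2))
}
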