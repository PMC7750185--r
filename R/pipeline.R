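# One-call analysis pipeline: descriptive benchmarking, the bootstrap
# stability analysis per outcome, diagnostics on the full model, report
# tables at display precision, figures and a reproducibility manifest.

#' Run the full colostrum contamination analysis
#'
#' Orchestrates the package end to end on a prepared sample table:
#' descriptive group summaries and per-farm failure rates, a bootstrap
#' stability analysis per requested outcome, the influential-variable
#' subset, full-model diagnostics (repeated cross-validation, predictor
#' correlations, interaction screen), figures, and a manifest (seed,
#' configuration, package version) sufficient to reproduce every artifact.
#' All tables are CSV, the diagnostics report JSON, figures PNG and SVG.
#'
#' @param data Per-sample data frame (already filtered complete; see
#'   [filter_complete()]).
#' @param dir Output directory, created if needed.
#' @param outcomes Outcome columns to analyse, default
#'   `c("log_tbc", "log_cc")`.
#' @param terms Candidate terms, default the schema variables.
#' @param B Bootstrap replicates per outcome, default 1000.
#' @param seed Master seed, default 1.
#' @param mode Bootstrap resampling unit, `"record"` (default) or `"farm"`.
#' @param stability_min,p_max Influence thresholds (10%, 0.025).
#' @param rule Failure [threshold_rule()].
#' @param cv_repeats Repeats for the cross-validation diagnostic, default 10.
#' @param make_figures Write figures? Default `TRUE`.
#' @return Invisible list with the `colstab` fits, diagnostics and the
#'   manifest; all artifact paths in `$files`.
#' @export
run_colostrum_analysis <- function(data, dir,
                                   outcomes = c("log_tbc", "log_cc"),
                                   terms = candidate_terms(),
                                   B = 1000, seed = 1,
                                   mode = c("record", "farm"),
                                   stability_min = 10, p_max = 0.025,
                                   rule = threshold_rule(),
                                   cv_repeats = 10,
                                   make_figures = TRUE) {
  mode <- match.arg(mode)
  problems <- validate_colostrum(data)
  if (length(problems)) {
    stop("input failed validation:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  terms <- intersect(terms, names(data))
  data <- standardize_dataset(data, intersect(terms, .continuous_vars()))
  files <- character()
  put <- function(name) {
    p <- file.path(dir, name)
    files[[name]] <<- p
    p
  }

  # descriptive benchmarking
  grp <- summarize_by_group(data, "collection_point", rule)
  utils::write.csv(grp, put("group_summary.csv"), row.names = FALSE)
  farm <- farm_failure_rates(data, rule)
  utils::write.csv(farm, put("farm_failure_rates.csv"), row.names = FALSE)

  fits <- list()
  diagnostics <- list()
  for (outcome in outcomes) {
    tag <- sub("^log_", "", outcome)
    fit <- boot_stability(data, outcome, terms, B = B, seed = seed,
                          mode = mode, standardize = FALSE)
    fits[[outcome]] <- fit
    utils::write.csv(fit$archive, put(paste0("replicates_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(summary(fit), put(paste0("stability_", tag, ".csv")),
                     row.names = FALSE)
    sel <- select_influential(fit, stability_min, p_max)
    utils::write.csv(sel, put(paste0("selected_", tag, ".csv")),
                     row.names = FALSE)

    full <- lmm_ml(stats::reformulate(terms, response = outcome), data,
                   drop_aliased = TRUE)
    diagnostics[[outcome]] <- list(
      cv = unclass(repeated_kfold_cv(data, outcome, terms, k = 10,
                                     repeats = cv_repeats,
                                     seed = seed))[c("internal_r2", "cv_r2",
                                                     "internal_mae", "cv_mae",
                                                     "k", "repeats")],
      residual_normality = unclass(residual_normality(full))[
        c("skewness", "kurtosis", "n", "unreliable")],
      interactions = interaction_screen(
        data, outcome, unique(sel$term) %||% character(), alpha = 0.05)
    )
    if (make_figures) {
      for (dev in c("png", "svg")) {
        path <- put(paste0("coefficients_", tag, ".", dev))
        if (dev == "png") grDevices::png(path, 1400, 900, res = 130)
        else grDevices::svg(path, 10, 7)
        try(plot(fit, stability_min = stability_min), silent = TRUE)
        grDevices::dev.off()
        path <- put(paste0("stability_vs_p_", tag, ".", dev))
        if (dev == "png") grDevices::png(path, 1100, 900, res = 130)
        else grDevices::svg(path, 8, 7)
        try(plot_stability_vs_p(fit, stability_min, p_max), silent = TRUE)
        grDevices::dev.off()
      }
    }
  }

  corr <- predictor_correlations(data, terms)
  utils::write.csv(corr$pairs, put("predictor_correlations.csv"),
                   row.names = FALSE)
  diagnostics$max_abs_predictor_correlation <- corr$max_abs
  jsonlite::write_json(diagnostics, put("diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)

  manifest <- list(
    package = "colstab",
    version = as.character(utils::packageVersion("colstab")),
    seed = seed, B = B, mode = mode, outcomes = outcomes, terms = terms,
    stability_min = stability_min, p_max = p_max,
    thresholds = list(tbc = rule$tbc_threshold, cc = rule$cc_threshold),
    n_samples = nrow(data),
    n_farms = length(unique(data$farm_id)),
    standardization = attr(data, "standardization"))
  jsonlite::write_json(manifest, put("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(fits = fits, diagnostics = diagnostics,
                 manifest = manifest, files = files))
}
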