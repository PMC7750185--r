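# Synthetic herd-data generator. The generative model is the analysis model
# run forwards: farm-clustered log-scale outcomes
#   y_ij = mu + sum(beta * x_ij) + U_j + eps_ij,
#   U_j ~ N(0, theta_U), eps_ij ~ N(0, theta_eps),
# with counts produced as max(0, round(exp(y) - 1)) so that the analysis
# transform log(count + 1) inverts the generator up to integer rounding.
# Coliform counts additionally receive structural zeros with probability
# cc_zero_prob, emulating the observed excess of zero-coliform samples.

# Conditional-on-applicable level frequencies. Collection point shares are
# the marginal sample shares; equipment variables are conditioned on the
# samples for which they are defined, which reproduces the marginal
# "Not applicable" shares through the structural rules.
.default_level_freqs <- function() {
  list(
    collection_point = c("Cows teat" = 0.178,
                         "Colostrum collection bucket" = 0.363,
                         "Feeding teat" = 0.244,
                         "Esophageal tube" = 0.215),
    premilk_disinfection = c(No = 57, Yes = 271) / 328,
    teat_dry_wiped = c(No = 58, Yes = 270) / 328,
    milking_system = c(Parlor = 220, Robot = 50) / 270,
    collection_clean_freq = c("Each use" = 69, "Less than each use" = 201) / 270,
    collection_clean_method = c(Water = 79, Hypochlorite = 54, "Parlor wash" = 94,
                                "Peracetic acid" = 31, Soap = 12) / 270,
    collection_hot_water = c(No = 125, Yes = 145) / 270,
    feeding_clean_freq = c("Each calf" = 102, "Less than each calf" = 49) / 151,
    feeding_clean_method = c(Water = 34, Hypochlorite = 45, "Parlor wash" = 24,
                             "Peracetic acid" = 24, Soap = 24) / 151,
    feeding_hot_water = c(No = 49, Yes = 102) / 151,
    colostrum_frozen = c(No = 256, Yes = 14) / 270,
    pasteuriser_used = c(No = 259, Yes = 11) / 270
  )
}

#' Default ground-truth effects for the synthetic generator
#'
#' Realistic log-scale coefficients for the total-bacterial-count and
#' coliform-count outcomes (e.g. robot milking +3.38 log cfu/ml against
#' teat collection), used as the generator defaults.
#'
#' @param outcome `"tbc"` or `"cc"`.
#' @return Named numeric vector; names are `"variable:level"` (or a bare
#'   continuous variable name).
#' @export
default_true_effects <- function(outcome = c("tbc", "cc")) {
  outcome <- match.arg(outcome)
  if (outcome == "tbc") {
    c("milking_system:Parlor" = 2.06,
      "milking_system:Robot" = 3.38,
      "collection_point:Feeding teat" = 0.30,
      "collection_point:Esophageal tube" = 0.30,
      "feeding_hot_water:Yes" = -2.54,
      "collection_clean_method:Hypochlorite" = -1.60,
      "collection_clean_method:Parlor wash" = 0.47,
      "collection_clean_method:Peracetic acid" = -2.04,
      "collection_clean_method:Soap" = -1.14,
      "collection_clean_freq:Less than each use" = 1.75,
      "teat_dry_wiped:Yes" = -1.97,
      "premilk_disinfection:Yes" = -1.85,
      "pasteuriser_used:Yes" = -3.79)
  } else {
    c("collection_point:Colostrum collection bucket" = 1.49,
      "collection_point:Feeding teat" = 3.40,
      "collection_point:Esophageal tube" = 3.40,
      "feeding_hot_water:Yes" = -2.72,
      "collection_hot_water:Yes" = -1.72,
      "collection_clean_method:Hypochlorite" = -0.64,
      "collection_clean_method:Parlor wash" = 1.28,
      "collection_clean_method:Peracetic acid" = -1.66,
      "collection_clean_freq:Less than each use" = 1.68,
      "teat_dry_wiped:Yes" = -2.33,
      "colostrum_frozen:Yes" = -2.70)
  }
}

#' Simulation configuration
#'
#' Ground-truth generative parameters for a synthetic colostrum study. The
#' defaults emulate the dimensions and structure of a 56-farm study with six
#' samples per farm: farm-clustered log-scale outcomes, conditional level
#' frequencies matching the observed management-practice shares, structural
#' "Not applicable" coding driven by the collection point, and an excess of
#' zero coliform counts.
#'
#' @param n_farms Number of farms (>= 2).
#' @param samples_per_farm Samples per farm; a single integer or a length-2
#'   range sampled uniformly per farm.
#' @param mu Intercept for log TBC (log cfu/ml; baseline = teat-collected
#'   sample at all reference levels).
#' @param mu_cc Intercept for log CC.
#' @param true_effects Named vector of log-scale coefficients for TBC,
#'   keyed `"variable:level"` (continuous variables by bare name, coefficient
#'   per standard deviation).
#' @param true_effects_cc Same, for CC.
#' @param theta_U Between-farm variance (log scale, >= 0).
#' @param theta_eps Residual variance (log scale, > 0).
#' @param level_freqs Per-variable categorical probabilities, conditional on
#'   the variable being applicable; each vector must sum to 1.
#' @param cc_zero_prob Probability of a structural zero coliform count.
#' @param pen_days_range Range of the days-between-calving-pen-clean-out
#'   covariate, drawn uniformly per farm.
#' @param seed Integer seed; every random draw in [generate_dataset()] is
#'   driven by it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_farms = 56,
                       samples_per_farm = 6,
                       mu = 10.0,
                       mu_cc = 1.5,
                       true_effects = default_true_effects("tbc"),
                       true_effects_cc = default_true_effects("cc"),
                       theta_U = 1.0,
                       theta_eps = 4.0,
                       level_freqs = .default_level_freqs(),
                       cc_zero_prob = 0.35,
                       pen_days_range = c(3.5, 90),
                       seed = NULL) {
  cfg <- structure(
    list(n_farms = n_farms, samples_per_farm = samples_per_farm,
         mu = mu, mu_cc = mu_cc,
         true_effects = true_effects, true_effects_cc = true_effects_cc,
         theta_U = theta_U, theta_eps = theta_eps,
         level_freqs = level_freqs, cc_zero_prob = cc_zero_prob,
         pen_days_range = pen_days_range, seed = seed),
    class = "sim_config")
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n_farms) || cfg$n_farms < 2) {
    stop("`n_farms` must be >= 2 (farm variance is unidentifiable otherwise)")
  }
  m <- cfg$samples_per_farm
  if (!is.numeric(m) || !length(m) %in% 1:2 || any(m < 1)) {
    stop("`samples_per_farm` must be a positive integer or length-2 range")
  }
  if (cfg$theta_U < 0) stop("`theta_U` must be >= 0")
  if (cfg$theta_eps < 0) stop("`theta_eps` must be >= 0")
  if (cfg$cc_zero_prob < 0 || cfg$cc_zero_prob > 1) {
    stop("`cc_zero_prob` must lie in [0, 1]")
  }
  for (var in names(cfg$level_freqs)) {
    p <- cfg$level_freqs[[var]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("probabilities for `", var, "` must be non-negative and sum to 1")
    }
    known <- .schema_levels(var)
    if (!is.null(known)) {
      bad <- setdiff(names(p), known)
      if (length(bad)) {
        stop("`", var, "` frequency names outside the schema levels: ",
             paste(shQuote(bad), collapse = ", "))
      }
    }
  }
  for (eff in list(cfg$true_effects, cfg$true_effects_cc)) {
    for (key in names(eff)) .parse_effect_key(key, cfg$level_freqs)
  }
  invisible(cfg)
}

.parse_effect_key <- function(key, level_freqs) {
  if (key %in% .continuous_vars()) {
    return(list(var = key, level = NULL))
  }
  parts <- regmatches(key, regexpr(":", key), invert = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("effect key `", key, "` is neither `variable:level` nor a declared ",
         "continuous variable")
  }
  var <- parts[1]; level <- parts[2]
  levels_known <- union(names(level_freqs[[var]]) %||% character(),
                        .schema_levels(var) %||% character())
  if (!var %in% union(names(level_freqs), .categorical_vars()) ||
      !level %in% levels_known) {
    stop("effect key `", key, "` refers to an unknown variable or level")
  }
  list(var = var, level = level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth coefficient table
#'
#' Expands a simulation configuration into the full per-level coefficient
#' table used by [generate_dataset()]: every level of every categorical
#' variable with its true effect, reference levels carrying coefficient zero
#' by construction, plus one row per continuous variable.
#'
#' @param config A [sim_config()].
#' @param outcome `"tbc"` or `"cc"`.
#' @return Data frame with columns `variable`, `level`, `reference`
#'   (logical) and `effect`.
#' @export
true_effect_table <- function(config, outcome = c("tbc", "cc")) {
  outcome <- match.arg(outcome)
  .validate_sim_config(config)
  effects <- if (outcome == "tbc") config$true_effects else config$true_effects_cc
  rows <- list()
  for (var in .categorical_vars()) {
    lv <- .schema_levels(var)
    for (i in seq_along(lv)) {
      key <- paste0(var, ":", lv[i])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = var, level = lv[i], reference = i == 1L,
        effect = if (i == 1L) 0 else unname(effects[key] %||% 0),
        stringsAsFactors = FALSE)
    }
  }
  for (var in .continuous_vars()) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = var, level = NA_character_, reference = FALSE,
      effect = unname(effects[var] %||% 0), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$effect[is.na(out$effect)] <- 0
  out
}

.linear_predictor <- function(data, effects, pen_days_range) {
  lp <- numeric(nrow(data))
  for (key in names(effects)) {
    parsed <- .parse_effect_key(key, list())
    if (is.null(parsed$level)) {
      # continuous covariate: coefficient per theoretical SD of its
      # generating uniform distribution
      m <- mean(pen_days_range)
      s <- diff(range(pen_days_range)) / sqrt(12)
      lp <- lp + effects[[key]] * (data[[parsed$var]] - m) / s
    } else {
      lp <- lp + effects[[key]] * (as.character(data[[parsed$var]]) == parsed$level)
    }
  }
  lp
}

#' Generate a synthetic colostrum dataset
#'
#' Draws a farm-clustered sample table with known ground truth. Management
#' practices (cleaning methods, milking system, calving-pen clean-out
#' interval, ...) are farm properties shared by all of a farm's samples; the
#' collection point varies sample by sample, and the structural
#' "Not applicable" rules of [colostrum_schema()] are enforced on the result.
#' Outcomes follow the random-intercept model on the log scale; counts are
#' `max(0, round(exp(y) - 1))` and coliform counts are replaced by zero with
#' probability `cc_zero_prob`.
#'
#' @param config A [sim_config()].
#' @return Data frame of one row per sample with a `ground_truth` attribute
#'   (true coefficient tables, variances, farm effects and seed).
#' @export
#' @examples
#' d <- generate_dataset(sim_config(n_farms = 4, seed = 1))
#' table(d$collection_point)
generate_dataset <- function(config) {
  .validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  J <- as.integer(config$n_farms)
  m <- config$samples_per_farm
  n_j <- if (length(m) == 1L) rep(as.integer(m), J) else
    sample(seq(m[1], m[2]), J, replace = TRUE)
  farm_ids <- sprintf("farm_%03d", seq_len(J))
  p <- config$level_freqs

  draw <- function(var, n) {
    pr <- p[[var]]
    factor(sample(names(pr), n, replace = TRUE, prob = pr),
           levels = .schema_levels(var))
  }
  # farm-level management practices
  farm <- data.frame(
    farm_id = farm_ids,
    calving_pen_days = stats::runif(J, config$pen_days_range[1],
                                    config$pen_days_range[2]),
    premilk_disinfection = draw("premilk_disinfection", J),
    teat_dry_wiped = draw("teat_dry_wiped", J),
    milking_system = draw("milking_system", J),
    collection_clean_freq = draw("collection_clean_freq", J),
    collection_clean_method = draw("collection_clean_method", J),
    collection_hot_water = draw("collection_hot_water", J),
    feeding_clean_freq = draw("feeding_clean_freq", J),
    feeding_clean_method = draw("feeding_clean_method", J),
    feeding_hot_water = draw("feeding_hot_water", J),
    colostrum_frozen = draw("colostrum_frozen", J),
    pasteuriser_used = draw("pasteuriser_used", J),
    stringsAsFactors = FALSE)

  idx <- rep(seq_len(J), n_j)
  n <- length(idx)
  data <- farm[idx, , drop = FALSE]
  rownames(data) <- NULL
  data$cow_id <- paste0(data$farm_id, "_cow",
                        unlist(lapply(n_j, seq_len), use.names = FALSE))
  # collection point is a sample-level draw
  data$collection_point <- draw("collection_point", n)
  data <- apply_structural_na(data)

  u_tbc <- stats::rnorm(J, 0, sqrt(config$theta_U))
  u_cc <- stats::rnorm(J, 0, sqrt(config$theta_U))
  y_tbc <- config$mu +
    .linear_predictor(data, config$true_effects, config$pen_days_range) +
    u_tbc[idx] + stats::rnorm(n, 0, sqrt(config$theta_eps))
  y_cc <- config$mu_cc +
    .linear_predictor(data, config$true_effects_cc, config$pen_days_range) +
    u_cc[idx] + stats::rnorm(n, 0, sqrt(config$theta_eps))

  data$tbc <- pmax(0, round(expm1(y_tbc)))
  cc <- pmax(0, round(expm1(y_cc)))
  cc[stats::runif(n) < config$cc_zero_prob] <- 0
  data$cc <- cc
  data$log_tbc <- log_cfu(data$tbc)
  data$log_cc <- log_cfu(data$cc)

  front <- c("farm_id", "cow_id", "collection_point", "calving_pen_days")
  data <- data[, c(front, setdiff(names(data), front))]
  attr(data, "ground_truth") <- list(
    config = config,
    effects_tbc = true_effect_table(config, "tbc"),
    effects_cc = true_effect_table(config, "cc"),
    theta_U = config$theta_U, theta_eps = config$theta_eps,
    mu = config$mu, mu_cc = config$mu_cc,
    farm_effects_tbc = stats::setNames(u_tbc, farm_ids),
    farm_effects_cc = stats::setNames(u_cc, farm_ids),
    latent_log_tbc = y_tbc, latent_log_cc = y_cc,
    seed = config$seed)
  data
}

#' Simulate a colostrum study in one call
#'
#' Convenience wrapper building a [sim_config()] and calling
#' [generate_dataset()].
#'
#' @param ... Passed to [sim_config()].
#' @return See [generate_dataset()].
#' @export
simulate_colostrum <- function(...) generate_dataset(sim_config(...))

#' Write a simulated dataset with its ground-truth sidecar
#'
#' Writes the sample table as CSV and the generative truth (true
#' coefficients, variances, intercepts and seed) as a JSON sidecar next to
#' it, so downstream recovery analyses can be run from files alone.
#'
#' @param data A dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param stem File stem, default `"colostrum_sim"`.
#' @return Named character vector of the two paths, invisibly.
#' @export
simulate_colostrum_files <- function(data, dir, stem = "colostrum_sim") {
  gt <- attr(data, "ground_truth")
  if (is.null(gt)) stop("`data` carries no ground-truth attribute")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, "_truth.json"))
  write_colostrum_csv(data, csv)
  cfg <- gt$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_farms = cfg$n_farms,
         samples_per_farm = cfg$samples_per_farm,
         mu = cfg$mu, mu_cc = cfg$mu_cc,
         theta_U = cfg$theta_U, theta_eps = cfg$theta_eps,
         cc_zero_prob = cfg$cc_zero_prob,
         true_effects = as.list(cfg$true_effects),
         true_effects_cc = as.list(cfg$true_effects_cc)),
    js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv = csv, truth = js))
}
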