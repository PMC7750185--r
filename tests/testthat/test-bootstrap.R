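test_that("bootstrap p-values follow the majority-side definition", {
  expect_equal(bootstrap_p(c(0.5, 1.2, 2.0)), 0)
  expect_equal(bootstrap_p(c(-1, 1)), 0.5)
  expect_equal(bootstrap_p(c(3, 1, 2, -1)), 0.25)
  expect_equal(bootstrap_p(c(-3, -1, -2, 1)), 0.25)
  expect_equal(bootstrap_p(7), 0)
  # an exact zero counts toward the minority side (conservative)
  expect_equal(bootstrap_p(c(1, 2, 3, 0)), 0.25)
  expect_error(bootstrap_p(numeric(0)), "at least one")
})

test_that("stability percentages are direct selection frequencies", {
  reps <- lapply(1:8, function(i) {
    structure(list(seed = i,
                   selected = if (i <= 6) "termA" else character(),
                   coefficients = data.frame(term = character(),
                                             column = character(),
                                             estimate = numeric()),
                   converged = TRUE, n_redraws = 0L, n_resample = 10L),
              class = "replicate_result")
  })
  attr(reps, "candidates") <- c("termA", "termB")
  expect_equal(stability_pct(reps, "termA"), 75)
  expect_equal(stability_pct(reps, "termB"), 0)
  expect_error(stability_pct(reps, "termZ"), "unknown term")
})

test_that("coefficient summaries use the linear-interpolation quantile rule", {
  mk <- function(vals) lapply(seq_along(vals), function(i) {
    list(selected = "t",
         coefficients = data.frame(term = "t", column = "tYes",
                                   estimate = vals[i],
                                   stringsAsFactors = FALSE))
  })
  s <- summarize_coefficients(mk(c(1, 2, 3, 4)), "tYes")
  expect_equal(s$mean_coef, 2.5)
  expect_equal(s$bci_low, interp_quantile(c(1, 2, 3, 4), 0.025))
  expect_equal(s$bci_high, interp_quantile(c(1, 2, 3, 4), 0.975))
  expect_equal(s$bci_low, 1.075)
  expect_equal(s$bci_high, 3.925)
  # a single selecting replicate collapses the interval onto the value
  s1 <- summarize_coefficients(mk(2.2), "tYes")
  expect_equal(s1[c("mean_coef", "bci_low", "bci_high")],
               list(mean_coef = 2.2, bci_low = 2.2, bci_high = 2.2))
  # never-selected levels are absent, not zero
  expect_null(summarize_coefficients(mk(1), "otherColumn"))
  # the mean always lies inside the selected range
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(20)
    s <- summarize_coefficients(mk(v), "tYes")
    expect_gte(s$mean_coef, min(v))
    expect_lte(s$mean_coef, max(v))
  }
})

test_that("replicates are seed-deterministic with resamples of original size", {
  d <- simulate_colostrum(n_farms = 12, seed = 5)
  r1 <- bootstrap_replicate(d, "log_tbc",
                            c("feeding_hot_water", "teat_dry_wiped"), 4242)
  r2 <- bootstrap_replicate(d, "log_tbc",
                            c("feeding_hot_water", "teat_dry_wiped"), 4242)
  expect_identical(r1, r2)
  expect_identical(r1$n_resample, nrow(d))
  expect_true(r1$converged)
})

test_that("runs with the same master seed give identical replicate archives", {
  d <- simulate_colostrum(n_farms = 10, seed = 9)
  terms <- c("collection_hot_water", "teat_dry_wiped")
  b1 <- boot_stability(d, "log_tbc", terms, B = 12, seed = 77)
  b2 <- boot_stability(d, "log_tbc", terms, B = 12, seed = 77)
  expect_identical(b1$archive, b2$archive)
  expect_identical(b1$summary, b2$summary)
  b3 <- boot_stability(d, "log_tbc", terms, B = 1, seed = 77)
  expect_true(all(b3$term_stability %in% c(0, 100)))
})

test_that("stability is shared across levels of a term, coefficients differ", {
  d <- simulate_colostrum(n_farms = 30, seed = 14)
  bs <- boot_stability(d, "log_tbc",
                       c("collection_clean_method", "feeding_hot_water"),
                       B = 25, seed = 3)
  s <- bs$summary
  for (t in unique(s$term)) {
    expect_identical(length(unique(s$stability[s$term == t])), 1L)
  }
  meth <- s[s$term == "collection_clean_method", ]
  if (nrow(meth) > 1) expect_gt(length(unique(meth$mean_coef)), 1L)
})

test_that("a level absent from the resample yields no coefficient entry", {
  d <- simulate_colostrum(n_farms = 12, seed = 5)
  # make a level unique to one record; resamples excluding that record
  # cannot estimate it
  d$pasteuriser_used <- factor(
    "No", levels = colostrum_schema()$variables$pasteuriser_used$levels)
  d$pasteuriser_used[1] <- "Yes"
  hit <- FALSE
  for (s in 1:20) {
    r <- bootstrap_replicate(d, "log_tbc",
                             c("pasteuriser_used", "feeding_hot_water"),
                             s * 101)
    set.seed((s * 101) %% .Machine$integer.max)
    took_first <- 1 %in% sample.int(nrow(d), nrow(d), replace = TRUE)
    if (!took_first) {
      hit <- TRUE
      expect_false("pasteuriser_used" %in% r$selected)
      expect_false(any(grepl("pasteuriser", r$coefficients$column)))
    }
  }
  expect_true(hit)
})

test_that("influence selection applies strict thresholds term-wise", {
  rows <- data.frame(
    term = c("milking_system", "milking_system", "feed_freq", "border",
             "unstable"),
    level = c("Parlor", "Robot", "Less", "Yes", "Yes"),
    column = c("msParlor", "msRobot", "ffLess", "borderYes", "unstableYes"),
    n = c(220, 50, 49, 10, 300),
    stability = c(92.5, 92.5, 9.7, 10.0, 45),
    n_selected = c(925, 925, 97, 100, 450),
    mean_coef = c(2.06, 3.38, -2.13, 1.0, 0.2),
    bci_low = 0, bci_high = 1,
    boot_p = c(0.01, 0.004, 0.004, 0.01, 0.025),
    stringsAsFactors = FALSE)
  kept <- select_influential(rows)
  # stability 92.5 with p 0.01 is kept, and both its levels together
  expect_identical(sort(kept$level[kept$term == "milking_system"]),
                   c("Parlor", "Robot"))
  # stability 9.7 fails despite p < 0.01; stability exactly 10 fails (strict)
  expect_false("feed_freq" %in% kept$term)
  expect_false("border" %in% kept$term)
  # p exactly 0.025 fails (strict)
  expect_false("unstable" %in% kept$term)
  expect_identical(nrow(select_influential(rows[0, ])), 0L)
})

test_that("a planted effect separates from a null term end to end", {
  cfg <- sim_config(n_farms = 56, samples_per_farm = 6, theta_U = 1,
                    theta_eps = 4,
                    true_effects = c("collection_hot_water:Yes" = 2.5),
                    true_effects_cc = c(), seed = 61)
  d <- generate_dataset(cfg)
  bs <- boot_stability(d, "log_tbc",
                       c("collection_hot_water", "teat_dry_wiped"),
                       B = 40, seed = 8)
  expect_gt(bs$term_stability[["collection_hot_water"]],
            bs$term_stability[["teat_dry_wiped"]])
  kept <- select_influential(bs)
  expect_true("collection_hot_water" %in% kept$term)
})

test_that("summaries are invariant to replicate order", {
  d <- simulate_colostrum(n_farms = 10, seed = 2)
  terms <- c("feeding_hot_water", "teat_dry_wiped")
  bs <- boot_stability(d, "log_tbc", terms, B = 10, seed = 30)
  reps <- rev(bs$replicates)
  attr(reps, "candidates") <- terms
  for (t in terms) {
    expect_equal(stability_pct(reps, t), bs$term_stability[[t]])
  }
  cols <- unique(bs$summary$column)
  for (cn in cols) {
    a <- summarize_coefficients(bs$replicates, cn)
    b <- summarize_coefficients(reps, cn)
    expect_equal(a, b)
  }
})

test_that("farm-mode resampling draws whole farms", {
  d <- simulate_colostrum(n_farms = 10, seed = 44)
  r <- bootstrap_replicate(d, "log_tbc", "feeding_hot_water", 7,
                           mode = "farm")
  expect_true(r$converged)
  # resample size is a multiple of the per-farm sample count
  expect_identical(r$n_resample %% 6L, 0L)
})
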