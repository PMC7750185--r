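test_that("count log transform maps the anchor values and rejects bad input", {
  expect_identical(log_cfu(0), 0)
  expect_equal(log_cfu(exp(1) - 1), 1)
  expect_equal(log_cfu(99999), log(100000))
  expect_true(all(diff(log_cfu(c(0, 1, 10, 500, 1e6))) > 0))
  expect_error(log_cfu(-1), "non-negative")
  expect_error(log_cfu(c(2, NaN)), "finite")
  expect_error(log_cfu(Inf), "finite")
})

test_that("standardization centres, scales, is affine-invariant and inverts", {
  s <- standardize_continuous(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(40, 5, 3)
    a <- runif(1, -10, 10); b <- runif(1, 0.1, 4)
    expect_equal(standardize_continuous(a + b * x)$values,
                 standardize_continuous(x)$values, tolerance = 1e-10)
    z <- standardize_continuous(x)
    expect_equal(mean(z$values), 0, tolerance = 1e-12)
    expect_equal(sd(z$values), 1, tolerance = 1e-12)
    expect_equal(unstandardize(z$values, z$mean, z$sd), x, tolerance = 1e-10)
  }
  expect_error(standardize_continuous(rep(2, 5), name = "pen_days"),
               "pen_days.*sd = 0")
})

test_that("cleaning-frequency levels are recategorised and unknowns rejected", {
  expect_identical(relevel_frequency("Daily"), "Less than each use")
  expect_identical(relevel_frequency("Less than daily"), "Less than each use")
  expect_identical(relevel_frequency("Each use"), "Each use")
  expect_identical(relevel_frequency("Not applicable"), "Not applicable")
  expect_identical(relevel_frequency(c("Each calf", "Daily")),
                   c("Each calf", "Less than each use"))
  expect_error(relevel_frequency("Weekly"), "unknown")
})

test_that("structural applicability is enforced by collection point", {
  rec <- data.frame(collection_point = c("Cows teat", "Esophageal tube",
                                         "Colostrum collection bucket"),
                    feeding_clean_method = c("Water", "Water", "Water"),
                    feeding_hot_water = c("Yes", "Yes", "Yes"),
                    milking_system = c("Parlor", "Parlor", "Parlor"),
                    stringsAsFactors = FALSE)
  out <- apply_structural_na(rec)
  # teat-collected: every equipment variable becomes structural
  expect_identical(out$feeding_clean_method[1], "Not applicable")
  expect_identical(out$milking_system[1], "Not applicable")
  # tube-collected records are unchanged
  expect_identical(out[2, ], rec[2, ])
  # bucket-collected: feeding equipment only
  expect_identical(out$feeding_hot_water[3], "Not applicable")
  expect_identical(out$milking_system[3], "Parlor")
})

test_that("completeness filtering reproduces the exclusion arithmetic", {
  d <- simulate_colostrum(n_farms = 60, samples_per_farm = 6, seed = 21)
  d <- d[seq_len(356), ]
  d$tbc[1:15] <- NA                      # missing or damaged in transit
  d$collection_clean_method[16:28] <- NA # incomplete collection data
  res <- filter_complete(d)
  expect_identical(res$report$n_received, 356L)
  expect_identical(res$report$removed_by_rule$missing_or_damaged, 15L)
  expect_identical(res$report$removed_by_rule$incomplete_collection_data, 13L)
  expect_identical(res$report$n_final, 328L)
  expect_identical(res$report$n_received - res$report$n_removed,
                   res$report$n_final)
  # idempotent
  res2 <- filter_complete(res$data)
  expect_identical(res2$report$n_removed, 0L)
  expect_identical(res2$data, res$data)
  # empty input
  res0 <- filter_complete(d[0, ])
  expect_identical(res0$report$n_final, 0L)
  expect_identical(res0$report$n_removed, 0L)
})

test_that("a record failing several rules is counted once, at the first rule", {
  d <- simulate_colostrum(n_farms = 3, seed = 2)
  d$tbc[1] <- NA
  d$milking_system[1] <- NA
  res <- filter_complete(d)
  expect_identical(res$report$removed_by_rule$missing_or_damaged, 1L)
  expect_identical(res$report$removed_by_rule$incomplete_collection_data, 0L)
})

test_that("CSV round trip preserves the sample table and validates levels", {
  d <- simulate_colostrum(n_farms = 5, seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_colostrum_csv(d, path)
  d2 <- read_colostrum_csv(path)
  expect_equal(nrow(d2), nrow(d))
  expect_identical(as.character(d2$collection_point),
                   as.character(d$collection_point))
  expect_identical(levels(d2$milking_system),
                   colostrum_schema()$variables$milking_system$levels)
  expect_equal(d2$log_tbc, d$log_tbc)
  # a corrupted level is caught
  bad <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad$milking_system[2] <- "Rotary"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_colostrum_csv(path2), "Rotary")
})

test_that("dataset standardization is applied once and recorded", {
  d <- simulate_colostrum(n_farms = 6, seed = 8)
  s1 <- standardize_dataset(d)
  expect_equal(mean(s1$calving_pen_days), 0, tolerance = 1e-12)
  expect_equal(sd(s1$calving_pen_days), 1, tolerance = 1e-12)
  std <- attr(s1, "standardization")
  expect_named(std, "calving_pen_days")
  s2 <- standardize_dataset(s1)   # no-op on the second call
  expect_equal(s2$calving_pen_days, s1$calving_pen_days)
  expect_equal(unstandardize(s1$calving_pen_days,
                             std$calving_pen_days$mean,
                             std$calving_pen_days$sd),
               d$calving_pen_days, tolerance = 1e-10)
})

test_that("the shipped schema JSON mirrors the in-code schema", {
  path <- system.file("extdata", "colostrum_schema.json", package = "colstab")
  expect_true(nzchar(path))
  shipped <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- colostrum_schema()
  expect_identical(names(shipped$variables), names(sch$variables))
  for (v in names(sch$variables)) {
    if (sch$variables[[v]]$type == "categorical") {
      expect_identical(shipped$variables[[v]]$levels,
                       sch$variables[[v]]$levels, label = v)
    }
  }
})
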