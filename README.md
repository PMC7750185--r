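# colstab

Bootstrap stability selection for colostrum bacteriology on dairy farms.

Bacterial contamination of bovine colostrum — measured as the total
bacterial count (TBC) and coliform count (CC) of a sample, in cfu/ml — is a
risk factor for failed passive immunity transfer and pathogen exposure in
neonatal calves. Samples cluster by farm, and most of the candidate risk
factors are farm-level management protocols (equipment cleaning chemistry
and frequency, milking system, teat preparation, pasteurisation), while the
collection point (cow's teat, collection bucket, feeding equipment) varies
per sample. `colstab` is for veterinary epidemiologists and herd-health
researchers who want to benchmark contamination against the conventional
thresholds (failure when TBC > 100,000 or CC > 10,000 cfu/ml, strictly) and
to rank management factors by how *reproducibly* they matter, not just how
large their estimated effects are.

## The method

Counts enter the model as `log(count + 1)`. For sample *i* on farm *j*:

    y_ij = mu + beta_1 x_1ij + beta_2 x_2ij + ... + U_j + eps_ij
    U_j ~ N(0, theta_U),   eps_ij ~ N(0, theta_eps)

fitted by full maximum likelihood (`lmm_ml()`, a profiled closed-form
random-intercept fitter; ML rather than REML because models with different
fixed effects are compared by AIC = −2·logLik + 2·(p + 2)). On each of B
(default 1000) bootstrap resamples of the sample table — record-level, with
replacement, same size as the original — `backward_aic()` greedily deletes
whole fixed-effect terms while deletions strictly lower the AIC, the farm
intercept always retained. Per variable the pipeline then reports:

* **stability** — % of replicates in which the variable survived;
* **mean coefficient** and **95% bootstrap confidence interval** —
  mean and 2.5/97.5 percentiles (linear-interpolation quantiles) over the
  replicates that selected it;
* **bootstrap p-value** — one minus the proportion of those coefficients on
  the majority side of zero.

`select_influential()` keeps variables with stability > 10% and bootstrap
p < 0.025. Because no raw per-sample data are publicly deposited for this
study design, the package ships a first-class synthetic herd generator
(`sim_config()` / `generate_dataset()`) with known ground truth —
farm-clustered log-scale outcomes, the exact Table-style level
vocabularies with structural "Not applicable" coding, and an excess of
zero coliform counts — used throughout the tests for recovery and
separation checks.

## Worked example

```r
library(colstab)

d <- simulate_colostrum(seed = 42)     # 56 farms x 6 samples, known truth

summarize_by_group(d)[, c("group", "n", "median_tbc",
                          "pct_tbc_fail", "pct_zero_cc")]
#>                         group   n median_tbc pct_tbc_fail pct_zero_cc
#> 1                   Cows teat  58      837.0          1.7        72.4
#> 2 Colostrum collection bucket 123    11725.0         26.0        55.3
#> 3                Feeding teat  85     9376.0         15.3        62.4
#> 4             Esophageal tube  70    10301.5         21.4        51.4

bs <- boot_stability(d, "log_tbc",
                     terms = c("milking_system", "feeding_hot_water",
                               "collection_clean_method", "teat_dry_wiped"),
                     B = 200, seed = 1)
bs
#> Bootstrap stability selection (log_tbc)
#>   200 replicates (record resampling), 336 samples on 56 farms
#>
#>                                   variable   n stability mean_coefficient
#> 1        feeding_hot_water: Not applicable 181     100.0            -0.69
#> 2                   feeding_hot_water: Yes 101     100.0            -2.31
#> 3    collection_clean_method: Hypochlorite  30      99.5             0.53
#> 4  collection_clean_method: Not applicable  58      99.5            -2.80
#> 5     collection_clean_method: Parlor wash 123      99.5             0.96
#> 6  collection_clean_method: Peracetic acid  42      99.5            -2.26
#> 7            collection_clean_method: Soap  14      99.5            -1.14
#> 8                      teat_dry_wiped: Yes 288      96.5            -1.54
#> 9                   milking_system: Parlor 224      68.0             2.51
#> 10                   milking_system: Robot  54      68.0             3.69
#>              bci_95 bootstrap_p
#> 1   (-1.44 to 0.14)        0.05
#> 2  (-3.15 to -1.51)       <0.01
#> ...
```

Reading the output: the teat-collected baseline is cleanest (1.7% TBC
failures, 72.4% zero-coliform), and hot-water cleaning of feeding equipment
is selected in every replicate with a mean effect of −2.31 log cfu/ml
(about a 10-fold count reduction), close to its planted ground truth of
−2.54. The milking-system contrast is larger per level (+2.5 to +3.7 log
against teat collection) but survives elimination in only 68% of
replicates: a large but less reproducibly identified effect, which is the
distinction stability selection exists to make. `plot(bs)` draws the
per-level coefficient distributions with stabilities in brackets;
`plot_stability_vs_p(bs)` shows each variable against both selection
thresholds. `run_colostrum_analysis(d, "out/")` writes the full artifact
set (descriptive tables, replicate archive, stability tables, diagnostics
JSON, figures, and a manifest that reproduces the run byte for byte).

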