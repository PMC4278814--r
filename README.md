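# windborne

Tools for reconstructing the secondary expansion of a windborne invasive
insect across a fragmented host landscape, from three independent kinds of
evidence:

- **annual presence/absence surveys**, analysed with an interval-censored
  survival model whose hazard is driven by wind exposure;
- **particle-trajectory wind data**, turned into per-site cumulative
  exposure covariates on a 10 km grid under competing dispersal scenarios;
- **microsatellite genotypes**, analysed both with classical
  population-genetic statistics and with coalescent-based approximate
  Bayesian computation (ABC) model choice among four demographic
  scenarios.

The motivating system is a seed-feeding chalcid wasp introduced once at a
single mountain site and spreading mainly down-wind (south-east) across
host stands separated by more than its flight range.  The package also
ships a synthetic-data generator that emulates all four input kinds
(site registry, trajectories, station wind runs, survey histories, plus
coalescent genotypes), so the full pipeline is testable without any
external data.

## The core models

**Establishment model.** Colonization of site *i* in year *t* is a
Poisson event with intensity

    lambda_i(t) = exp(beta0 + beta1 * x_i(t))

where `x_i(t)` is the cumulative count of trajectory endpoints in the
site's 10 km grid cell under a dispersal scenario.  Detection is
interval-censored by the annual surveys.  `establishment_fit()` returns
the maximum-likelihood fit with a profile-likelihood CI for `beta1`;
`compare_scenarios()` ranks dispersal scenarios by likelihood-ratio
statistic against a shared intercept-only null.

**Coalescent ABC.**  `simulate_genotypes()` simulates microsatellite
data under dated deme-founding scenarios (discrete-generation
Wright-Fisher coalescent, generalized stepwise mutation),
`build_reference()` builds a reference table of summary statistics
(per-deme gene diversity, Garza-Williamson M, pairwise classification
indices), and `model_choice()` estimates scenario posterior
probabilities by polychotomous logistic regression on the closest
simulations.  `confusion_rates()` quantifies type I/II scenario-choice
errors on pseudo-observed data.

**Population genetics.**  `locus_summaries()`, `f_statistics()`
(Weir-Cockerham F-statistics and allele-size R-statistics),
`pairwise_tests()`, `ibd_test()`, `allele_size_randomization()`,
`null_allele_em()`, `probability_of_identity()`, `hw_exact_test()`.

## A worked example

```r
library(windborne)

cfg <- synth_config(seed = 1)          # the default synthetic study system
reg <- generate_sites(cfg)             # 50 sites, introduction site "Vx"
tr  <- generate_trajectories(cfg, reg, c(Vx = 1994))
grid <- grid_spec(reg)

blank <- survey_table(rep(reg$site_id, each = 17),
                      rep(1994:2010, nrow(reg)), FALSE)
ex  <- build_exposure(tr, grid, reg, blank, "ventoux_only",
                      root = "Vx", years = 1994:2010)
set.seed(7)
sv  <- simulate_survey(ex, cfg$beta0, cfg$beta1, 1994:2010)

fit <- establishment_fit(ex, sv)
fit
#> Interval-censored Poisson establishment model (scenario: ventoux_only)
#>   beta0 (log baseline intensity) = -4.8644
#>   beta1 (effect per exposure unit) = 0.006714  [95% CI 0.00480253, 0.00873278]
#>   log-likelihood = -75.4717;  events = 22, censored = 28
```

The printed effect (`beta1`) is the increase in log colonization
intensity per trajectory endpoint accumulated in the site's cell; the
simulation truth here was 0.005, inside the profile CI, and 22 of the 50
stands were colonized over the 17 survey years.  A full
synthetic run — exposure scenarios, survival ranking, demographic
scenario construction, popgen tables and ABC model choice — is one
call:

```r
res <- run_all(run_config(seed = 1), out_dir = "reports")
```

which writes survival-comparison, diversity, pairwise-differentiation,
ABC-posterior and confusion tables plus a JSON run log.

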