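# scatdetect

Hierarchical Bayesian modelling of prey DNA detection in scat
metabarcoding feeding trials.

## What problem this solves

Scat DNA metabarcoding infers a carnivore's diet from taxon-assigned
amplicon reads in faecal samples. But a prey species' DNA is only
detectable in a scat under favourable conditions: detection depends on how
long before defecation the prey was eaten, what share of the daily meal it
made up, how long the scat weathered outdoors before sampling, the prey
species itself, and scat-to-scat noise. Captive feeding trials — animals
fed known daily menus, every scat collected, degraded outdoors and
repeatedly subsampled — make these biases estimable, and the estimates are
what field studies need to interpret wild-collected scats honestly.

`scatdetect` is a complete, tested implementation of that analysis for
anyone running or reanalysing such a trial:

* **Presence/absence calling** from taxon-assigned read tables and matched
  negative controls: length ≥ 80 bp and abundance ≥ 10 filters,
  family-to-species reassignment, the fewer-than-10-reads-in-control rule,
  burn-in scat exclusion.
* **Covariate construction**: per-species proportions fed on the
  defecation day and the three days before (`pr0`–`pr3`), degradation day,
  individual indicator.
* **The detection model**, a Bernoulli–logit hierarchical regression

  ```
  Y[s,ij] ~ Bernoulli(p[s,ij])
  logit(p[s,ij]) = b0[s] + b1[s]·pr0 + b2[s]·pr1 + b3[s]·pr2 + b4[s]·pr3
                   + b5·degradation_day[j] + b6·individual + alpha[i]
  ```

  with the species-indexed families `b0..b4` pooled as `N(mu_k, sigma_k²)`
  (`mu_k ~ N(0, 100)`, `sigma_k ~ U(0, 10)`), scat random effects
  `alpha[i] ~ N(0, sigma_alpha²)`, fitted by a built-in adaptive
  Metropolis-within-Gibbs sampler (C++ core) with Gelman–Rubin
  convergence diagnostics.
* **Derived quantities**: detection probability versus feeding lag per
  species, the meal proportion needed for a target detection probability
  (with grams equivalent), spike-diet gut-transit windows, forest-plot
  summaries.
* **A synthetic-data generator** with the same statistical structure
  (Dirichlet menus, Bernoulli detections with stored true probabilities,
  contaminated read tables), so every stage is testable without
  sequencing data.

The package also ships the captive cheetah trial's feeding schedule
(`cheetah_feeding_schedule()`), in a verbatim and a documented corrected
variant, and a file-to-file pipeline (`run_pipeline()`, plus a thin
wrapper script in `inst/scripts/`).

## Worked example

Simulate a trial with known coefficients, refit it, and ask the questions
the real trial asks:

```r
library(scatdetect)

species <- c("Cervus spp", "Gallus gallus", "Equus caballus",
             "Oryctolagus cuniculus", "Coturnix coturnix")
schedule <- generate_feeding_schedule(n_days = 20,
  individuals = c("Innis", "Jura"), species = species,
  max_species_per_day = 3, seed = 1)

truth <- true_parameters(sort(species),
  beta0 = -2, beta1 = 0.01, beta2 = 4.43, beta3 = 1.82, beta4 = 1.04,
  beta5 = -0.16, beta6 = -1.19, sigma_alpha = 0.5)

detections <- simulate_detections(schedule, truth,
  scat_days = as.Date("2017-11-03") + 3:15,
  degradation_days = 0:15, seed = 2)

input <- build_model_input(detections, schedule)
#> Detection model input: 2080 rows | 5 species | 26 scats | 2 individuals

fit <- run_mcmc(input, n_chains = 3, n_iter = 6000, n_burnin = 2000,
                seed = 3)
gelman_rubin(fit)
#> Gelman-Rubin diagnostic: max Rhat = 1.0127 (threshold 1.1)
#> All parameters converged.

main_effect_summary(fit)
#>      parameter  mean    sd  q2.5 q97.5
#> 1 Day 0/pr fed  0.26 0.450 -0.58  1.10
#> 2 Day 1/pr fed  4.29 0.354  3.66  4.92
#> 3 Day 2/pr fed  1.79 0.332  1.14  2.40
#> 4 Day 3/pr fed  0.57 0.456 -0.33  1.39
#> 5  Degradation -0.19 0.017 -0.22 -0.16
#> 6      Cheetah -1.85 0.361 -2.61 -1.17

proportion_for_target_probability(fit, species = NULL, lag_day = 1,
                                  target_p = 0.5)
#> Proportion of daily diet for 50% detection ((species-averaged), lag day 1):
#>   median 0.297 (95% CrI 0.152 to 0.417); ~520 g of daily intake
```

Reading the output: the species-averaged effect of meal proportion peaks
one day after feeding (`Day 1/pr fed`, posterior mean 4.29 against a
generating value of 4.43, with the 95% interval covering it), detection
decays slowly with scat age (`Degradation`, per day of exposure), and the
fitted model can be inverted — here a prey item would need to be roughly
30% of the previous day's diet for an even chance of showing up in a fresh
scat. With real trial data, replace the simulated `detections` with the
output of `filter_reads()` → `reassign_taxa()` → `call_presence()` →
`exclude_burnin_scats()` on your read tables, and
`cheetah_feeding_schedule()` (or `read_feeding_schedule()`) for the
schedule.

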