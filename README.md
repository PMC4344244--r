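# birdiet

Monthly diet compositions of birds, estimated from episodic foraging
observations.

## The problem

Volunteer monitoring programs accumulate large numbers of *feeding
episodes* — one-off field reports of a bird consuming a dietary item at a
foraging location. Pooled across years and split by month, these episodes
yield a species' **raw observation proportions** (ROPs): the monthly
fraction of episodes per diet category (seed, fleshy fruit, flower,
invertebrate, …). Two biases stand in the way of reading ROPs as diet
compositions:

1. many episodes have an **unidentified** dietary item, and identifiability
   depends on where the bird foraged (an item snatched inside a bush is
   harder to see than one taken on short grass), so simply dropping
   unidentified episodes skews the composition; and
2. some months have few observations, so raw monthly proportions fluctuate.

`birdiet` addresses both with a hierarchical Bayesian model producing
**model-aided observation proportions** (MOPs). Writing
`n_{m,k} ~ Poisson(λ_{m,k})` for the complete (identified + imputed) count
of item *k* in month *m*, the model assumes

- a single **location-given-item** law per species,
  `θ_{k,l} = P(location l | item k)`, shared by identified and unidentified
  episodes, with conjugate Dirichlet priors on each row; an unidentified
  episode seen at location *l* in month *m* is imputed to item *k* with
  posterior probability `π_{m,k} θ_{k,l} / Σ_{k'} π_{m,k'} θ_{k',l}`, where
  `π_{m,·}` normalises `λ_{m,·}`;
- **seasonal autocorrelation**: `log λ_{·,k}` follows a circular first-order
  Gaussian random walk over the 12-month cycle (December adjacent to
  January) with per-item precision `τ_k ~ Gamma(a_τ, b_τ)`, plus a Normal
  level prior — months with few episodes borrow strength from their
  neighbours.

Inference is Metropolis-within-Gibbs (latent assignments, conjugate
Dirichlet and Gamma updates, random-walk Metropolis on `log λ`). MOPs are
the rounded posterior-mean complete counts, normalised per month.

The package also computes the surrounding analyses: foraging-location
profiles, one-sided chi-square tests for seasonal shifts (animal diets in
the April–September breeding season vs the October–March wintering season;
ground foraging in the reverse direction), count proportions (CPs) from
literature stomach-content tables, and root-mean-square differences (RMSD,
percentage points) between monitoring-based and stomach-based compositions.
A synthetic-data generator with known ground truth supports
parameter-recovery experiments.

## Worked example

Simulate a species whose item identifiability depends on foraging location
(missingness 10–60% by location), fit the imputation model, and compare
recovery:

```r
library(birdiet)

truth <- synthetic_truth(seed = 42)        # 12 months x 4 items x 3 locations
gen   <- generate_episodes(truth)
ct    <- tally_episodes(gen$episodes, schema = truth$schema)
fit   <- fit_mop(ct, mop_control(chains = 2, iterations = 4000,
                                 burn_in = 1000, thin = 5), seed = 42)
fit
#> Bayesian diet imputation model fit for species: synthetic species
#>   4 identified items x 3 locations; 344 identified and 136 unidentified episodes
#>   2 chain(s), 4000 iterations (1000 burn-in, thin 5); MH acceptance 0.62
#>   max split-Rhat 1.017, min ESS 154

compute_mop(fit)
#> MOP composition table for species: synthetic species
#>     item1 item2 item3 item4 support
#> Jan  0.35  0.42  0.03  0.20      40
#> Feb  0.30  0.38  0.05  0.28      40
#> ...
```

About 28% of the simulated episodes lost their item label, preferentially
at hard-to-observe locations. Scoring both estimators against the known
truth (mean per-month total-variation distance):

```r
tv_to_truth(compute_mop(fit), truth)            # 0.093
tv_to_truth(rop_identified_only(ct), truth)     # 0.140
```

The MOP sits markedly closer to the generating diet distribution than the
identified-only ROP, whose bias follows the location-dependent missingness.

For real data, `run_pipeline()` ties the stages together — episode reading
and filtering (feeder records, non-lowland records, episodes with neither
item nor location), per-species tallies, ROPs, location profiles, seasonal
tests, MOP fits and, when stomach tables are supplied, CP computation and
per-item RMSD comparison — writing every artifact as CSV plus a plain-text
log. `inst/scripts/run_pipeline.R` is a thin command-line wrapper; the
shipped `focal_species_summary()` table provides realistic monthly
sample-size profiles for 15 resident species of lowland Kanagawa, Japan.

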