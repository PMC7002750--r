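# driverscan

Combined burden and functional-impact testing for cancer driver discovery.

`driverscan` finds candidate driver elements — coding sequences, splice
sites, UTRs, promoters, enhancers — in somatic mutation catalogs from
tumour cohorts. It is aimed at cancer genomics analysts who have per-cohort
SNV/indel tables, element definitions in BED, covariate features, and
(optionally) per-mutation functional impact scores, and who need calibrated
q-values for both coding and non-coding candidates.

## The method

Driver elements betray themselves by carrying more mutations than the local
background mutation rate (BMR) can explain. `driverscan`:

1. subtracts excluded regions (gaps, blacklists, low-mappability) from every
   element, leaving the effective length *L*;
2. learns the BMR on neutral training elements, as either a **binomial GLM**
   on features retained by randomised-lasso stability selection
   (y ~ B(N·L, p), logit(p) = Xβ) or **gradient-boosted trees** with a
   Poisson objective and ln(N·L) offset, giving an expected count
   ŷ = E(y | X, L) per element for a cohort of N donors;
3. tests the **balanced count** y_b = √(y·n_d) (geometric mean of the
   mutation count and the mutated-donor count, damping single-donor
   hypermutation) against ŷ under a binomial null — or a negative-binomial
   null NB(ŷ, s·θ) when a regression-based overdispersion test on the
   training set rejects equidispersion — followed by Benjamini–Hochberg
   correction;
4. re-weights nearly significant elements (cohort q < 0.25) by a
   **functional weight** w = S/S_T, where S is the element's mean
   phred-scaled impact (−10·log10(rank/N_m) over all scored cohort
   mutations) and S_T = −10·log10(F) encodes the assumed fraction F of
   functionally relevant variants (default F = 0.01, S_T = 20);
5. re-tests with y_f = w·y_b and reports cohort and global q-values;
   elements with global q < 0.1 form the driver list.

A bundled synthetic-cohort generator (`simulate_cohort()`) produces
elements, features, mutations and raw scores with known ground truth, so
the whole pipeline is testable without any external download. A benchmark
module scores driver call sets against reference lists with the
precision / lower-bound-recall / F1 protocol.

## Worked example

Simulate a 1,000-element cohort of 200 donors with 8 spiked drivers
(5× rate, shifted functional scores), then run the full pipeline with the
gradient-boosted BMR model:

```r
library(driverscan)

cfg <- sim_config(n_elements = 1000, n_train = 1000, n_drivers = 8, seed = 42)
sim <- simulate_cohort(cfg)
run <- infer_drivers(sim$elements, sim$training, sim$mutations,
                     sim$X, sim$X_train, model = "gbm",
                     raw_scores = sim$raw_scores, donors = sim$donors, seed = 7)
print(run)
#> driverscan_run (gbm): 1000 elements tested, 7 significant (global q < 0.1); theta = 0.000975 (p_od = 0.29)

run$results[order(p_func)][1:8, .(element_id, y, n_d, yhat = round(yhat, 1),
                                  w = round(w, 2), p_func = signif(p_func, 2),
                                  q_global = signif(q_global, 2), flag)]
#>    element_id     y   n_d  yhat     w  p_func q_global        flag
#> 1:  elem00629   140   105  19.9  0.86 6.5e-41  6.5e-38 significant
#> 2:  elem00681    76    64  11.7  0.84 6.6e-23  3.3e-20 significant
#> 3:  elem00628    72    64  12.8  0.90 2.7e-22  9.1e-20 significant
#> 4:  elem00064    69    60  11.2  0.77 1.7e-17  4.3e-15 significant
#> 5:  elem00163    78    63  15.5  0.78 1.6e-15  3.3e-13 significant
#> 6:  elem00124    21    21   4.0  0.84 2.4e-07  3.9e-05 significant
#> 7:  elem00607     9     9   2.0  0.90 2.1e-04  3.0e-02 significant
#> 8:  elem00139    16    15   7.8  0.17 6.8e-03  6.5e-01          ns
```

Reading the table: `elem00629` carries 140 mutations across 105 donors
where the BMR model expects ~20, hence the extreme p-value; `elem00139`
has a mild excess (16 observed vs 7.8 expected) but its mutations rank low
functionally (w = 0.17), so the functional adjustment deflates it and it
stays non-significant. Seven of the eight spiked drivers are recovered at
global q < 0.1; the overdispersion test finds no excess variance
(p_od = 0.29), so the binomial null was used.

The same pipeline is scriptable from a shell via
`inst/scripts/driverscan.R` (`simulate`, `infer`, `benchmark` subcommands),
reading and writing only plain BED/TSV files plus a JSON run manifest.

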