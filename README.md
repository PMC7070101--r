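# ehckin

Individual kinetic modeling of postprandial plasma bile acid responses.

Plasma bile acids rise after every meal, and the response varies strongly
both *between* people and, for the same person, *between* days. `ehckin`
analyzes this variability mechanistically: a compartmental model of the
enterohepatic circulation — hepatic synthesis and conjugation, gallbladder
storage with meal-triggered emptying, intestinal transit, active (ASBT)
and passive uptake, microbial deconjugation and CA→DCA dehydroxylation,
hepatic first-pass extraction with systemic spillover — is fitted per
subject to plasma concentration time series of six bile acid species
(glycine-conjugated and unconjugated CA, CDCA, DCA) from three repeated
liquid mixed-meal tests.

The central modeling idea: a subject is described by 22 personal
parameters shared across all meals, while only 4 gallbladder emptying
parameters (lag `t_lag`, rate `k_empty`, ejection target `F_eject`,
window duration `T_empty`) may differ from meal to meal. Day-to-day
variation in gallbladder kinetics then suffices to explain intraindividual
variability of the postprandial response, while interindividual
variability maps onto the personal parameters.

The model is a linear mass-balance ODE system
`dy/dt = A(θ) y + s + e(t) E y + b(t) B y`, with a smooth logistic-product
emptying window `e(t)` and refill-bypass window `b(t)`, solved with a
stiff-capable solver (compiled right-hand side and Jacobian, rtol 1e-6).
Estimation minimizes the L1 distance between simulated and measured
concentrations over all species × time points × meals simultaneously, from
25 restarts; practical identifiability is classified from the restart
ensemble (solutions within 25% of the best cost; per-parameter CV < 20%
well identified, > 50% nonidentifiable), and parameters are ranked by
local sensitivity of the total plasma bile acid concentration
(+0.01% perturbations).

## Worked example

```r
library(ehckin)

# a synthetic three-meal cohort with known ground truth
coh <- generate_cohort(cohort_spec(n_subjects = 2, seed = 1))
coh
#> Synthetic mixed-meal-test cohort: 2 subjects x 3 meals x 11 samples (6 species)
#>   396 measurement rows; noise CV 10%; seed 1

# descriptive variability: AUC of the total bile acid pool
subset(variability_report(coh$measurements, metrics = "auc"),
       grouping == "total")[, 3:4]
#>         statistic      value
#>           mean_M1 2247.53319
#>           mean_M2 1737.82896
#>           mean_M3 2090.09324
#>            cv_pct   12.88713
#>       inter_cv_M1   88.52186
#>       inter_cv_M2   40.08944
#>       inter_cv_M3   73.87823
#>     intra_cv_mean   21.91496
#>       intra_cv_lo   -4.54331
#>       intra_cv_hi   48.37323
#>  high_variability    0.00000

# fit a personal model to one subject (restarts reduced for the example)
fit <- ehc_fit(coh$measurements, subject_id = "S1",
               config = fit_config(n_restarts = 5, seed = 2))
fit
#> Personal enterohepatic circulation model fit
#>   subject: S1 | meals: 3 | free parameters: 34
#>   restarts: 5 (5 finite) | best L1 cost: 24.43 umol/L
#>   s_tot = 0.629 umol/min, r_CA = 0.60, F_eject = 0.53/0.46/0.47

identifiability(fit)   # CV_par per parameter across near-optimal restarts
local_sensitivity(fit$subject, fit$meals[[1]])  # ranked process influence
plot(fit)              # data vs fitted total bile acid, one panel per meal
```

The meal-test CV (`cv_pct`, variability of the three meal means) is low
while the interindividual (`inter_cv_M*`, across subjects per day) and
intraindividual (`intra_cv_mean`, across a subject's meals) CVs are high —
the signature pattern of repeated mixed-meal testing. The fitted `F_eject`
values differ between the three meals: the meal-specific gallbladder
parameters absorb the day-to-day variation.

`run_ehc_study()` chains generation → statistics → fitting →
identifiability → sensitivity → recovery-vs-truth into one seeded,
manifest-stamped run.

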