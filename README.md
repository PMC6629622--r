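# capnoseq

State sequence analysis of capnography-derived respiratory monitoring
during procedural sedation.

Sedative and analgesic drugs depress breathing. Capnography records, second
by second, how a sedated patient is ventilating — but summary statistics
such as total apnea time discard the structure of when and for how long
abnormalities occur. `capnoseq` keeps that structure. It is intended for
researchers analysing per-second intra-procedural monitoring data (or
validating methods for such data) and implements the full analysis chain:

1. **Classification.** Every second is assigned one of four respiratory
   states from standard cut-offs: `APNEA` (no waveform or etCO₂ = 0),
   `BRADYPNEA` (rate < 8/min), `HYPOPNEA` (waveform amplitude deviating
   > 10% from the pre-sedation baseline), else `NORMAL`; artifact seconds
   are `MISSING`.
2. **Dissimilarity.** Patients are compared through distances between their
   state occupancy distributions. The default χ² distance
   d(x,y) = √( Σₛ (pₛ(x) − pₛ(y))² / mₛ ) weights each state by the inverse
   of its pooled cohort proportion mₛ, so rare states (bradypnea) matter
   more; a plain Euclidean variant is available. Distances are
   length-invariant, handling variable procedure durations.
3. **Typology.** Ward (D2) hierarchical clustering of the dissimilarity
   matrix, quality report (average silhouette width, point-biserial
   correlation) over k = 2..6, and sequence index plots.
4. **Distance matrix regression.** `mdmr()` fits a multivariable distance
   matrix regression through Gower centering: total pseudo-R² =
   tr(HGH)/tr(G), marginal (drop-one) per-term pseudo-F and pseudo-R², and
   permutation p-values. A bivariate variant tests rare covariates (e.g.
   hypoxemia) separately.
5. **Synthetic cohorts.** `simulate_cohort()` generates per-second
   monitoring streams plus covariate tables from a semi-Markov model with
   known ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(capnoseq)

cohort <- simulate_cohort(cohort_config(n_patients = 102, seed = 1))
seqs   <- build_sequences(cohort$samples)
D      <- seq_dissimilarity(seqs, metric = "chi2")
ty     <- seq_cluster(D, k = 4, seqs = seqs)
ty
#> Respiratory state sequence typology (Ward.D2), k = 4
#>  cluster  n share dominant_state
#>        1 39 0.382         NORMAL
#>        2 44 0.431       HYPOPNEA
#>        3 14 0.137          APNEA
#>        4  5 0.049      BRADYPNEA
#> Average silhouette width 0.966; point-biserial r 0.893
```

Four breathing patterns emerge, each named by its dominant state: 38% of
this simulated cohort breathes normally for most of the procedure, 43% is
dominated by hypopneic hypoventilation, and smaller groups by apnea and
bradypnea. The quality report (`cluster_quality_report(D)`) confirms k = 4
maximises the average silhouette width.

```r
cv  <- derive_covariates(cohort$samples, cohort$covariates)
fit <- bivariate_mdmr(D, cv$hypoxemia_s, n_perm = 999, seed = 2)
fit
#> Multivariable distance matrix regression (permutation inference)
#> n = 102  permutations = 999
#>
#>  term df pseudo_F pseudo_R2 proportion_explained p_value
#>     x  1    0.584     0.006                    1   0.629
#> Total  1    0.584     0.006                    1   0.629
```

Seconds of desaturation explain under 1% of the between-patient sequence
dissimilarity (p = 0.63): oxygenation status tells you little about the
breathing pattern, which is exactly why capnography adds information over
pulse oximetry. The full multivariable model is one call:
`run_pipeline(pipeline_config(synth = cohort_config(n_patients = 102, seed = 1)))`
writes sequences, the distance matrix, cluster labels, the quality report,
sequence index plots and the regression table to an output directory.

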