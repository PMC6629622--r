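---
title: "Respiratory state sequence analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory state sequence analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnoseq)
```

## The problem

During procedural sedation, capnography yields a per-second record of how a
patient is breathing. Summaries such as "minutes of apnea" discard the
structure of *when* and *for how long* abnormalities occur. State sequence
analysis keeps that structure: every second of a procedure is assigned one
of four respiratory states, each patient becomes a categorical sequence, and
patients are compared through pairwise dissimilarities between their
sequences. Clustering the dissimilarity matrix yields a typology of common
breathing patterns, and distance matrix regression asks how much of the
between-patient dissimilarity is attributable to clinical covariates.

## State classification

`classify_states()` maps each monitored second to one state:

| state | criterion |
|---|---|
| `MISSING` | artifact flag set (talking, dislodged sampling cannula) |
| `APNEA` | no capnography waveform, or end-tidal CO~2~ equal to 0 |
| `BRADYPNEA` | capnography-derived respiratory rate < 8 breaths/min |
| `HYPOPNEA` | waveform amplitude deviating more than 10% (either direction) from the pre-sedation baseline |
| `NORMAL` | none of the above |

Precedence is exactly the order of the table. The ordering for co-occurring
criteria is a design choice: an apneic second is apneic regardless of what
the rate or amplitude channel reports, so apnea subsumes rate- and
amplitude-based criteria (severity ordering). Both thresholds are strict
comparisons: a rate of exactly 8 is not bradypnea, a deviation of exactly
10% is not hypopnea. Thresholds are configurable (`rate_cutoff`, `amp_tol`)
but default to these conventional cut-offs. A bedside monitor may only alert
after 10 s of apnea; that is display behaviour, and classification here is
per-second from the first apneic second.

Observer-marked onset/offset intervals are an equivalent input
representation; `expand_intervals()` expands them with a half-open
`[start, end)` convention in 0-based integer seconds, filling unmarked
seconds with `NORMAL` by default (an observer marks abnormalities only).

Artifact seconds are coded `MISSING` and excluded from all occupancy
computations — both numerator and denominator. A redistribution option was
considered and deliberately rejected: redistributing missing time over
observed states silently biases occupancy toward the dominant state.

## Dissimilarity between sequences

Duration — the time spent in states — is treated as the salient feature of
these sequences, rather than the exact timing or ordering of spells. The
dissimilarities are therefore computed from state *occupancy distributions*.
For patient $x$, let $p_{s}(x)$ be the fraction of non-missing seconds spent
in state $s$. With pooled cohort proportions $m_s$ (all patients' seconds
pooled, so longer procedures weigh more), the chi-squared distance is

$$ d_{\chi^2}(x, y) = \sqrt{\sum_s \frac{(p_s(x) - p_s(y))^2}{m_s}}, $$

and the Euclidean distance drops the $1/m_s$ weights. The inverse-marginal
weighting gives rare states (bradypnea in a typical sedation cohort) higher
importance, which is why the chi-squared metric is the package default.
States never observed in the cohort are dropped from the support — they
cannot be weighted by $1/0$ and no sequence has mass there.

Two normalisation conventions make distances comparable across patients and
settings:

* **Unequal lengths.** Distributions are proportions, so repeating a
  sequence (or monitoring twice as long with the same behaviour) does not
  change its distances. This is the operative normalisation for variable
  procedure durations, and it is tested as an invariant.
* **Interval splitting.** `n_intervals = K` splits each sequence into $K$
  equal spans and concatenates per-span distributions, restoring some timing
  sensitivity; distances are then divided by $\sqrt{K}$ so that the
  degenerate case of identical spans reproduces the $K = 1$ value. The
  default is $K = 1$ (whole-sequence distributions). The exact normalisation
  used by other sequence-analysis software is not always documented; the
  convention here is stated so results are reproducible from the definition
  alone.

Both metrics are Euclidean distances in a re-weighted coordinate system, so
symmetry, zero self-distance and the triangle inequality hold exactly; the
test suite checks them on random triples, and checks the algebraic identity
that the chi-squared distance under a uniform marginal over $S$ states is
$\sqrt{S}$ times the Euclidean distance.

## Typology by Ward clustering

`seq_cluster()` applies agglomerative minimum-variance clustering to the
dissimilarity matrix using the **Ward.D2** convention (the Lance–Williams
update on squared dissimilarities), which is the variance-minimising form
when the input is a general dissimilarity rather than raw coordinates. The
tree is cut at `k` clusters; `cluster_quality_report()` tabulates, for
`k = 2..6`, the average silhouette width computed directly from the
dissimilarity matrix and the point-biserial correlation between distances
and the same/different-cluster indicator. The final `k` is a judgment call
informed by that report; the pipeline defaults to `k = 4`, and the report
flags the highest-silhouette `k` as a convention. Each cluster is
auto-labelled by the modal state over its members' seconds, and
`seq_index_plot()` draws the classic one-bar-per-patient colour-coded
rendering, one panel per cluster, sorted within panel by sequence length
(the sort order is a documented convention; any fixed order works).

Degenerate conventions: silhouette widths of singleton clusters are 0, and a
partition of all singletons has average silhouette width 0.

## Distance matrix regression

`mdmr()` regresses the dissimilarity matrix on covariates. With squared
dissimilarities $d_{ij}^2$, Gower centering forms
$G = -\tfrac12 J (D \circ D) J$ with $J = I - \mathbf{1}\mathbf{1}'/n$;
$\operatorname{tr}(G) = \frac1n \sum_{i<j} d_{ij}^2$ is the total
discrepancy $SS_T$. For a design matrix $X$ (intercept included) with hat
matrix $H$, the explained discrepancy is $\operatorname{tr}(HGH)$ and

$$ \text{pseudo-}R^2 = \frac{\operatorname{tr}(HGH)}{\operatorname{tr}(G)},
   \qquad
   \text{pseudo-}F = \frac{SS_{expl}/m}{SS_{res}/(n - m - 1)}, $$

with $m$ the model degrees of freedom excluding the intercept. Per-term
statistics are **marginal (drop-one)**: the explained discrepancy lost when
that term's column block is removed from the full design. Drop-one shares
are order-invariant, unlike sequential decompositions; with correlated
covariates the per-term shares need not sum to the total, which is why the
table also reports each term's share *of* the explained total
(`proportion_explained = pseudo_R2 / total pseudo_R2`).

Inference is by permutation of patient identities of the distance matrix
(equivalently, joint permutation of the design rows): every statistic is
recomputed under `n_perm` permutations and
$p = (1 + \#\{F^{perm} \ge F^{obs}\}) / (n_{perm} + 1)$, the standard
add-one correction that keeps $p$ in $(0, 1]$. Raw identities are permuted
(the simplest exchangeable-null scheme) rather than residuals. The default
is 999 permutations in `mdmr()` and 1000 in the pipeline configuration.

Numerical and design notes:

* Numeric design columns are rescaled to unit variance before the QR
  decomposition; this changes no projection (each term's column space is
  unchanged) and only conditions the factorisation.
* Categorical covariates enter as reference-coded indicator blocks and are
  tested as one term with their block degrees of freedom.
* A constant covariate spans only the intercept: its term is retained in
  the table with zero df, zero pseudo-R² and no test, rather than being a
  rank error. Genuine collinearity between informative terms *is* an error
  naming the terms.
* Rows with missing covariates are dropped listwise together with the
  matching rows/columns of the matrix; the count is recorded in the fit.
* On a matrix of Euclidean distances from one-dimensional data with a
  single binary covariate, the pseudo-F *equals* the classical one-way
  ANOVA F — an exact identity used as a correctness oracle in the tests.

`bivariate_mdmr()` is the intercept-plus-one-covariate special case, used
for the separate hypoxemia test: desaturation is too rare to sit inside the
multivariable model, so its association with the distance matrix is tested
alone.

## The synthetic cohort generator

No patient-level dataset ships with the package, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
with full ground truth for validation. Choices, with defaults:

* **Archetypes.** Each patient draws one of four sequence archetypes —
  dominated by normal breathing, hypopnea, apnea or bradypnea — with
  prevalences 0.41 / 0.37 / 0.15 / 0.07, the typology shape typical of
  sedated cardiac-procedure cohorts.
* **Dynamics.** A semi-Markov chain with geometric dwell times: mean 120 s
  in the archetype's dominant state, 5 s elsewhere, and a 0.7 probability
  of returning to the dominant state after an excursion. Explicit dwell
  distributions (rather than a first-order chain) produce the long
  homogeneous spells that make archetypes visually and statistically
  distinct; geometric dwells keep every derived quantity analytically
  checkable. These defaults produce well-separated archetypes (dominant
  state occupancy around 0.9), which is the regime the recovery experiments
  assume.
* **Durations.** Lognormal, median 30 min (`sdlog` 0.4), floored at 60 s.
  Procedure-duration statistics are rarely published; this is a stated
  convention, not an estimate.
* **Emissions.** State-conditional uniform distributions chosen so the
  classifier recovers the hidden state exactly on artifact-free seconds:
  normal (rate 10–18, amplitude 0.905–1.095), hypopnea (amplitude below
  0.885 or above 1.115), bradypnea (rate 3–7.9), apnea (no waveform,
  etCO~2~ 0). Supports sit strictly clear of the cut-offs (8 breaths/min,
  ±10%) so no boundary draw can flip a label.
* **Oxygenation.** Per-patient SpO~2~ level N(98.0, 0.8) plus per-second
  N(0, 0.65) noise, giving a median patient roughly 93% of pulse-valid time
  above 97% (predominant hyperoxia under prophylactic oxygen); 3% of
  patients receive one 31–80 s desaturation episode below 90%.
* **TcCO~2~.** A stabilized baseline N(37.5, 4.5) ramping toward a peak
  that rises weakly with total abnormal-breathing time (0.0015 mmHg per
  abnormal second, noise sd 3), so CO~2~ retention is associated with — but
  far from determined by — the sequence pattern.
* **Covariates.** OSA, smoking and comorbidity burden shift archetype
  membership through a multinomial logit with small standardized
  coefficients; the intercepts are calibrated so the marginal archetype
  probabilities equal the configured prevalences exactly, which keeps
  frequency tests unbiased. The coefficients are tuned so per-covariate
  pseudo-R² lands in the few-percent range — tuning constants, not
  estimates. Interventions to support respiration attach preferentially to
  apnea seconds through a logit on apnea time (marginal rate ≈ 13%).

What the generator does **not** emulate: capnogram waveform morphology,
pharmacokinetic dose–response, autocorrelated measurement noise, informative
artifact patterns, or any within-state nonstationarity. Passing recovery
tests on these cohorts therefore demonstrates that the pipeline's machinery
is correct under its own assumptions — not that real sedation cohorts are
this well separated. On real data the archetype blobs will overlap more and
the typology will be correspondingly fuzzier.

## Problem sizes used in validation

The test-suite experiments use cohorts of 100–500 patients (2000 for the
prevalence-convergence check), 50 seeds for the typology-recovery and
model-selection experiment at n = 200, 1000 simulated null datasets of 20
patients at 199 permutations each for the calibration check, and 100 seeds
at three effect levels for power monotonicity. These sizes give the checks
comfortable statistical resolution (binomial standard errors of 1–3% on
rates) while keeping a full run fast on a single core.

## Known limitations

* The chi-squared normalisation convention (proportion-based distributions
  plus the $\sqrt{K}$ interval factor) is stated, but other software may
  normalise differently; numerical identity with any particular external
  implementation is not asserted.
* Drop-one term shares are one of several defensible partitioning schemes;
  sequential (Type-I-like) shares would differ with correlated covariates.
* The permutation scheme treats patients as exchangeable under the null;
  stratified or residual permutation schemes are out of scope.
* With `n_intervals > 1`, a span consisting entirely of artifact seconds is
  an error rather than being bridged; sequences with heavy artifact load
  should be inspected before analysis.
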