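---
title: "Discovering and evaluating clinical subtypes of Alzheimer's disease from EHR features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and evaluating clinical subtypes of Alzheimer's disease from EHR features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alzheimer's disease (AD) is clinically heterogeneous: patients differ in
symptom mix, comorbidity burden, age of onset and rate of progression.
Primary-care electronic health records (EHR) describe the whole clinical
course of a patient — symptoms, comorbidities, demographics, prescriptions,
service use — as coded events, which makes them a natural substrate for
subtype discovery at scale. `adsubtype` implements a complete pipeline for
this task: it turns longitudinal coded event tables into a binary clinical
feature matrix, embeds the matrix with multiple correspondence analysis
(MCA), partitions patients with four clustering algorithms, and subjects
every solution to a four-way evaluation — structure, stability,
replicability and clinical utility — before comparing solutions across
methods.

Because real primary-care extracts are access-restricted, the package ships
a synthetic cohort generator with planted latent subtypes and
class-dependent outcomes. Every stage of the pipeline is exercised end to
end on generated data; nothing in the package requires a data download.

## Feature construction

The input schema is two delimited tables: events
(`patient_id, code, date`) and demographics (`patient_id, birth_year,
gender, practice_id, smoking, drinking`). Cohort inclusion
(`select_cohort()`) requires a diagnosis event, recorded birth year and
gender, age at diagnosis of at least 40, at least one year of observation
on both sides of the diagnosis date, and at least one recorded symptom or
comorbidity. Every exclusion is counted and attached to the returned
cohort, so a run can be audited filter by filter.

Symptoms are subject to two temporal attribution rules
(`attribute_symptoms()`): a symptom counts only if its earliest record
falls *strictly after* the diagnosis date, and only if no explaining
comorbidity (for example a depression diagnosis before a depression
symptom) precedes that record. A symptom coded on the diagnosis day itself
is not attributed — the inclusive/exclusive choice at the boundary is not
dictated by the source procedures, and the strict rule is the conservative
one. Attribution is monotone by construction: deleting an explaining
comorbidity can only turn flags on, never off.

Raw symptoms are collapsed into four categories (memory, confusion,
neuropsychological, motor) because most raw symptoms are individually rare.
Confusion appears both as its own category and, in some published
groupings, inside the neuropsychological list; the default keeps it
separate (`confusion_in_neuropsychological = FALSE`) because double
counting one raw flag in two categories makes the categories collinear by
construction, which MCA would faithfully but uselessly encode.

Comorbidities count only when recorded strictly before diagnosis, so that
features reflect antecedent conditions rather than consequences of the
disease. With the default dictionary the matrix has 21 parent variables:
4 symptom categories, 13 comorbidities (hypercholesterolemia is excluded
for its very low recorded prevalence) and 4 demographic variables — age at
diagnosis banded into quintiles (42–73, 74–78, 79–82, 83–87, 88+), gender,
smoking and drinking status. Missing smoking is coded "non-smoker";
missing drinking is its own "not specified" level, as in the underlying
lifestyle phenotypes. The banding uses fixed published quintile edges
rather than recomputed quantiles so that synthetic runs and real runs band
identically.

## MCA

`fit_mca()` performs correspondence analysis of the full indicator matrix:
binary parents are expanded into explicit yes/no column pairs so that every
parent contributes a one-hot group summing to 1 per row. The standardized
residual matrix is decomposed by SVD with row and column masses, and
patients are returned in principal coordinates, where Euclidean distance
approximates the chi-square distance between patient profiles. Two checks
are built into the tests: the sum of principal inertias equals `J/Q - 1`
(`J` categories, `Q` parents), and full-rank coordinates reproduce
chi-square row distances to 1e-8.

Design choices that were genuinely open:

* **Indicator-matrix MCA, no inertia correction by default.** Benzécri
  re-weighting is available (`correction = "benzecri"`) but changes only
  the reported inertia fractions, and the uncorrected fractions feed the
  component-selection elbow. The source procedure does not state a variant.
* **Component selection** (`select_components()`) locates the elbow of the
  explained-inertia profile as the maximum second difference
  `f(i) - 2 f(i+1) + f(i+2)` — the discrete analogue of "the point at which
  the gain per component collapses". A curvature-free profile returns one
  component with a warning rather than an arbitrary cut.
* **Sign convention**: the first nonzero column loading of each component
  is forced positive, so coordinates are reproducible across platforms.

## The four clustering methods

* **k-means** (`run_kmeans()`): Lloyd iterations on the MCA coordinates,
  100 random restarts, keeping the restart with the lowest total
  within-cluster sum of squares. `select_k()` scans k = 2–14 by default
  and applies three rules — the WSS elbow (maximum second difference),
  maximum mean silhouette, and minimum BIC — choosing k by majority vote
  with silhouette as the tie-break. BIC uses the spherical-Gaussian
  reading of k-means (shared variance `WSS / (d(n-k))`, `k(d+1)`
  parameters), since no formula is prescribed for k-means model selection.
* **Kernel k-means** (`run_kernel_kmeans()`): the same Lloyd scheme in the
  feature space of a Hamming-distance kernel
  `K(x,y) = exp(-gamma * d_H(x,y))`, computed on the raw one-hot matrix
  without MCA. `d_H` counts disagreeing parent variables; the exponential
  of a negative conditionally-negative-definite distance is positive
  semidefinite, so the kernel is valid for any `gamma > 0`. The default
  `gamma = 1/Q` makes the exponent the fraction of disagreeing variables.
  The cited kernel family is not parameterised precisely in the source, so
  the package states its exact form and exposes `gamma`. With a linear
  kernel the updates reduce algebraically to plain k-means, and the test
  suite asserts exact label agreement from a shared initialisation.
* **Affinity propagation** (`run_affinity_propagation()`): standard
  damped responsibility/availability message passing over the negative
  squared Euclidean similarity of MCA coordinates. Defaults — damping 0.9,
  1000 maximum sweeps, convergence after 50 sweeps of an unchanged
  exemplar set — are unstated in the source and follow common practice.
  `sweep_preference()` varies the preference over a grid from the minimum
  to the median off-diagonal similarity, records (preference, K, net
  similarity), and picks the elbow of net similarity versus K.
* **Latent class analysis** (`run_latent_class()`): EM over k = 2–8 with
  BIC selection (`-2 logL + p log n`) and maximum-posterior assignment.
  The source applies MCA *before* LCA, which conflicts with classical
  categorical LCA; both readings are provided. The default, matching that
  order, models the MCA coordinates as a diagonal-covariance Gaussian
  mixture; `mode = "bernoulli"` runs classical LCA with independent
  Bernoulli indicators on the raw one-hot matrix. EM converges at a
  log-likelihood tolerance of 1e-6 (at most 500 iterations); a start whose
  smallest expected class count falls below one patient is discarded as
  degenerate and redrawn; variances are floored at 1e-6 to avoid
  singularities.

Determinism is enforced everywhere: all methods take a seed, ties in
assignment go to the lowest cluster index, and re-running with the same
seed reproduces labels exactly.

## Evaluation framework

* **Structure** — mean silhouette over the embedded points;
  `s(i) = (b - a)/max(a, b)`, singletons score 0. Values below the
  conventional 0.25 mark are flagged as "no substantial structure".
* **Stability** (`bootstrap_stability()`) — 100 bootstrap resamples,
  re-clustering each with frozen hyperparameters; for every original
  cluster the maximum Jaccard overlap with any bootstrap cluster is taken
  on unique resampled indices (clusterwise matching, the established
  bootstrap-stability scheme; a one-to-one assignment variant is available
  via `matching = "assignment"`). The mean over clusters and bootstraps is
  reported with the conventional 0.75 stability threshold.
* **Replicability** (`replicability()`) — a classification tree is trained
  on the training features against cluster membership, with an internal
  80/20 split selecting the cost-complexity pruning level; the tree labels
  a held-out set (the "gold standard"), the clustering procedure is run
  independently on that set, and the aligned label agreement is the
  concordance. The held-out set is either the 25%-of-practices split
  (`split_by_practice()`, test practices = `ceiling(fraction * P)`) or a
  second cohort drawn independently from the generator. The denominator is
  all held-out patients; there are no abstentions.
* **Clinical utility** (`utility_comparison()`) — for each single feature
  and for cluster membership: a univariable linear model for the MMSE
  decline slope (reported as adjusted R²) and a univariable Cox model for
  time to assisted living (Breslow ties; reference level = largest
  cluster). If cluster membership outranks every individual feature on
  both criteria, the partition carries more predictive value than any one
  variable. Per-factor models are univariable throughout, matching the
  comparison's purpose of ranking single predictors against the partition.

Label switching is handled by `align_labels()`, an exact maximum-agreement
assignment on the contingency table (bitmask dynamic programming;
rectangular cases leave unmatched clusters with fresh labels). All metrics
are invariant to relabeling, which the tests verify by permutation.

## Outcomes

Five clinical outcomes validate (never define) the clusters: per-patient
MMSE decline slope (OLS over all dated scores; equal to the two-point slope
when only two exist), time from diagnosis to assisted living, time on
cholinesterase inhibitors anchored at diagnosis, consultation and missed
appointment rates, and all-cause mortality. Survival endpoints use the
Kaplan–Meier product limit with Greenwood (plain) 95% intervals, log-rank
tests across clusters, and Cox proportional hazards for the utility
comparison. Interval captions in the source are read as 95% confidence
intervals; means use normal-approximation intervals.

## The synthetic cohort generator

`generate_cohort()` draws patients from a mixture of `subtype_profile`
objects: per-class comorbidity and symptom-category probabilities, age-band
/ gender / smoking / drinking distributions, and outcome parameters (MMSE
decline mean and SD, exponential hazards for assisted living and death, a
Poisson consultation rate, a ChEI duration mean). Events are emitted in the
shape the feature stage expects — comorbidities strictly before diagnosis,
raw symptoms strictly after — and a configurable fraction of patients
(default 5%) receive a contaminating pre-diagnosis comorbidity that
explains one of their symptoms, so the explained-symptom rule is exercised
with known ground truth. Outcomes (`generate_outcomes()`) follow the
simplest models consistent with the downstream analyses: exponential event
times right-censored at end of follow-up, one MMSE visit just before
diagnosis then annual visits with Gaussian measurement noise, Poisson
counts, and normally distributed ChEI durations truncated at zero.

No generative model of the real cohort exists, so all distributional
choices are stand-ins. Two configurations ship with the package:

* `default_profiles()` — five classes mirroring reported subtype patterns
  (anxiety/depression/early-onset/smoking with a threefold decline rate;
  typical AD with hypertension and kidney disease; typical AD with cancer
  and hearing loss, mostly male; non-typical AD; cardiovascular disease
  with hypertension spared), with non-signature features at cohort-like
  baseline prevalences. This is the noisy, realistic regime: under it the
  pipeline recovers the planted partition only approximately, which is
  itself informative about what EHR feature noise does to subtype
  recovery.
* `separated_profiles()` — the same class themes with signature blocks at
  probability 0.9 against baselines of at most 0.10, i.e. every class pair
  differs on several parents with gaps of at least 0.6. This is the regime
  the recovery benchmarks specify, and in it k-selection chooses k = 5 and
  the adjusted Rand index exceeds 0.9 at n = 2,000.

What passing tests on generated data do **not** show: robustness to
real-world coding idiosyncrasies (code-list drift, practice-level recording
habits, informative missingness beyond the simple missing-category
mechanisms modelled here), to non-exponential event-time shapes, or to
feature dictionaries other than the default. The generator produces
independent features within class; real comorbidities are correlated even
conditional on subtype.

## Problem sizes and runtime choices

The shipped defaults are sized for a single CPU: demo studies use
n = 2,000 patients; kernel k-means and affinity propagation — the two
O(n²)-per-iteration methods — run model selection and bootstrap stability
on configurable subsamples (defaults 800 and 600) with reduced restart and
bootstrap counts, while k-means and LCA use the full training set and 100
bootstraps. All of these are explicit `run_study()` configuration entries,
and the summary reports the sizes actually used. The test suite and the
acceptance script size their simulations the same way (recovery and
utility at n = 2,000; calibration nulls at 200 replicates; survival power
at 500 per arm).

## Known limitations

* Assisted-living detection in real data relies on address-change
  heuristics that are out of scope; the synthetic outcomes carry explicit
  event times instead.
* The consistent-cluster rule (intersection of signature-matching cluster
  memberships across methods) is one reasonable reading of a procedure
  whose union/intersection semantics are not fully specified; it is
  deliberately strict.
* Cluster naming is a convenience built from significantly deviating
  features under Bonferroni control (chosen over FDR so that names stay
  conservative); it is not a clinical assignment.
* The discrete elbow rules replace visual judgements; they reproduce the
  judgement on clean profiles but can differ on flat ones, which is why
  every selection report carries its full curves.
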