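# adsubtype

Discovery and evaluation of clinical subtypes of Alzheimer's disease (AD)
from primary-care electronic health records (EHR).

AD is clinically heterogeneous — patients differ in symptom mix,
comorbidity burden, onset age and progression rate — and coded EHR data
describe the whole clinical course at population scale. `adsubtype` is an R
implementation of a complete subtyping pipeline for such data, aimed at
health-informatics and biostatistics researchers:

1. **Features.** Longitudinal event tables (`patient_id, code, date`) are
   turned into a binary patient × feature matrix under explicit temporal
   rules: symptoms count only when first recorded strictly after diagnosis
   and not explained by a prior comorbidity; comorbidities count only when
   recorded strictly before diagnosis. With the default dictionary the
   matrix has 21 parent variables: 4 grouped symptom categories (memory,
   confusion, neuropsychological, motor), 13 comorbidities, and one-hot
   age-band / gender / smoking / drinking demographics.
2. **Embedding.** Multiple correspondence analysis (MCA) of the indicator
   matrix: SVD of the standardized residuals `D_r^{-1/2}(P - rc')D_c^{-1/2}`,
   returning patients in principal coordinates where Euclidean distance
   approximates chi-square profile distance.
3. **Clustering.** Four methods with their model-selection procedures:
   k-means (best of 100 restarts; k chosen by WSS-elbow / silhouette / BIC
   majority vote), kernel k-means with a Hamming-distance kernel
   `K(x,y) = exp(-γ d_H(x,y))` on the raw one-hot data, affinity
   propagation with a preference sweep and net-similarity elbow, and latent
   class analysis by EM with BIC selection over 2–8 classes.
4. **Evaluation.** Cluster structure (silhouette `s = (b-a)/max(a,b)`),
   bootstrap stability (clusterwise maximum Jaccard over 100 resamples,
   0.75 stability convention), replicability (decision-tree label transfer
   to held-out practices or a second cohort, reported as % concordance)
   and clinical utility (adjusted R² for MMSE decline and Cox fits for
   time to assisted living, cluster membership versus every single
   feature).
5. **Comparison.** Cluster characterisation by Bonferroni-controlled
   two-proportion tests against the cohort, alluvial flow tables across
   methods, and consistent-cluster detection by feature signature.

Because real extracts are access-restricted, the package includes a
synthetic cohort generator (`generate_cohort()`) with planted latent
subtypes and class-dependent outcomes (MMSE decline, assisted living,
death, consultations, time on cholinesterase inhibitors); the whole
pipeline is developed and tested against it.

## Worked example

```r
library(adsubtype)

ch <- generate_cohort(separated_profiles(), n_patients = 1000,
                      n_practices = 10, seed = 42)
fx <- extract_features(ch$events, ch$demographics)
fm <- fx$features
#> Feature matrix: 1000 patients x 32 columns ( 21 parent variables )

m <- fit_mca(fm)
coords <- m$row_coordinates[, 1:select_components(m)]   # 4 components

ks <- select_k(coords, 2:8, n_restarts = 50, seed = 42)
#> k selection over k = 2-8 -> chosen k = 5 (majority)
#>   picks: wss elbow 5 | silhouette 5 | BIC 5

sol <- run_kmeans(coords, ks$chosen_k, n_restarts = 100, seed = 42)
truth <- ch$truth$class_id[match(fm$patients, ch$truth$patient_id)]
adjusted_rand(truth, sol$labels)
#> 0.958

st <- bootstrap_stability(coords,
        function(x, s) run_kmeans(x, 5, 20, seed = s)$labels,
        n_bootstraps = 50, seed = 42)
#> Bootstrap stability (50 resamples): mean Jaccard 0.997 [stable at 0.75]

characterize(fm, sol$labels)
#> Cluster characterisation (bonferroni, alpha = 0.05, family = 160 tests):
#>   cluster 1: anxiety + depression + smoking:current smoker (17 significant features)
#>   cluster 2: heart_failure + atrial_fibrillation + haemorrhagic_stroke (16 significant features)
#>   cluster 3: Typical AD (16 significant features)
#>   cluster 4: Non-typical AD (19 significant features)
#>   cluster 5: Typical AD (17 significant features)
```

Reading the output: the five planted classes are recovered almost exactly
(adjusted Rand index 0.96), the solution is highly stable under
bootstrapping (mean Jaccard 0.997, far above the 0.75 stability
convention), and the characterisation names the familiar clinical
patterns — an anxiety/depression/smoking cluster, a cardiovascular
cluster, a non-typical cluster (non-memory symptoms elevated), and two
typical-AD clusters whose memory-dominant symptom profile is identical but
which separate on comorbidities.

The full study — simulation, features, train/test split by practice, MCA,
all four methods, the four evaluation measures, outcomes and cross-method
comparison — runs from one config:

```r
run_study(list(seed = 1), out_dir = "my-run")   # writes summary.json etc.
```

or from the shell via `inst/scripts/adsubtype-run.R`
(`simulate` / `run-all` subcommands).

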