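# posturekit

Markerless posture analysis from pose-estimation landmarks, in R.

Clinical posture assessment has traditionally relied on visual inspection
or laboratory motion capture. Markerless pose estimation offers a middle
path: from three standing photographs (frontal, dorsal, lateral) a
33-keypoint pose model (MediaPipe Pose / BlazePose-style) emits labelled
landmark coordinates, and posture
can be quantified objectively from those coordinates alone. `posturekit`
implements that pipeline for researchers in biomechanics, physiotherapy,
and ergonomics: it consumes per-subject landmark records (the core never
touches images) and produces normative-style statistical reports and an
unsupervised posture classification.

## What it computes

**Postural parameters.** Per subject and session, 22 parameters in four
families: seven body-joint angles (e.g. shoulder adduction = angle between
shoulder→elbow and shoulder→hip; elbow extension = 180° − the angle at the
elbow), computed on (x, y, z) per side and per coronal view and fused by
the circular mean; seven horizontal inclinations (acute angle of each
bilateral landmark line against the image horizontal); four vertical
inclinations (neck and trunk lean from the lateral view, whole-body
imbalance and leg inclination from the coronal views); and four body
vectors in pixel distance (torso, total arm, total leg, shoulder−hip
width difference).

**Inferential layer.** Shapiro–Wilk-gated two-group tests (Student's
pooled-variance *t* or Mann–Whitney U), Cohen's d with the
average-variance denominator

    d = (x̄_b − x̄_a) / sqrt((s_a² + s_b²) / 2),

Pearson height–posture correlations with the relevance rule
(*p* < 0.05 and r > 0.45), and test–retest reliability as ICC(3,k)
(two-way mixed effects, consistency, average measures) with
SEM = s·√(1 − ICC) and MDC95 = 1.96·√2·SEM.

**Multivariate layer.** Covariance PCA with variance-retention component
selection (default 90%), five clustering algorithms (k-means, mean-shift,
Ward/complete/average linkage) in the retained score space, silhouette and
elbow model selection, and a cluster-stratified re-comparison of every
parameter.

**Synthetic cohort.** Because the study-style landmark data are not
publicly deposited, the package includes a first-class generator: sex-
specific parameter distributions, a sex-independent two-cluster mixture
of the body vectors, a height–vector latent coupling, ICC-calibrated
session noise, and a forward stick-figure synthesizer whose three-view
projections invert the geometry *exactly* at zero landmark jitter. Every
stage of the pipeline is testable end to end without any download.

## Worked example

```r
library(posturekit)

spec <- synthetic_spec(n_subjects = 40, n_retest = 20)
g <- generate_cohort(spec, seed = 42)
g$cohort
#> <posture_cohort> 40 subjects, 180 captures (synthetic seed=42)

profiles <- profile_cohort(g$cohort)
round(profiles[1:3, c("shoulder_adduction", "hip_adduction",
                      "neck_inclination", "torso_vector")], 1)
#>   shoulder_adduction hip_adduction neck_inclination torso_vector
#> 1               15.1           7.8             15.7        225.4
#> 2               14.6           6.3             17.4        242.4
#> 3               13.2           8.7             17.0        291.7

subset(sex_comparison_table(profiles), parameter == "hip_adduction")
#>      parameter mean_men sd_men mean_women sd_women p_value   d
#>  hip_adduction      9.3   1.93       7.33     1.64 0.00127 1.1

subset(reliability_table(profiles), parameter == "shoulder_adduction")
#>           parameter  n k icc_3k  sem mdc95
#>  shoulder_adduction 20 2  0.932 0.52  1.44

x <- as.matrix(profiles[profiles$session == 1, posture_parameters()])
pca <- run_pca(x)                     # covariance PCA
round(pca$variance_ratio[1:3], 3)
#> [1] 0.794 0.098 0.067                # two components pass 90%

cl <- cluster_scores(pca$scores[, 1:select_components(pca, 0.9)],
                     method = "meanshift")
cl
#> <cluster_result> meanshift: 2 clusters, silhouette 0.612
table(recovered = cl$labels, truth = g$truth$subjects$cluster)
#>          truth
#> recovered  1  2
#>         1 20  0
#>         2  0 20
```

Hip adduction separates men and women with a large effect (d ≈ 1.1 at
this small n; ~1.6 at the full study size), shoulder adduction is highly
reliable across sessions (ICC 0.93, a minimal detectable change of about
1.4°), and mean-shift on the first two principal components recovers the
generated two-cluster body-vector structure perfectly — the cluster split
is driven by segment lengths, not by sex.

## The analysis workflow

The study replica runs as numbered drivers over the package:

```sh
Rscript analysis/01_generate_cohort.R   # 200 subjects, 90 retest -> results/cohort/
Rscript analysis/02_extract_profiles.R  # landmarks -> results/profiles.csv
Rscript analysis/03_group_statistics.R  # sex table, correlations, reliability
Rscript analysis/04_pca_clustering.R    # PCA, five clusterings, cluster table
```

`run_full_analysis()` performs the same stages in one call on any cohort
(read from CSV/JSON via `read_captures()` or generated) and writes the
full artifact set plus a JSON run manifest.

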