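Package: posturekit
Title: Markerless Posture Analysis from Pose-Estimation Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 23 postural parameters (joint angles, horizontal and
    vertical inclinations, and pixel-distance body vectors) from 33-keypoint
    pose-landmark records of frontal, dorsal, and lateral standing
    photographs, with circular-mean fusion of the coronal views. Provides the
    accompanying inferential layer (Shapiro-Wilk gating, Student's t /
    Mann-Whitney U, Cohen's d with the average-variance denominator, Pearson
    height correlations, ICC(3,k), SEM, MDC95), a PCA and clustering layer
    (k-means, mean-shift, Ward/complete/average linkage, elbow and silhouette
    model selection) for discovering sex-independent posture clusters, and a
    forward stick-figure cohort synthesizer whose captures invert the
    geometry exactly at zero noise, so the full pipeline is testable without
    photographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
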