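Package: perioFD
Title: Fractal-Dimension Analysis of Trabecular Alveolar Bone for
    Periodontitis Staging
Version: 0.1.0
Authors@R:
    person("perioFD", "Maintainers", email = "periofd@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify cancellous (trabecular) alveolar bone
    texture on intraoral periapical radiographs and relate it to
    periodontitis severity. Implements the White-Rudolph radiographic
    preprocessing sequence (Gaussian blur, background subtraction with a
    gray offset, binarization, morphological cleanup, skeletonization),
    box-counting fractal-dimension estimation with log-log least-squares
    regression, percent radiographic bone loss from anatomical landmarks
    (CEJ, defect base, root apex), cohort statistics (Kruskal-Wallis,
    chi-square independence, Pearson correlation, Shapiro-Wilk, pooled
    summaries, noncentral chi-square power analysis), ROC analysis with
    Youden-optimal cutoffs and exact binomial confidence intervals, and a
    fractal-dimension-based periodontitis stage classifier. A synthetic
    module generates analytic fractal fixtures, trabecular radiograph
    phantoms, and simulated cohorts so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
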