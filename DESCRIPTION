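Package: ciliaprof
Title: Time-Course Expression Profiling of Ciliogenesis Induction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for five-point FPKM time courses collected
    during flagellar regeneration. Classifies genes as up-regulated,
    down-regulated, unchanged or not expressed by fold-ratio thresholds,
    clusters up-regulated expression profiles by fuzzy k-means with an
    adaptive membership cutoff, merges clusters on a single-linkage tree of
    Pearson correlations between mean profiles, assigns every up-regulated
    gene to a final cluster or an outlier bucket, labels clusters with one of
    sixteen principal induction patterns in five pattern groups, and compares
    the up-regulated set against reference gene lists. Includes a synthetic
    time-course generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    jsonlite
Config/testthat/edition: 3
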