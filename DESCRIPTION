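Package: eegpheno
Title: Digital EEG Phenotyping and Stratification of tDCS Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised stratification of individuals into digital EEG
    phenotypes from resting-state relative band power, and labeling of each
    phenotype cluster as a positive, negative or non-responder to transcranial
    direct current stimulation (tDCS). Provides a synthetic cohort generator
    with planted spectral phenotypes and cluster-linked behavioral effects, an
    EEG preprocessing and feature-extraction chain (FIR band-pass, detrending,
    channel exclusion, Cz re-referencing, amplitude-based epoch rejection,
    per-epoch relative band power, median aggregation), fuzzy c-means and
    normalized-Laplacian spectral clustering with prototype-based soft
    memberships and internal validity indices, covariate-adjusted partial
    Spearman correlation of cluster memberships with active-sham behavioral
    differences (Benjamini-Hochberg corrected) confirmed by rank-sum tests,
    and hold-out robustness analyses for both the clustering and the
    correlational stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    mclust,
    signal,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
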