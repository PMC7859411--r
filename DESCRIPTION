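Package: chordomics
Title: Somatic Genome Characterization for Low-Mutation-Burden Tumor Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the somatic genome of whole-genome-sequenced tumor
    cohorts with low mutation burden, as found in skull-base chordoma.
    Implements ensemble variant-retention filtering and tumor mutational
    burden; tumor-purity estimation from copy-neutral SNV allele counts by an
    ordered binomial mixture fitted with EM and selected by BIC; the
    allele-specific copy-number landscape (five-state classification,
    arm-level event calls, whole-genome doubling, length-weighted CN-state
    distance and elbow-selected hierarchical clustering); high-confidence
    chromothripsis calling from interleaved structural variants with
    oscillating copy-number states; and driver-marker survival stratification
    with covariate-adjusted proportional-hazards models, mutual-exclusivity
    tests, Bonferroni arm scans and paired-sample shared-alteration
    fractions. A synthetic-cohort generator with known truth supports
    end-to-end testing without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SomaticMutation, Survival, StructuralVariation
RoxygenNote: 7.3.3
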