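Package: polyqvoc
Title: PolyQ Repeat Quantification in FOXP Proteins and Vocalization
    Frequency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the two major polyglutamine (polyQ) repeats (Q1 and
    Q2) flanking the conserved hinge peptide of FOXP2 and FOXP1 orthologs,
    using hinge-anchored repeat calling with proline-interruption and
    single-histidine tolerance rules. Computes the Q1+Q2 sum and Q1/Q2
    ratio, classifies species into vocalization classes by published
    repeat-length thresholds (echolocation call types in bats, mammal-wide
    ratio bands), and relates repeat metrics to vocalization and hearing
    phenotypes through binned group-mean Pearson correlations and one-way
    ANOVA with Student-Newman-Keuls post hoc comparisons. Also implements
    the quantification formulas for the accompanying molecular assays:
    circular dichroism mean residue ellipticity and spectral features,
    FRAP double normalization and single-exponential recovery fitting,
    dual-luciferase normalization, condensate relative area, and cochlear
    landmark ratios. A synthetic-data module generates sequences, species
    panels, and assay fixtures with ground-truth tables for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
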