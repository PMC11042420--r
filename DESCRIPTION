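Package: organfield
Title: Whole-Organ Mutational Field-Effect Mapping and Clonal Chronology
Version: 0.1.0
Authors@R: person("OrganField", "Developers", email = "organfield@example.org",
    role = c("aut", "cre"))
Description: Analysis of whole-organ mucosal mutation maps: spatial
    alpha/beta/gamma clonality classification of variants from per-field
    variant allele frequencies, trinucleotide mutational-signature
    deconvolution by simplex-constrained least squares with bootstrap
    significance, maximum-parsimony clonal trees rooted at the unmutated
    ancestral state, a time-continuous branching process with Poisson
    immigration that converts sorted field VAF profiles into per-mutation
    proliferation rates and ages, and downstream omics scoring
    (half-minimum imputation, differential and monotonic-trend filters,
    single-sample set enrichment).  Includes a synthetic whole-organ
    generator with known ground truth used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
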