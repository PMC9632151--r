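Package: hervtools
Title: Locus-Specific Detection and Association Analysis of Expressed
    Endogenous Retroviruses
Version: 0.1.0
Authors@R:
    person("HERV", "Toolkit Authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate human endogenous retrovirus (HERV) transcript
    loci from assembled-transcript alignment summaries, classifies them by
    genomic location (antisense, intergenic, inserted) and retroviral origin
    (solo-LTR, truncated, chimeric, full-length with four subtypes), calls
    per-body-site expression, maps cis expression quantitative trait loci
    with presence-aware genotyping and permutation-based empirical p-values,
    runs matched-background variant enrichment, and tests epigenetic (histone
    peak, DNA methylation) and biological-factor (sex, ethnicity, age)
    associations.  A seeded synthetic-data generator emulates every input
    with machine-readable truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
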