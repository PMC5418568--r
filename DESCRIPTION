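Package: mmrscreen
Title: Mismatch-Repair Deficiency Screening, Etiology Classification and
    Founder-Variant Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for universal tumour screening studies of Lynch syndrome in
    population-based colorectal cancer cohorts. Implements the
    immunohistochemistry panel and scoring logic for the four mismatch-repair
    proteins, quantitative MLH1 promoter-methylation calling with a BRAF-V600E
    reflex rule, tumour-sequencing interpretation (microsatellite-instability
    calling from an instability score, loss-of-heterozygosity banding from
    variant allele fractions, and double-somatic resolution rules), the full
    per-case etiology cascade with screening-performance and prevalence
    arithmetic, case-control logistic association for rare founder variants
    with genomic-inflation correction and odds-ratio to lifetime-risk
    conversion, and a discordant read-pair scanner that infers translocation
    breakpoints and their micro-event anatomy from soft-clipped reads.
    Includes seeded generators for synthetic cohorts, case-control genotype
    tables and paired-end reads spanning a reciprocal translocation, plus a
    deterministic fixture cohort reproducing the published study marginals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    IRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
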