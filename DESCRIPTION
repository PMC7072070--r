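Package: flocus
Title: Copy-Number Dynamics of the Cucumber Femaleness (F) Locus
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the cucumber F locus as a tandem-repeat copy number
    variant whose meiotic instability arises from unequal crossing over
    (UCO). Builds annotated synthetic haplotype sequences for monecious,
    gynoecious and triple-repeat lines (including the recombinant
    BCAT-derived distal promoter of CsACS1G) and runs in-silico PCR
    against them; simulates meiosis with UCO, selfing and crosses over
    generations, and maps genotypes to sex phenotypes by CsACS1G dosage;
    estimates repeat copy number from windowed read depth and from
    genomic qPCR delta-Ct normalisation; and provides the segregation
    statistics (chi-square goodness of fit, exact binomial mutation-rate
    intervals, Welch tests, UCO-rate calibration) needed to reproduce
    dosage-dependent Mendelian segregation in gynoecious cucumber.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
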