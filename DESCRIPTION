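Package: alkaneSIP
Title: DNA Stable-Isotope Probing Analysis of Gaseous-Alkane Degraders
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying active gaseous-alkane (ethane/propane)
    degrading bacteria from DNA stable-isotope probing (SIP) experiments.
    Provides a forward simulator of CsCl isopycnic gradient SIP experiments
    with full ground truth, refractive-index to buoyant-density conversion
    and heavy/light fraction pooling, a three-criterion classifier of
    13C-labelled taxa, headspace gas consumption accounting, pairwise
    alignment utilities, genome relatedness indices (fragment-based ANI,
    reciprocal-best-hit AAI, tetranucleotide signature correlation) with
    species-delineation calls, MAG quality filtering and dereplication, and
    a soluble di-iron monooxygenase (SDIMO) marker screen with
    fragment-recruitment abundance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
SystemRequirements: NCBI BLAST+ (makeblastdb, blastn, blastp) on the PATH
    for ANI/AAI, marker screening and fragment recruitment.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
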