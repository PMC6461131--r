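Package: oreo
Title: Reference-Bias-Aware Variant and Heteroplasmy Calling for
    Overlapping-Amplicon Mitochondrial DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling variants and quantifying point heteroplasmy
    from single-multiplex overlapping-amplicon massively parallel sequencing
    of the human mtDNA control region. PCR primers designed from the
    reference sequence leave reference alleles at read ends and, in
    single-reaction chemistries, inside read bodies, biasing allele
    fractions at sites under primer-binding regions. The package implements
    the Overarching Read Enrichment Option (OREO): equal-length
    allele-specific in-silico probes that span amplicon ends are matched
    exactly against reads so that only overarching reads - which carry
    genuine template sequence across the primer site - are counted. It also
    provides circular rCRS coordinate arithmetic, amplicon/segment coverage
    models with boundary detection and low-coverage flagging, tiered
    threshold classification of sites (homoplasmic, heteroplasmic,
    uncallable), in-silico size selection, screening for nuclear
    mitochondrial insertion (numt) reads via diagnostic sites, and a seeded
    amplicon read simulator that reproduces the primer-derived bias
    mechanisms as ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
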