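Package: strainlift
Title: Reconciling Draft and Complete Bacterial Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for closely related bacterial
    strains sequenced at different assembly qualities. Splits a draft
    assembly at undetermined ('N') runs, places the fragments on a
    completed genome under an explicit alignment cost model, and accounts
    the gaps and overlaps between adjacent fragments; lifts draft gene
    annotations onto the completed assembly and classifies every gene as
    Identical, Long, Short, Moved, New or Missing; classifies secondary
    metabolite biosynthetic gene cluster (BGC) conservation between
    strains from per-gene role tables; calls variants between coding
    sequence pairs and predicts frameshift consequences; scans upstream
    and intergenic regions for exact tandem repeats; and estimates
    fragment-based average nucleotide identity (ANI) with the 95 percent
    same-species convention. A synthetic-data module generates strain
    pairs with machine-readable ground truth so every stage is testable
    end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
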