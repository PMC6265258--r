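Package: larch2s
Title: Two-Species Larch Treeline Simulation and Sedimentary DNA Haplotype Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An individual-based, spatially explicit simulator of two-species
    larch (Larix sibirica / Larix gmelinii) stand dynamics at the northern
    treeline, driven by monthly climate forcing assembled by bootstrap-splicing
    recent weather windows onto a millennial paleoclimate series. Companion
    tools classify sedimentary-DNA amplicon reads of the diagnostic
    mitochondrial nad4 single-nucleotide variant into the two species lineages,
    call per-sample variant dominance, and ordinate coupled DNA-metabarcoding
    and pollen taxa tables (genus aggregation, abundance filtering, square-root
    transform, principal component analysis). Synthetic-data generators with
    known ground truth make every stage runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
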