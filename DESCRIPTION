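Package: varprior
Title: Variant Prioritization and Reference Augmentation for Graph Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every variant in a population catalog by its predicted
    benefit (allele-frequency-weighted population coverage) and cost (added
    reference repetitiveness), ranks and greedily selects an optimal subset
    with a blowup-avoidance penalty, and emits the selected subset plus
    augmented-reference artifacts (enhanced-segment FASTA, major-allele
    FASTA) for downstream graph or linear aligners. Includes a seeded
    synthetic-data generator (reference genomes with tunable repeat content,
    phased haplotype panels, variant catalogs with controllable
    allele-frequency spectrum and clustering) so the full pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
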