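Package: kaspforge
Title: Design and Score KASP Genotyping Assays from Two-Line Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning variant calls from two inbred lines into
    Kompetitive Allele-Specific PCR (KASP) genotyping assays. Classifies
    variant sites between the two lines against a shared reference (unique,
    concordant-shared, discordant-overlapping), summarises variant panels
    (per-chromosome variant rates, windowed densities, Ts/Tv ratios, SnpEff
    impact classes, read-mapping percentages), screens SNP flanking sequences
    for assay suitability (InDel proximity, ambiguous bases, read depth,
    tandem repeats, homozygosity, proximity culling), designs tailed
    allele-specific primer assays with a common reverse primer, and scores
    F2 genotyping panels from discrete allele-call tables. Includes a seeded
    synthetic-data generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
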