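Package: chloroplastr
Title: Chloroplast Genome Structure and Long-Read Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for circular plastid (chloroplast) genomes
    studied with long genomic reads and full-length cDNAs: resolution of the
    quadripartite LSC/IRa/SSC/IRb architecture by exact inverted-repeat
    detection, k-mer based fishing of chloroplast reads from mixed pools,
    spliced mapping of full-length transcripts, calling of group-II introns,
    C-to-U RNA editing sites with per-site efficiencies, and polycistronic
    operons, and p-distance divergence scoring of candidate DNA-barcode
    markers. Includes a ground-truthed simulator of plastomes, long genomic
    reads and full-length cDNAs so every stage is verifiable by planted-truth
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    stringi,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
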