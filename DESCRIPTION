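Package: haplomarker
Title: Gene-Region Haplotype Analysis and CAPS/dCAPS/Indel Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying germplasm accessions into gene-region
    haplotype groups and haplotypes from per-accession sequences or variant
    matrices, identifying variants unique to elite haplotypes, and turning
    them into diagnostic PCR markers (Indel, CAPS and dCAPS). Includes
    restriction-site scanning over IUPAC motifs, primer design with
    deliberate dCAPS mismatches, in-silico PCR and digestion with a gel
    resolvability model, and a synthetic multi-subpopulation panel
    generator with planted haplotype structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
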