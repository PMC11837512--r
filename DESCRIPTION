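Package: bestop
Title: Knockout Guide Design for Cytosine Base Editors via Premature Stop Codons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide design of single-guide RNAs for CRISPR cytosine base
    editors (nCas9-deaminase fusions) that inactivate protein-coding genes by
    converting sense codons into premature stop codons. Scans both strands of a
    genome for 20-nt protospacers adjacent to NGG PAMs, maps cytosines inside
    the deamination window onto reading frames from GFF3 annotation, and
    reports guides whose C-to-T (coding strand) or G-to-A (template strand)
    edits create TAA, TAG or TGA codons upstream of the native stop. Includes
    genome-wide coverage summaries (editable genes, guides and editable codons
    per gene, relative stop positions), Sanger-trace editing-efficiency
    metrics from per-position base-frequency tables, a synthetic-genome
    generator with planted targets, and an independent edit-and-translate
    brute-force oracle used to validate the designer.
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
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
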