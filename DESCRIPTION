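Package: dinoarch
Title: Post-Transcriptional Gene Architecture Analyses for Dinoflagellate Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise post-transcriptional regulation and unusual
    gene architecture in dinoflagellate genomes and transcriptomes: extraction
    of introns and splice-motif tabulation, detection of introner elements by
    terminal inverted/direct repeats, calling of mRNA editing sites from
    DNA-versus-RNA base-count pileups with replicate-aware significance
    filters, differential editing and differential exon usage tests, FPKM
    computation and complete-linkage expression superclustering, duplicate-gene
    mode classification (tandem/proximal/dispersed) with expression-direction
    concordance summaries, spliced-leader (dinoSL) detection at transcript 5'
    ends, and segmentation of multi-coding-unit proteins into coding units and
    spacers with motif scanning. Includes a seeded synthetic-data generator
    that plants every feature class with ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
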