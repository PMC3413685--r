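Package: isotigr
Title: De Novo Transcriptome Assembly, Annotation and Enzyme Discovery at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, self-contained reimplementation of a short-read de novo
    transcriptome analysis workflow for non-model insects: Phred-window read
    filtering, multi-k de Bruijn graph assembly with isotig/isogroup generation,
    homologue-keyed merging of assemblies built at different k, translated local
    alignment against protein databases, assembly completeness and per-base
    coverage statistics, EC-group enzyme prediction backed by flexible-gap
    catalytic-site motifs, collapsing of redundant isotigs into putative genes,
    and translated scans for insecticide target-site genes. A synthetic-data
    module generates transcriptomes, paired-end reads, diverged protein
    databases and planted motifs with known ground truth, so the whole pipeline
    is exercised end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
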