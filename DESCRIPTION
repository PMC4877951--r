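Package: strataseq
Title: Taxon-Restricted Gene Expression Analysis for De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for comparative transcriptomics of de novo assembled
    transcriptomes across tissues: alien-index screening of putative foreign
    transcripts with a genome-rescue filter, phylostratum (taxon-restriction)
    classification of transcripts from ortholog-cluster membership,
    negative-binomial differential expression with a compound
    upregulated/uniquely-expressed classification across three tissues,
    stratum-by-tissue enrichment reporting, reciprocal-best-hit annotation
    against a categorized stress-gene database, and assembly summary metrics
    (N50, GC content, ORF statistics). Includes a seeded synthetic-data
    generator with planted ground truth so the full chain is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
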