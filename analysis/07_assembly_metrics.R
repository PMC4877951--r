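#!/usr/bin/env Rscript
# Assembly summary statistics of the cleaned transcriptome: transcript and
# ORF counts, no-expression census (total raw count < 2 across all samples),
# mean length, N50 and GC content.

suppressPackageStartupMessages(library(strataseq))

manifest <- jsonlite::read_json("results/sim/manifest.json",
                                simplifyVector = TRUE)
retained <- readLines("results/retained_ids.txt")
tx <- read_fasta(manifest$fasta)
tx <- tx[tx$id %in% retained, ]
orfs <- read_orfs(manifest$orfs)
orfs <- orfs[orfs$transcript_id %in% retained, ]
counts <- read_counts(manifest$counts, read_tissue_map(manifest$tissue_map))

s <- summarize_assembly(tx, orfs, counts)
jsonlite::write_json(s, "results/assembly_summary.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = 6)

message(sprintf("transcripts %d | with ORFs %d | ORFs %d (%.1f per transcript)",
                s$n_transcripts, s$n_orf_transcripts, s$n_orfs,
                s$orfs_per_orf_transcript))
message(sprintf("no expression (total count < 2): %d", s$n_no_expression))
message(sprintf("mean length %.0f bp | N50 %d bp | GC %.2f%% (pooled)",
                s$mean_length_bp, s$n50_bp, s$gc_percent_pooled))
message("summary -> results/assembly_summary.json")
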