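#!/usr/bin/env Rscript
# Assign each retained, ORF-bearing transcript a phylostratum from its
# ortholog-cluster membership (broadest lineage class in the cluster wins;
# transcript stratum is the maximum over its ORFs) and print the census.

suppressPackageStartupMessages(library(strataseq))

manifest <- jsonlite::read_json("results/sim/manifest.json",
                                simplifyVector = TRUE)
tm <- read_taxon_map(manifest$taxon_map)
retained <- readLines("results/retained_ids.txt")

orfs <- read_orfs(manifest$orfs)
orfs <- orfs[orfs$transcript_id %in% retained, ]
groups <- read_groups(manifest$groups, tm)
membership <- membership_from_groups(groups)
membership <- membership[names(membership) %in% orfs$orf_id]

strata <- assign_transcript_strata(groups, orfs, membership)
census <- stratum_census(strata)

utils::write.table(strata, "results/strata.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(census, "results/stratum_census.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("%d transcripts assigned a stratum", nrow(strata)))
for (i in seq_len(nrow(census))) {
  message(sprintf("  %-13s %5d (%d%%)", census$stratum[i], census$count[i],
                  census$percent[i]))
}
message("assignments -> results/strata.tsv; census -> results/stratum_census.tsv")
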