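#!/usr/bin/env Rscript
# Annotate each tissue's upregulated set against the categorized stress-gene
# database by reciprocal best BLAST hit and tabulate category counts
# (a transcript tied between two categories counts in both).

suppressPackageStartupMessages(library(strataseq))

manifest <- jsonlite::read_json("results/sim/manifest.json",
                                simplifyVector = TRUE)
db <- read_stress_db(manifest$stress_db)
fwd <- utils::read.delim(manifest$stress_fwd, header = FALSE)[, c(1, 2, 12)]
names(fwd) <- c("query_id", "subject_id", "bitscore")
rev <- utils::read.delim(manifest$stress_rev, header = FALSE)[, c(1, 2, 12)]
names(rev) <- c("query_id", "subject_id", "bitscore")

pairs <- reciprocal_best_hits(fwd, rev, db)
utils::write.table(pairs, "results/stress_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

rows <- list()
for (t in c("mesentery", "nematosome", "tentacle")) {
  up <- readLines(sprintf("results/upregulated_%s.txt", t))
  cen <- stress_census(up, pairs)
  message(sprintf("%-10s: %d/%d upregulated transcripts annotated (%d%%)",
                  t, cen$n_annotated, cen$n_upregulated, cen$overall_percent))
  for (i in seq_len(nrow(cen$by_category))) {
    message(sprintf("    %-9s %3d (%s%%)", cen$by_category$category[i],
                    cen$by_category$count[i],
                    ifelse(is.na(cen$by_category$percent[i]), "NA",
                           cen$by_category$percent[i])))
  }
  rows[[t]] <- cbind(tissue = t, cen$by_category,
                     n_annotated = cen$n_annotated,
                     n_upregulated = cen$n_upregulated)
}
utils::write.table(do.call(rbind, rows), "results/stress_census.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("pairs -> results/stress_pairs.tsv; census -> results/stress_census.tsv")
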