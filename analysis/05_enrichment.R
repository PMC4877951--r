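#!/usr/bin/env Rscript
# Cross-tabulate phylostrata against the per-tissue expression classes and
# compute the single-tissue-restriction fractions per stratum group
# (lineage-restricted vs cnidarian sensu lato vs conserved/metazoan).

suppressPackageStartupMessages(library(strataseq))

strata <- utils::read.delim("results/strata.tsv", stringsAsFactors = FALSE)
tissues <- c("mesentery", "nematosome", "tentacle")
sets <- lapply(setNames(tissues, tissues), function(t) {
  up <- readLines(sprintf("results/upregulated_%s.txt", t))
  un <- readLines(sprintf("results/unique_%s.txt", t))
  # transcripts without a qualifying ORF carry no stratum: excluded
  list(upregulated = up[up %in% strata$transcript_id],
       unique = un[un %in% strata$transcript_id])
})

ct <- crosstab_proportions(strata, sets)
long <- data.frame(
  class = rep(colnames(ct$counts), each = nrow(ct$counts)),
  stratum = rep(rownames(ct$counts), ncol(ct$counts)),
  count = as.vector(ct$counts), percent = as.vector(ct$percent))
utils::write.table(long, "results/crosstab.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(ct$cnidarian_sensu_lato,
                   "results/cnidarian_sensu_lato.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (t in tissues) {
  col <- paste0("upregulated_", t)
  message(sprintf("%-10s: %d%% of upregulated transcripts are lineage-restricted (N = %d/%d)",
                  t, ct$percent["NEMATOSTELLA", col],
                  ct$counts["NEMATOSTELLA", col], ct$totals[[col]]))
}

stf <- single_tissue_fraction(strata, sets)
utils::write.table(stf, "results/single_tissue_fraction.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(stf))) {
  message(sprintf("single-tissue fraction, %-20s: %d/%d (%s%%)",
                  stf$group[i], stf$n_unique[i], stf$n_de[i],
                  ifelse(is.na(stf$percent[i]), "NA", stf$percent[i])))
}
message("tables -> results/crosstab.tsv, results/single_tissue_fraction.tsv")
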