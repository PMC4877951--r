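# Assembly summary statistics for a transcript set: N50, pooled GC content,
# mean length, ORF counts, and the no-expression census.

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together contain
#' at least half of the total bases, computed by a descending cumulative
#' sum. Invariant to input order.
#'
#' @param lengths positive integer vector
#' @return the N50 length
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) abort_fmt("N50 of an empty set is undefined")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  s[which(cum >= sum(as.numeric(s)) / 2)[1]]
}

#' Summarize a transcriptome assembly
#'
#' Reports transcript and ORF counts, ORFs per ORF-bearing transcript, the
#' number of ORF-bearing transcripts with (total raw count across all
#' samples) below `expr_min` ("no expression"; set
#' `no_expression_mode = "per_tissue"` to instead require total count below
#' `expr_min` within at least one tissue), mean transcript length, N50, and
#' GC content both pooled over all non-N bases (length-weighted) and as the
#' unweighted mean of per-sequence GC.
#'
#' @param transcripts data.frame from [read_fasta()]
#' @param orfs data.frame from [read_orfs()] (may have zero rows)
#' @param counts optional list from [read_counts()]; enables the
#'   no-expression census
#' @param expr_min expression floor; totals strictly below it count as "no
#'   expression" (default 2)
#' @param no_expression_mode `"total"` (sum across all samples) or
#'   `"per_tissue"`
#' @return list of summary statistics
#' @export
summarize_assembly <- function(transcripts, orfs = NULL, counts = NULL,
                               expr_min = 2,
                               no_expression_mode = c("total", "per_tissue")) {
  no_expression_mode <- match.arg(no_expression_mode)
  if (nrow(transcripts) == 0) abort_fmt("cannot summarize an empty transcript set")
  if (!is.null(orfs) && nrow(orfs) > 0) {
    unknown <- setdiff(unique(orfs$transcript_id), transcripts$id)
    if (length(unknown) > 0) {
      abort_fmt("ORF references unknown transcript: %s", unknown[1])
    }
  }
  n_tx <- nrow(transcripts)
  orf_tx <- if (is.null(orfs)) character(0) else unique(orfs$transcript_id)
  n_orfs <- if (is.null(orfs)) 0L else nrow(orfs)

  n_noexpr <- NA_integer_
  if (!is.null(counts) && length(orf_tx) > 0) {
    present <- intersect(orf_tx, rownames(counts$counts))
    sub <- counts$counts[present, , drop = FALSE]
    if (no_expression_mode == "total") {
      low <- rowSums(sub) < expr_min
    } else {
      tis <- unique(unname(counts$tissue_of))
      per <- sapply(tis, function(t) {
        rowSums(sub[, names(counts$tissue_of)[counts$tissue_of == t],
                    drop = FALSE])
      })
      low <- apply(per < expr_min, 1, any)
    }
    # ORF transcripts absent from the count matrix have no observed counts
    n_noexpr <- sum(low) + length(setdiff(orf_tx, present))
  }

  seqs <- transcripts$sequence
  n_base <- function(ch) sum(vapply(seqs, function(s) {
    sum(charToRaw(s) == charToRaw(ch))
  }, numeric(1)))
  gc_num <- n_base("G") + n_base("C")
  gc_den <- gc_num + n_base("A") + n_base("T")

  list(
    n_transcripts = n_tx,
    n_orf_transcripts = length(orf_tx),
    n_orfs = n_orfs,
    orfs_per_orf_transcript = if (length(orf_tx) > 0) n_orfs / length(orf_tx) else NA_real_,
    n_no_expression = n_noexpr,
    mean_length_bp = mean(transcripts$length),
    n50_bp = n50(transcripts$length),
    gc_percent_pooled = if (gc_den > 0) 100 * gc_num / gc_den else NA_real_,
    gc_percent_per_seq_mean = 100 * mean(transcripts$gc_fraction, na.rm = TRUE)
  )
}
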