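# Alien-index contamination screen.
#
# The alien index (AI) contrasts a transcript's best (lowest) E-value among
# metazoan subjects with its best among non-metazoan subjects on a natural
# log scale:
#
#   AI = ln(E_meta + eps) - ln(E_nonmeta + eps),   eps = 1e-200
#
# so AI > 0 means the foreign hit is the better one and the transcript is
# flagged as putatively alien. A side with no hit defaults to E = 1.
# Flagged transcripts can be rescued by a high-quality genomic alignment
# (identity > 70%, aligned length >= 200 bp by default); flagged,
# un-rescued transcripts are removed.

AI_EPS <- 1e-200

#' Compute alien indices from a homology hit table
#'
#' For each query in `hits` (and any extra ids in `all_ids` with no hits at
#' all), takes the minimum E-value among metazoan-class subjects and among
#' non-metazoan-class subjects (missing side defaults to 1.0) and returns
#' the log-ratio alien index. A transcript is flagged when its index is
#' strictly positive.
#'
#' @param hits data.frame of hits as returned by [read_blast_tab()]
#' @param all_ids optional character vector of transcript ids that must be
#'   covered; ids without hits get both defaults (AI = 0, not flagged)
#' @param missing_evalue default E-value for a side with no hit (1.0)
#' @return data.frame with `transcript_id`, `best_metazoan_evalue`,
#'   `best_nonmetazoan_evalue`, `ai`, `flagged`
#' @export
compute_alien_index <- function(hits, all_ids = NULL, missing_evalue = 1.0) {
  ids <- unique(c(if (nrow(hits) > 0) hits$query_id else character(0), all_ids))
  best_m <- rep(missing_evalue, length(ids))
  best_nm <- rep(missing_evalue, length(ids))
  names(best_m) <- names(best_nm) <- ids
  if (nrow(hits) > 0) {
    is_m <- hits$subject_class %in% METAZOAN_CLASSES
    is_nm <- hits$subject_class %in% NONMETAZOAN_CLASSES
    if (any(is_m)) {
      bm <- tapply(hits$evalue[is_m], hits$query_id[is_m], min)
      best_m[names(bm)] <- unname(bm)
    }
    if (any(is_nm)) {
      bn <- tapply(hits$evalue[is_nm], hits$query_id[is_nm], min)
      best_nm[names(bn)] <- unname(bn)
    }
  }
  ai <- log(best_m + AI_EPS) - log(best_nm + AI_EPS)
  data.frame(
    transcript_id = ids,
    best_metazoan_evalue = unname(best_m),
    best_nonmetazoan_evalue = unname(best_nm),
    ai = unname(ai),
    flagged = unname(ai > 0),
    stringsAsFactors = FALSE
  )
}

#' Apply the contamination screen with genome rescue
#'
#' A flagged transcript is rescued when it has at least one genomic
#' alignment with identity strictly above `min_identity` and aligned length
#' of at least `min_align_len`; removed = flagged and not rescued. All other
#' transcripts are retained.
#'
#' @param transcript_ids character vector of all transcript ids under screen
#' @param ai_results output of [compute_alien_index()]; must cover every id
#' @param genome_hits data.frame of transcript-vs-genome alignments (as from
#'   [read_blast_tab()]; only `query_id`, `pct_identity`, `align_length`
#'   are used). May have zero rows.
#' @param min_identity rescue identity threshold, percent (exclusive; 70)
#' @param min_align_len rescue alignment length threshold, bp (inclusive; 200)
#' @return list with `retained` and `removed` id vectors, a per-transcript
#'   `table` (ai, flagged, rescued, removed) and a `report` of counts
#' @export
apply_screen <- function(transcript_ids, ai_results, genome_hits = NULL,
                         min_identity = 70.0, min_align_len = 200) {
  missing <- setdiff(transcript_ids, ai_results$transcript_id)
  if (length(missing) > 0) {
    abort_fmt("no alien-index result for transcript: %s", missing[1])
  }
  ai <- ai_results[match(transcript_ids, ai_results$transcript_id), ]
  rescued_ids <- character(0)
  if (!is.null(genome_hits) && nrow(genome_hits) > 0) {
    ok <- genome_hits$pct_identity > min_identity &
      genome_hits$align_length >= min_align_len
    rescued_ids <- unique(genome_hits$query_id[ok])
  }
  flagged <- ai$flagged
  rescued <- flagged & transcript_ids %in% rescued_ids
  removed <- flagged & !rescued
  tab <- data.frame(
    transcript_id = transcript_ids,
    ai = ai$ai, flagged = flagged, rescued = rescued, removed = removed,
    stringsAsFactors = FALSE
  )
  list(
    retained = transcript_ids[!removed],
    removed = transcript_ids[removed],
    table = tab,
    report = list(
      n_input = length(transcript_ids),
      n_flagged = sum(flagged),
      n_rescued = sum(rescued),
      n_removed = sum(removed),
      n_retained = sum(!removed)
    )
  )
}
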