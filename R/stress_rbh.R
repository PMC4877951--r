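# Reciprocal-best-hit annotation against a categorized stress-gene database
# (categories: wound, pathogen, chemical) and the per-category census.

#' Read a stress-gene database
#'
#' @param path two-column TSV with header `gene_id`, `category`
#' @param categories allowed category labels
#' @return named character vector gene_id -> category
#' @export
read_stress_db <- function(path, categories = c("wound", "pathogen", "chemical")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df))) {
    abort_fmt("stress DB must have columns gene_id, category")
  }
  bad <- setdiff(unique(df$category), categories)
  if (length(bad) > 0) abort_fmt("unknown stress category: %s", bad[1])
  if (anyDuplicated(df$gene_id)) {
    abort_fmt("duplicate stress gene id: %s", df$gene_id[duplicated(df$gene_id)][1])
  }
  stats::setNames(df$category, df$gene_id)
}

# best subjects per query by bit score, within tie_tol of the maximum
.best_by_query <- function(hits, tie_tol) {
  out <- split(seq_len(nrow(hits)), hits$query_id)
  lapply(out, function(idx) {
    b <- hits$bitscore[idx]
    unique(hits$subject_id[idx][b >= max(b) - tie_tol])
  })
}

#' Reciprocal best hits between transcripts and stress genes
#'
#' A gene g is a best hit of transcript t when its bit score is within
#' `tie_tol` of t's maximum forward bit score; symmetrically for the reverse
#' direction. A pair is emitted when both directions hold. With the exact-tie
#' default (`tie_tol = 0`), a transcript with equally high reciprocating hits
#' to genes of two categories keeps both genes.
#'
#' @param fwd forward hit table (transcripts -> stress genes); needs columns
#'   `query_id`, `subject_id`, `bitscore`
#' @param rev reverse hit table (stress genes -> transcripts)
#' @param db named vector gene_id -> category (from [read_stress_db()]);
#'   when supplied, hits to genes absent from it raise an error and each
#'   pair's category set is attached
#' @param tie_tol bit-score tie tolerance (0 keeps exact ties only)
#' @return data.frame with `transcript_id`, `stress_gene_ids`
#'   (comma-joined), `n_genes`, `categories` (comma-joined, sorted unique)
#' @export
reciprocal_best_hits <- function(fwd, rev, db = NULL, tie_tol = 0.0) {
  if (!is.null(db)) {
    unknown <- setdiff(unique(fwd$subject_id), names(db))
    if (length(unknown) > 0) abort_fmt("hit references unknown stress gene: %s", unknown[1])
    unknown <- setdiff(unique(rev$query_id), names(db))
    if (length(unknown) > 0) abort_fmt("hit references unknown stress gene: %s", unknown[1])
  }
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(data.frame(transcript_id = character(), stress_gene_ids = character(),
                      n_genes = integer(), categories = character(),
                      stringsAsFactors = FALSE))
  }
  best_fwd <- .best_by_query(fwd, tie_tol)   # transcript -> best genes
  best_rev <- .best_by_query(rev, tie_tol)   # gene -> best transcripts
  rows <- lapply(names(best_fwd), function(t) {
    genes <- best_fwd[[t]]
    keep <- vapply(genes, function(g) t %in% best_rev[[g]], logical(1))
    genes <- sort(genes[keep])
    if (length(genes) == 0) return(NULL)
    cats <- if (!is.null(db)) {
      paste(sort(unique(unname(db[genes]))), collapse = ",")
    } else ""
    data.frame(transcript_id = t,
               stress_gene_ids = paste(genes, collapse = ","),
               n_genes = length(genes), categories = cats,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(), stress_gene_ids = character(),
                      n_genes = integer(), categories = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$transcript_id), , drop = FALSE]
}

#' Stress-category census of an upregulated set
#'
#' Counts upregulated transcripts with at least one reciprocal best hit
#' (overall percent of the upregulated set, round-half-up) and, per
#' category, the number of annotated transcripts carrying that category
#' (percent of the annotated count). A transcript tied between two
#' categories increments both, so category sums may exceed the annotated
#' total.
#'
#' @param upregulated character vector of transcript ids
#' @param pairs output of [reciprocal_best_hits()] (with categories)
#' @param categories category universe for the census
#' @return list with `n_upregulated`, `n_annotated`, `overall_percent`,
#'   and `by_category` (data.frame: category, count, percent)
#' @export
stress_census <- function(upregulated, pairs,
                          categories = c("wound", "pathogen", "chemical")) {
  if (length(upregulated) == 0) abort_fmt("empty upregulated set")
  pairs <- pairs[pairs$transcript_id %in% upregulated, , drop = FALSE]
  n_ann <- length(unique(pairs$transcript_id))
  cat_lists <- strsplit(pairs$categories, ",", fixed = TRUE)
  by_cat <- vapply(categories, function(cc) {
    sum(vapply(cat_lists, function(v) cc %in% v, logical(1)))
  }, numeric(1))
  list(
    n_upregulated = length(upregulated),
    n_annotated = n_ann,
    overall_percent = pct_half_up(n_ann, length(upregulated)),
    by_category = data.frame(
      category = categories,
      count = as.integer(by_cat),
      percent = pct_half_up(by_cat, rep(n_ann, length(categories))),
      stringsAsFactors = FALSE
    )
  )
}
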