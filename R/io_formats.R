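# Readers and writers for the external formats consumed by the workflow.
# All parsers are strict: malformed input raises an error rather than being
# skipped, so downstream censuses are never silently corrupted.

# Lineage classes a subject-id prefix may resolve to. The three NVEC_*
# classes are the assembly's own species (counted as "self" and metazoan);
# the last three are the non-metazoan side of the alien index.
LINEAGE_CLASSES <- c(
  "NVEC_SELF", "NVEC_JGI", "NVEC_TECHNAU",
  "EDWARDSIELLA", "ANTHOZOAN", "CNIDARIAN_OTHER", "METAZOAN_OUTGROUP",
  "NONMETAZOAN_EUK", "ARCHAEA", "BACTERIA"
)

METAZOAN_CLASSES <- c(
  "NVEC_SELF", "NVEC_JGI", "NVEC_TECHNAU",
  "EDWARDSIELLA", "ANTHOZOAN", "CNIDARIAN_OTHER", "METAZOAN_OUTGROUP"
)

NONMETAZOAN_CLASSES <- c("NONMETAZOAN_EUK", "ARCHAEA", "BACTERIA")

#' Read transcript sequences from FASTA
#'
#' Parses a FASTA file into a transcript table. Ids are truncated at the
#' first whitespace; sequences are upper-cased and must use only the
#' alphabet {A, C, G, T, N}. GC fraction is computed over non-N bases and is
#' `NA` for all-N sequences.
#'
#' @param path path to a FASTA file
#' @return data.frame with columns `id`, `sequence`, `length`, `gc_fraction`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_fmt("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), gc_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) abort_fmt("duplicate FASTA id: %s", dup[1])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort_fmt("empty sequence for record: %s", ids[nchar(seqs) == 0][1])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort_fmt("non-IUPAC character (outside A/C/G/T/N) in record: %s",
              ids[bad][1])
  }
  transcript_table(ids, seqs)
}

# build the transcript table with derived length and GC fraction
transcript_table <- function(ids, seqs) {
  counts <- function(ch) {
    vapply(seqs, function(s) {
      sum(charToRaw(s) == charToRaw(ch))
    }, numeric(1), USE.NAMES = FALSE)
  }
  nG <- counts("G"); nC <- counts("C"); nA <- counts("A"); nT <- counts("T")
  denom <- nA + nC + nG + nT
  gc <- ifelse(denom > 0, (nG + nC) / denom, NA_real_)
  data.frame(id = ids, sequence = seqs, length = nchar(seqs),
             gc_fraction = gc, stringsAsFactors = FALSE)
}

#' Write transcripts to FASTA
#'
#' @param transcripts data.frame as returned by [read_fasta()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::BStringSet(transcripts$sequence)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a taxon map (source prefix to lineage class) from JSON
#'
#' @param path JSON file mapping each database source prefix to one of the
#'   recognized lineage classes
#' @return named character vector (prefix -> class)
#' @export
read_taxon_map <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- unlist(m)
  validate_taxon_map(m)
  m
}

validate_taxon_map <- function(taxon_map) {
  if (is.null(names(taxon_map)) || any(names(taxon_map) == "")) {
    abort_fmt("taxon map must be a named prefix -> class mapping")
  }
  bad <- setdiff(unique(taxon_map), LINEAGE_CLASSES)
  if (length(bad) > 0) abort_fmt("unknown lineage class in taxon map: %s", bad[1])
  invisible(taxon_map)
}

# resolve subject-id prefixes (text before the first delimiter) to classes
resolve_prefix <- function(ids, taxon_map, delim = "|") {
  pre <- vapply(strsplit(ids, delim, fixed = TRUE), `[`, character(1), 1)
  unknown <- setdiff(unique(pre), names(taxon_map))
  if (length(unknown) > 0) abort_fmt("unmapped taxon prefix: %s", unknown[1])
  unname(taxon_map[pre])
}

#' Read tabular homology results (12-column format)
#'
#' Reads the standard 12-column tab-separated homology output (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' query/subject start/end, E-value, bit score) and annotates each hit with
#' the subject's lineage class, resolved from the prefix of the subject id
#' (text before the first `delim`) via `taxon_map`. Row order is preserved.
#'
#' @param path path to the tab-separated file
#' @param taxon_map named character vector (prefix -> lineage class)
#' @param delim prefix delimiter in subject ids (default `"|"`)
#' @return data.frame with the 12 standard columns plus `subject_class`
#' @export
read_blast_tab <- function(path, taxon_map, delim = "|") {
  validate_taxon_map(taxon_map)
  cols <- c("query_id", "subject_id", "pct_identity", "align_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = 12), stringsAsFactors = FALSE)
    names(out) <- cols
    out$subject_class <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    abort_fmt("expected 12 tab-separated columns, got %d at line %d",
              nf[nf != 12][1], which(nf != 12)[1])
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), align_length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$evalue)) || any(out$evalue < 0)) {
    abort_fmt("invalid E-value at line %d",
              which(is.na(out$evalue) | out$evalue < 0)[1])
  }
  if (any(is.na(out$bitscore)) || any(out$bitscore <= 0)) {
    abort_fmt("invalid bit score at line %d",
              which(is.na(out$bitscore) | out$bitscore <= 0)[1])
  }
  out$subject_class <- resolve_prefix(out$subject_id, taxon_map, delim)
  out
}

#' Read ortholog groups (OrthoMCL "groups" text format)
#'
#' Each line is `GROUP_ID: prefix|seq1 prefix|seq2 ...`. Member prefixes are
#' validated against the taxon map at parse time.
#'
#' @inheritParams read_blast_tab
#' @return list of groups; each element has `group_id`, `members`
#'   (data.frame with `prefix`, `member_id`, `class`)
#' @export
read_groups <- function(path, taxon_map, delim = "|") {
  validate_taxon_map(taxon_map)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) abort_fmt("missing ':' separator at line %d", i)
    gid <- trimws(substr(ln, 1, colon - 1))
    rest <- trimws(substr(ln, colon + 1, nchar(ln)))
    if (!nzchar(rest)) abort_fmt("group '%s' has no members (line %d)", gid, i)
    members <- strsplit(rest, "[ \t]+")[[1]]
    pre <- vapply(strsplit(members, delim, fixed = TRUE), `[`, character(1), 1)
    cls <- resolve_prefix(members, taxon_map, delim)
    out[[i]] <- list(
      group_id = gid,
      members = data.frame(prefix = pre, member_id = members, class = cls,
                           stringsAsFactors = FALSE)
    )
  }
  out
}

#' Read a raw count matrix with a sample-to-tissue map
#'
#' Expects a TSV whose header row holds sample ids and whose first column
#' holds transcript ids. Counts must be non-negative integers. The tissue
#' map must cover every sample, define exactly three tissues, and give every
#' tissue at least two replicates.
#'
#' @param path counts TSV
#' @param tissue_of named character vector mapping sample id -> tissue label
#' @return list with `counts` (integer matrix, transcripts x samples) and
#'   `tissue_of` (named character vector restricted to the matrix columns)
#' @export
read_counts <- function(path, tissue_of) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) abort_fmt("counts file needs transcript ids plus samples")
  tids <- df[[1]]
  if (anyDuplicated(tids)) abort_fmt("duplicate transcript id: %s", tids[duplicated(tids)][1])
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) abort_fmt("duplicate sample id in header")
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_fmt("non-integer or negative count at row %d (transcript %s), sample %s",
              bad[1, 1], tids[bad[1, 1]], samples[bad[1, 2]])
  }
  counts <- matrix(as.integer(num), nrow = nrow(num),
                   dimnames = list(tids, samples))
  missing <- setdiff(samples, names(tissue_of))
  if (length(missing) > 0) abort_fmt("sample without tissue mapping: %s", missing[1])
  tissue_of <- tissue_of[samples]
  validate_tissues(tissue_of)
  list(counts = counts, tissue_of = tissue_of)
}

validate_tissues <- function(tissue_of) {
  tab <- table(tissue_of)
  if (length(tab) != 3) {
    abort_fmt("expected exactly 3 tissues, got %d", length(tab))
  }
  if (any(tab < 2)) {
    abort_fmt("tissue '%s' has fewer than 2 replicates", names(tab)[tab < 2][1])
  }
  invisible(tissue_of)
}

#' Read a sample-to-tissue map from JSON
#'
#' @param path JSON object mapping sample id -> tissue label
#' @return named character vector
#' @export
read_tissue_map <- function(path) {
  m <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  if (is.null(names(m))) abort_fmt("tissue map must be a named mapping")
  m
}

#' Read an ORF table
#'
#' Two- or three-column TSV with header: `transcript_id`, `orf_id`, and
#' optionally `aa_length`. Only ORFs of at least 100 amino acids are ever
#' represented; shorter entries are rejected.
#'
#' @param path ORF TSV
#' @param min_aa minimum ORF length in amino acids (default 100)
#' @return data.frame with `transcript_id`, `orf_id`, `aa_length`
#' @export
read_orfs <- function(path, min_aa = 100) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "orf_id")
  if (!all(need %in% names(df))) {
    abort_fmt("ORF table must have columns: %s", paste(need, collapse = ", "))
  }
  if (is.null(df$aa_length)) df$aa_length <- min_aa
  if (anyDuplicated(df$orf_id)) {
    abort_fmt("duplicate ORF id: %s", df$orf_id[duplicated(df$orf_id)][1])
  }
  if (any(df$aa_length < min_aa)) {
    abort_fmt("ORF below the %d aa threshold: %s", min_aa,
              df$orf_id[df$aa_length < min_aa][1])
  }
  df[, c("transcript_id", "orf_id", "aa_length")]
}
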