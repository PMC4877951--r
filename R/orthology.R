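# Phylostratum assignment from ortholog-cluster membership.
#
# Strata are ordered from most lineage-restricted to most conserved:
#   NEMATOSTELLA < EDWARDSIIDAE < ANTHOZOA < CNIDARIA < METAZOA
# A group's stratum is the broadest lineage class present among its members;
# a transcript's stratum is the maximum over its ORFs' group strata.

#' Stratum levels, most restricted first
#' @export
STRATA <- c("NEMATOSTELLA", "EDWARDSIIDAE", "ANTHOZOA", "CNIDARIA", "METAZOA")

# lineage class -> the stratum it pins a group to, by precedence
.class_stratum <- c(
  NVEC_SELF = "NEMATOSTELLA", NVEC_JGI = "NEMATOSTELLA",
  NVEC_TECHNAU = "NEMATOSTELLA",
  EDWARDSIELLA = "EDWARDSIIDAE",
  ANTHOZOAN = "ANTHOZOA",
  CNIDARIAN_OTHER = "CNIDARIA",
  METAZOAN_OUTGROUP = "METAZOA"
)

#' Classify one ortholog group to a stratum
#'
#' Precedence is by the broadest class present: any metazoan-outgroup member
#' makes the group METAZOA; failing that, any non-anthozoan cnidarian makes
#' it CNIDARIA; then any anthozoan (ANTHOZOA), then any Edwardsiidae member
#' (EDWARDSIIDAE); a group whose members are all self-species is
#' NEMATOSTELLA.
#'
#' @param group one element of the list returned by [read_groups()] (a list
#'   with `group_id` and a `members` data.frame carrying a `class` column)
#' @return one of [STRATA]
#' @export
classify_group <- function(group) {
  cls <- unique(group$members$class)
  bad <- setdiff(cls, c(names(.class_stratum), NONMETAZOAN_CLASSES))
  if (length(bad) > 0) abort_fmt("unresolvable member class: %s", bad[1])
  strata_present <- unname(.class_stratum[intersect(names(.class_stratum), cls)])
  if (length(strata_present) == 0) {
    abort_fmt("group %s has no metazoan members to classify", group$group_id)
  }
  STRATA[max(match(strata_present, STRATA))]
}

#' Assign transcripts to phylostrata via their ORFs
#'
#' Every ORF inherits the stratum of the group it clusters into; ORFs in no
#' group (unclustered singletons) are classified NEMATOSTELLA, since a
#' protein with no detectable ortholog anywhere is lineage-restricted by
#' definition (set `singleton_stratum = NA` to drop them instead). The
#' transcript-level stratum is the maximum over its ORF strata under the
#' stratum order, so one conserved ORF makes the whole transcript conserved.
#' Transcripts with no qualifying ORF are excluded.
#'
#' @param groups list of groups from [read_groups()]
#' @param orfs data.frame with `transcript_id`, `orf_id` (see [read_orfs()])
#' @param membership named character vector: orf_id -> group_id (ORFs absent
#'   from it are treated as unclustered)
#' @param singleton_stratum stratum for unclustered ORFs
#'   (default "NEMATOSTELLA"; `NA` excludes them)
#' @return data.frame with `transcript_id`, `stratum`, `n_orfs`, `group_ids`
#' @export
assign_transcript_strata <- function(groups, orfs, membership,
                                     singleton_stratum = "NEMATOSTELLA") {
  group_ids <- vapply(groups, `[[`, character(1), "group_id")
  group_strata <- vapply(groups, classify_group, character(1))
  names(group_strata) <- group_ids
  unknown <- setdiff(unique(membership), group_ids)
  if (length(unknown) > 0) abort_fmt("ORF references unknown group: %s", unknown[1])

  gid <- unname(membership[orfs$orf_id])
  orf_stratum <- ifelse(is.na(gid),
                        if (is.na(singleton_stratum)) NA_character_ else singleton_stratum,
                        group_strata[gid])
  keep <- !is.na(orf_stratum)
  if (!any(keep)) {
    return(data.frame(transcript_id = character(), stratum = character(),
                      n_orfs = integer(), group_ids = character(),
                      stringsAsFactors = FALSE))
  }
  tid <- orfs$transcript_id[keep]
  lev <- match(orf_stratum[keep], STRATA)
  best <- tapply(lev, tid, max)
  norf <- tapply(lev, tid, length)
  gids <- tapply(ifelse(is.na(gid[keep]), "-", gid[keep]), tid,
                 function(g) paste(g, collapse = ","))
  out <- data.frame(
    transcript_id = names(best),
    stratum = STRATA[unname(best)],
    n_orfs = as.integer(unname(norf)),
    group_ids = unname(gids),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Stratum census with printed-style integer percentages
#'
#' @param assignments data.frame from [assign_transcript_strata()] (or any
#'   data.frame with a `stratum` column)
#' @return data.frame with one row per stratum: `stratum`, `count`,
#'   `percent` (round-half-up integer of 100*count/total)
#' @export
stratum_census <- function(assignments) {
  if (nrow(assignments) == 0) abort_fmt("cannot take a census of zero transcripts")
  counts <- table(factor(assignments$stratum, levels = STRATA))
  total <- sum(counts)
  data.frame(
    stratum = STRATA,
    count = as.integer(counts),
    percent = pct_half_up(as.integer(counts), rep(total, length(STRATA))),
    stringsAsFactors = FALSE
  )
}
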