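# Stratum-by-expression-class reporting: cross-tabulation of phylostrata
# against the per-tissue upregulated / uniquely-expressed sets, plus the
# single-tissue-restriction fractions per stratum group.

#' Cross-tabulate strata against expression classes
#'
#' Builds one column per class — the full expressed set plus, per tissue,
#' the upregulated and unique sets — and counts members per stratum, with
#' round-half-up integer percentages of the column total and a
#' "cnidarian sensu lato" aggregate (all strata except METAZOA) per column.
#'
#' @param strata data.frame from [assign_transcript_strata()]
#' @param sets per-tissue sets from [classify_de_sets()]
#' @param all_expressed character vector of ids forming the reference column
#'   (default: every assigned transcript)
#' @return list with `counts` (strata x classes matrix), `percent` (same
#'   shape, NA where the column is empty), `totals` (per column), and
#'   `cnidarian_sensu_lato` (data.frame: class, count, percent)
#' @export
crosstab_proportions <- function(strata, sets, all_expressed = NULL) {
  if (is.null(all_expressed)) all_expressed <- strata$transcript_id
  stratum_of <- stats::setNames(strata$stratum, strata$transcript_id)
  columns <- c(list(all_expressed = all_expressed))
  for (t in names(sets)) {
    columns[[paste0("upregulated_", t)]] <- sets[[t]]$upregulated
    columns[[paste0("unique_", t)]] <- sets[[t]]$unique
  }
  missing <- setdiff(unique(unlist(columns)), names(stratum_of))
  if (length(missing) > 0) {
    abort_fmt("transcript in an expression class has no stratum: %s", missing[1])
  }
  counts <- sapply(columns, function(ids) {
    table(factor(stratum_of[ids], levels = STRATA))
  })
  counts <- matrix(as.integer(counts), nrow = length(STRATA),
                   dimnames = list(STRATA, names(columns)))
  totals <- colSums(counts)
  percent <- counts
  for (j in seq_along(totals)) {
    percent[, j] <- if (totals[j] > 0) {
      pct_half_up(counts[, j], rep(totals[j], nrow(counts)))
    } else NA_real_
  }
  csl_count <- totals - counts["METAZOA", ]
  csl <- data.frame(
    class = names(totals),
    count = as.integer(csl_count),
    percent = pct_half_up(csl_count, totals),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(counts = counts, percent = percent, totals = totals,
       cnidarian_sensu_lato = csl)
}

#' Single-tissue-restriction fraction per stratum group
#'
#' For each stratum group — NEMATOSTELLA, the cnidarian-sensu-lato aggregate
#' (all strata except METAZOA), and METAZOA — sums, over tissues, the number
#' of that group's transcripts in the upregulated sets (n_de) and in the
#' unique sets (n_unique), and reports n_unique / n_de as a round-half-up
#' integer percent (NA when n_de is 0).
#'
#' @inheritParams crosstab_proportions
#' @return data.frame: `group`, `n_unique`, `n_de`, `fraction`, `percent`
#' @export
single_tissue_fraction <- function(strata, sets) {
  stratum_of <- stats::setNames(strata$stratum, strata$transcript_id)
  groups <- list(
    NEMATOSTELLA = "NEMATOSTELLA",
    CNIDARIAN_SENSU_LATO = setdiff(STRATA, "METAZOA"),
    METAZOA = "METAZOA"
  )
  rows <- lapply(names(groups), function(g) {
    in_group <- function(ids) {
      miss <- setdiff(ids, names(stratum_of))
      if (length(miss) > 0) {
        abort_fmt("transcript in an expression class has no stratum: %s", miss[1])
      }
      sum(stratum_of[ids] %in% groups[[g]])
    }
    n_de <- sum(vapply(sets, function(s) in_group(s$upregulated), numeric(1)))
    n_unique <- sum(vapply(sets, function(s) in_group(s$unique), numeric(1)))
    data.frame(group = g, n_unique = n_unique, n_de = n_de,
               fraction = if (n_de > 0) n_unique / n_de else NA_real_,
               percent = pct_half_up(n_unique, n_de),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
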