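# End-to-end orchestration: (simulate ->) read -> alien screen -> strata ->
# differential expression -> enrichment -> stress annotation -> assembly
# metrics, with a machine-readable report. Reruns with the same config are
# byte-identical.

#' Build a pipeline configuration
#'
#' Either `simulate` (a [sim_config()]) or `inputs` (named list of file
#' paths: `fasta`, `orfs`, `groups`, `blastx`, `blastn`, `counts`,
#' `taxon_map`, `tissue_map`, `stress_db`, `stress_fwd`, `stress_rev`) must
#' be supplied. Every decision threshold of the analysis is a named field
#' with its published default.
#'
#' @param outdir output directory
#' @param simulate optional [sim_config()]
#' @param inputs optional named list of input paths
#' @param ai_threshold alien-index flagging threshold (strict; 0)
#' @param rescue_min_identity,rescue_min_align_len genome-rescue thresholds
#' @param fc_thresh,fdr_thresh,unique_mean_thresh DE classification thresholds
#' @param tie_tol reciprocal-best-hit bit-score tie tolerance
#' @return config list of class `pipeline_config`
#' @export
pipeline_config <- function(outdir, simulate = NULL, inputs = NULL,
                            ai_threshold = 0, rescue_min_identity = 70.0,
                            rescue_min_align_len = 200, fc_thresh = 2.0,
                            fdr_thresh = 0.05, unique_mean_thresh = 2.0,
                            tie_tol = 0.0) {
  if (is.null(simulate) && is.null(inputs)) {
    abort_fmt("either a simulate block or input paths must be given")
  }
  structure(list(outdir = outdir, simulate = simulate, inputs = inputs,
                 ai_threshold = ai_threshold,
                 rescue_min_identity = rescue_min_identity,
                 rescue_min_align_len = rescue_min_align_len,
                 fc_thresh = fc_thresh, fdr_thresh = fdr_thresh,
                 unique_mean_thresh = unique_mean_thresh,
                 tie_tol = tie_tol),
            class = "pipeline_config")
}

#' Run the full analysis chain
#'
#' Executes the stages in fixed order, logs per-stage counts, writes the
#' stage tables and `report.json` under the configured output directory, and
#' returns the report. Any stage error aborts with the stage name; tables
#' written so far are moved under `failed/`.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress stage logging
#' @return report list (also written as `report.json`)
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "setup"
  on_fail <- function(e) {
    faildir <- file.path(outdir, "failed")
    dir.create(faildir, showWarnings = FALSE)
    written <- list.files(outdir, pattern = "\\.(tsv|json)$", full.names = TRUE)
    file.copy(written, faildir, overwrite = TRUE)
    abort_fmt("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  tryCatch({
    inputs <- config$inputs
    seed <- NA_integer_
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      seed <- config$simulate$seed
      truth <- generate_truth(config$simulate)
      inputs <- emit_files(truth, config$simulate, file.path(outdir, "sim"))
      say("simulate: %d transcripts (%d contaminants)", nrow(truth),
          sum(truth$is_contaminant))
    }

    stage <- "read"
    taxon_map <- read_taxon_map(inputs$taxon_map)
    transcripts <- read_fasta(inputs$fasta)
    orfs <- read_orfs(inputs$orfs)
    groups <- read_groups(inputs$groups, taxon_map)
    blastx <- read_blast_tab(inputs$blastx, taxon_map)
    blastn <- read_blast_tab(inputs$blastn, taxon_map)
    tissue_of <- read_tissue_map(inputs$tissue_map)
    counts <- read_counts(inputs$counts, tissue_of)
    stress_db <- read_stress_db(inputs$stress_db)
    stress_fwd <- utils::read.delim(inputs$stress_fwd, header = FALSE,
                                    stringsAsFactors = FALSE)[, c(1, 2, 12)]
    names(stress_fwd) <- c("query_id", "subject_id", "bitscore")
    stress_rev <- utils::read.delim(inputs$stress_rev, header = FALSE,
                                    stringsAsFactors = FALSE)[, c(1, 2, 12)]
    names(stress_rev) <- c("query_id", "subject_id", "bitscore")
    say("read: %d transcripts, %d ORFs, %d groups", nrow(transcripts),
        nrow(orfs), length(groups))

    stage <- "alien_screen"
    ai <- compute_alien_index(blastx, all_ids = transcripts$id)
    screen <- apply_screen(transcripts$id, ai, blastn,
                           min_identity = config$rescue_min_identity,
                           min_align_len = config$rescue_min_align_len)
    utils::write.table(
      within(screen$table, ai <- sprintf("%.6f", ai)),
      file.path(outdir, "alien_screen.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    say("alien_screen: %d flagged, %d rescued, %d removed, %d retained",
        screen$report$n_flagged, screen$report$n_rescued,
        screen$report$n_removed, screen$report$n_retained)

    stage <- "strata"
    retained_orfs <- orfs[orfs$transcript_id %in% screen$retained, ]
    membership <- membership_from_groups(groups)
    membership <- membership[names(membership) %in% retained_orfs$orf_id]
    strata <- assign_transcript_strata(groups, retained_orfs, membership)
    census <- stratum_census(strata)
    utils::write.table(strata, file.path(outdir, "strata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("strata: %s", paste(census$stratum, census$count, collapse = ", "))

    stage <- "diffexp"
    keep <- rownames(counts$counts) %in% screen$retained
    de <- run_de(counts$counts[keep, , drop = FALSE], counts$tissue_of)
    sets <- classify_de_sets(de, fc_thresh = config$fc_thresh,
                             fdr_thresh = config$fdr_thresh,
                             unique_mean_thresh = config$unique_mean_thresh)
    set_sizes <- lapply(sets, function(s) list(
      upregulated = length(s$upregulated), unique = length(s$unique)))
    say("diffexp: %s", paste(names(sets), vapply(sets, function(s)
      length(s$upregulated), numeric(1)), collapse = ", "))

    stage <- "enrichment"
    # transcripts without a qualifying ORF have no stratum and are excluded
    # from the enrichment panels
    with_stratum <- function(ids) ids[ids %in% strata$transcript_id]
    sets_str <- lapply(sets, function(s) list(
      upregulated = with_stratum(s$upregulated),
      unique = with_stratum(s$unique)))
    crosstab <- crosstab_proportions(strata, sets_str)
    stf <- single_tissue_fraction(strata, sets_str)
    utils::write.table(stf, file.path(outdir, "single_tissue_fraction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ct_long <- data.frame(
      class = rep(colnames(crosstab$counts), each = nrow(crosstab$counts)),
      stratum = rep(rownames(crosstab$counts), ncol(crosstab$counts)),
      count = as.vector(crosstab$counts),
      percent = as.vector(crosstab$percent), stringsAsFactors = FALSE)
    utils::write.table(ct_long, file.path(outdir, "crosstab.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "stress"
    pairs <- reciprocal_best_hits(stress_fwd, stress_rev, db = stress_db,
                                  tie_tol = config$tie_tol)
    stress <- lapply(sets, function(s) {
      if (length(s$upregulated) == 0) return(NULL)
      stress_census(s$upregulated, pairs)
    })
    utils::write.table(pairs, file.path(outdir, "stress_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "assembly_metrics"
    retained_tx <- transcripts[transcripts$id %in% screen$retained, ]
    asm <- summarize_assembly(retained_tx, retained_orfs, counts)

    stage <- "report"
    report <- list(
      seed = seed,
      thresholds = config[c("ai_threshold", "rescue_min_identity",
                            "rescue_min_align_len", "fc_thresh", "fdr_thresh",
                            "unique_mean_thresh", "tie_tol")],
      alien_screen = screen$report,
      stratum_census = census,
      de_set_sizes = set_sizes,
      crosstab = list(counts = crosstab$counts, percent = crosstab$percent,
                      cnidarian_sensu_lato = crosstab$cnidarian_sensu_lato),
      single_tissue_fraction = stf,
      stress = stress,
      assembly = asm
    )
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10,
                         na = "null")
    report
  }, error = on_fail)
}
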