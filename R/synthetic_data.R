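# Seeded generator for a complete, internally consistent synthetic study:
# transcript sequences, ORF table, ortholog groups realizing planted
# phylostrata, homology tables with planted contaminants (strictly better
# non-metazoan E-values), a genome-alignment table realizing planted
# rescues, an NB count matrix with planted tissue-specific upregulation and
# uniquely expressed transcripts, and a categorized stress database with
# planted reciprocal-best-hit pairs. All class sizes are planted by exact
# assignment, never by Bernoulli sampling, so recovery tests have fixed
# denominators.

#' Default taxon map used by the synthetic study
#' @export
sim_taxon_map <- function() {
  c(NVEC = "NVEC_SELF", NVJGI = "NVEC_JGI", NVTEC = "NVEC_TECHNAU",
    ELIN = "EDWARDSIELLA", ADIG = "ANTHOZOAN", HMAG = "CNIDARIAN_OTHER",
    HSAP = "METAZOAN_OUTGROUP",
    SCER = "NONMETAZOAN_EUK", HALO = "ARCHAEA", ECOL = "BACTERIA",
    GENOME = "NVEC_SELF")
}

# prefix used to plant a group pinned at exactly each stratum
.stratum_partner <- c(EDWARDSIIDAE = "ELIN", ANTHOZOA = "ADIG",
                      CNIDARIA = "HMAG", METAZOA = "HSAP")

#' Build a simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 2000 transcripts split across strata in the proportions of the real
#' census, three tissues with three replicates each (sample names follow the
#' study's scheme), NB counts with dispersion 0.1 over a log-normal baseline,
#' 10% of transcripts planted as upregulated per tissue at log2FC 3 (baseline
#' mean floored at 50 so the planted effect is identifiable), 20% of planted
#' DE transcripts uniquely expressed (literal zeros elsewhere), 50
#' contaminants of which half meet the genome-rescue criterion, and 22% of
#' each tissue's planted DE set carrying a stress annotation with category
#' weights proportional to the published database's category sizes.
#'
#' @param seed integer RNG seed; all generator randomness flows from it
#' @param n_per_stratum named integer vector over the five strata
#' @param n_contaminants number of planted foreign transcripts
#' @param n_replicates replicates per tissue (>= 2)
#' @param baseline_log_mean,baseline_log_sd log-normal prior on NB means
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @param de_fraction_per_tissue fraction of non-contaminant transcripts
#'   planted as upregulated in each tissue (disjoint across tissues)
#' @param de_log2fc planted log2 fold change
#' @param de_min_baseline_mean floor on planted-DE baseline means
#' @param unique_fraction fraction of each tissue's planted DE set forced to
#'   zero expression in the other tissues
#' @param rescue_fraction fraction of contaminants planted with a qualifying
#'   genome alignment
#' @param stress_fraction fraction of each tissue's planted DE set given a
#'   reciprocal-best-hit stress partner
#' @param stress_category_weights weights over wound/pathogen/chemical
#'   (normalized to sum 1)
#' @param stress_db_extra decoy (unpaired) stress genes per category
#' @param tissues three tissue labels
#' @param seq_len_range transcript length range, nt
#' @return validated config list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       n_per_stratum = c(NEMATOSTELLA = 322, EDWARDSIIDAE = 41,
                                         ANTHOZOA = 290, CNIDARIA = 144,
                                         METAZOA = 1203),
                       n_contaminants = 50,
                       n_replicates = 3,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1,
                       dispersion = 0.1,
                       de_fraction_per_tissue = 0.1,
                       de_log2fc = 3,
                       de_min_baseline_mean = 50,
                       unique_fraction = 0.2,
                       rescue_fraction = 0.5,
                       stress_fraction = 0.22,
                       stress_category_weights = c(wound = 741, pathogen = 1984,
                                                   chemical = 187) / 2912,
                       stress_db_extra = 10,
                       tissues = c("mesentery", "nematosome", "tentacle"),
                       seq_len_range = c(200, 800)) {
  stopifnot(all(STRATA %in% names(n_per_stratum)))
  n_per_stratum <- n_per_stratum[STRATA]
  frac <- c(de_fraction_per_tissue, unique_fraction, rescue_fraction,
            stress_fraction)
  if (any(frac < 0 | frac > 1)) abort_fmt("fractions must lie in [0, 1]")
  if (any(n_per_stratum < 0) || n_contaminants < 0) {
    abort_fmt("class sizes must be non-negative")
  }
  if (n_replicates < 2) abort_fmt("need at least 2 replicates per tissue")
  if (length(tissues) != 3) abort_fmt("exactly 3 tissues required")
  if (dispersion < 0) abort_fmt("dispersion must be >= 0")
  if (de_log2fc < 0) abort_fmt("de_log2fc must be >= 0")
  n_total <- sum(n_per_stratum)
  if (3 * round(de_fraction_per_tissue * n_total) > n_total) {
    abort_fmt("de_fraction_per_tissue too large for disjoint per-tissue sets")
  }
  w <- stress_category_weights / sum(stress_category_weights)
  structure(list(
    seed = as.integer(seed), n_per_stratum = n_per_stratum,
    n_contaminants = as.integer(n_contaminants),
    n_replicates = as.integer(n_replicates),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    de_fraction_per_tissue = de_fraction_per_tissue,
    de_log2fc = de_log2fc, de_min_baseline_mean = de_min_baseline_mean,
    unique_fraction = unique_fraction, rescue_fraction = rescue_fraction,
    stress_fraction = stress_fraction, stress_category_weights = w,
    stress_db_extra = as.integer(stress_db_extra),
    tissues = tissues, seq_len_range = seq_len_range
  ), class = "sim_config")
}

# split n into named category counts matching weights exactly (largest
# remainder), so planted sizes are exact, not expected
.apportion <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate the planted ground truth
#'
#' Deterministic given the config seed. Every planted class has exactly the
#' configured size.
#'
#' @param config a [sim_config()]
#' @return data.frame, one row per transcript: `transcript_id`, `stratum`
#'   (NA for contaminants), `is_contaminant`, `de_tissue` (NA when not
#'   planted DE), `is_unique`, `is_rescued` (contaminants only),
#'   `stress_category` and `stress_gene` (NA unless planted),
#'   `baseline_mean`
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_clean <- sum(config$n_per_stratum)
  n_total <- n_clean + config$n_contaminants
  ids <- sprintf("TX%05d", seq_len(n_total))
  clean_ids <- ids[seq_len(n_clean)]
  contam_ids <- ids[-seq_len(n_clean)]

  stratum <- rep(NA_character_, n_total)
  stratum[seq_len(n_clean)] <- rep(STRATA, times = config$n_per_stratum)

  # planted DE: disjoint per-tissue sets of exact size, drawn across strata
  # the randomized pool decorrelates planted DE/unique/stress status from
  # the stratum blocks
  n_de <- round(config$de_fraction_per_tissue * n_clean)
  de_tissue <- rep(NA_character_, n_total)
  pool <- sample(clean_ids)
  de_ids_of <- list()
  for (k in seq_along(config$tissues)) {
    take <- pool[seq_len(n_de) + (k - 1) * n_de]
    de_tissue[match(take, ids)] <- config$tissues[k]
    de_ids_of[[config$tissues[k]]] <- take
  }

  # unique subset: exact count per tissue, leading ids in draw order
  is_unique <- rep(FALSE, n_total)
  n_uni <- round(config$unique_fraction * n_de)
  for (t in config$tissues) {
    is_unique[match(de_ids_of[[t]][seq_len(n_uni)], ids)] <- TRUE
  }

  # rescued subset of contaminants: exact count
  is_rescued <- rep(FALSE, n_total)
  n_res <- round(config$rescue_fraction * config$n_contaminants)
  if (n_res > 0) is_rescued[match(contam_ids[seq_len(n_res)], ids)] <- TRUE

  # stress annotation: exact count per tissue among planted DE, with
  # category counts apportioned to the weights
  stress_category <- rep(NA_character_, n_total)
  stress_gene <- rep(NA_character_, n_total)
  gene_counter <- 0
  n_stress <- round(config$stress_fraction * n_de)
  for (t in config$tissues) {
    # trailing ids in draw order, so stress status is independent of
    # uniqueness wherever the two subsets do not overlap
    chosen <- rev(de_ids_of[[t]])[seq_len(n_stress)]
    cats <- rep(names(config$stress_category_weights),
                times = .apportion(n_stress, config$stress_category_weights))
    stress_category[match(chosen, ids)] <- cats
    stress_gene[match(chosen, ids)] <-
      sprintf("SG%04d", gene_counter + seq_along(chosen))
    gene_counter <- gene_counter + length(chosen)
  }

  baseline_mean <- exp(stats::rnorm(n_total, config$baseline_log_mean,
                                    config$baseline_log_sd))
  planted <- !is.na(de_tissue)
  baseline_mean[planted] <- pmax(baseline_mean[planted],
                                 config$de_min_baseline_mean)

  data.frame(
    transcript_id = ids, stratum = stratum,
    is_contaminant = ids %in% contam_ids,
    de_tissue = de_tissue, is_unique = is_unique, is_rescued = is_rescued,
    stress_category = stress_category, stress_gene = stress_gene,
    baseline_mean = baseline_mean,
    stringsAsFactors = FALSE
  )
}

# fixed-format scientific notation so emitted files are byte-stable
.fmt_e <- function(x) sprintf("%.3e", x)
.fmt_f <- function(x) sprintf("%.1f", x)

.blast_row <- function(q, s, pid, len, ev, bits) {
  paste(q, s, .fmt_f(pid), len, 0, 0, 1, len, 1, len, .fmt_e(ev),
        .fmt_f(bits), sep = "\t")
}

#' Sample names following the study's three-tissue scheme
#'
#' With 3 replicates the mesentery samples are M3, M4, Mes; nematosomes N1,
#' N2, Nem; tentacles T3, T4, Ten. Other replicate counts fall back to
#' `<tissue>_<k>`.
#'
#' @param tissues three tissue labels (mesentery/nematosome/tentacle order)
#' @param r replicates per tissue
#' @return named character vector sample id -> tissue
#' @export
sim_sample_map <- function(tissues, r = 3) {
  if (r == 3 && identical(tissues, c("mesentery", "nematosome", "tentacle"))) {
    stats::setNames(rep(tissues, each = 3),
                    c("M3", "M4", "Mes", "N1", "N2", "Nem", "T3", "T4", "Ten"))
  } else {
    nm <- unlist(lapply(tissues, function(t) paste(t, seq_len(r), sep = "_")))
    stats::setNames(rep(tissues, each = r), nm)
  }
}

#' Simulate the count matrix for a planted truth table
#'
#' NB draws (variance = mu + dispersion * mu^2) around each transcript's
#' baseline mean, multiplied by `2^de_log2fc` in the planted tissue for DE
#' transcripts; uniquely expressed transcripts get literal zeros outside
#' their tissue. Uses the current RNG state, so seed before calling (or rely
#' on the stream set by [generate_truth()] when used inside [emit_files()]).
#'
#' @param truth output of [generate_truth()]
#' @param config the same [sim_config()]
#' @return list with `counts` (integer matrix, transcripts x samples) and
#'   `tissue_of` (named character vector), as from [read_counts()]
#' @export
sim_counts <- function(truth, config) {
  ids <- truth$transcript_id
  tissue_of <- sim_sample_map(config$tissues, config$n_replicates)
  samples <- names(tissue_of)
  mu <- outer(truth$baseline_mean, rep(1, length(samples)))
  for (i in which(!is.na(truth$de_tissue))) {
    up_cols <- tissue_of == truth$de_tissue[i]
    mu[i, up_cols] <- mu[i, up_cols] * 2^config$de_log2fc
    if (truth$is_unique[i]) mu[i, !up_cols] <- 0
  }
  draw <- function(m) {
    if (m == 0) return(0)
    if (config$dispersion > 0) {
      stats::rnbinom(1, mu = m, size = 1 / config$dispersion)
    } else {
      stats::rpois(1, m)
    }
  }
  counts <- matrix(as.integer(vapply(as.vector(t(mu)), draw, numeric(1))),
                   nrow = length(ids), byrow = TRUE,
                   dimnames = list(ids, samples))
  list(counts = counts, tissue_of = tissue_of)
}

#' Emit the synthetic study's files
#'
#' Writes every input the downstream chain reads: FASTA sequences, ORF
#' table, ortholog groups whose membership realizes each transcript's
#' planted stratum, a protein-homology table in which contaminants have a
#' strictly better non-metazoan E-value (disjoint exponent ranges guarantee
#' the alien-index sign), a genome-alignment table realizing planted
#' rescues, the count matrix, the stress database and forward/reverse
#' stress-hit tables realizing the planted reciprocal-best pairs, taxon and
#' tissue maps, and the truth table. Byte-identical for identical
#' config + seed.
#'
#' @param truth output of [generate_truth()]
#' @param config the same [sim_config()]
#' @param outdir output directory (created if needed)
#' @return named list of file paths (the manifest, also written as JSON)
#' @export
emit_files <- function(truth, config, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) abort_fmt("cannot create outdir: %s", outdir)
  }
  set.seed(config$seed + 1L)
  ids <- truth$transcript_id
  n <- length(ids)
  p <- function(f) file.path(outdir, f)

  ## FASTA
  lens <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]), n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  writeLines(paste0(">", ids, "\n", seqs), p("transcripts.fa"))

  ## ORFs: one per clean transcript; every 5th gets a second (unclustered,
  ## hence lineage-restricted) ORF to exercise the aggregation rule
  clean <- !truth$is_contaminant
  orf1 <- sprintf("%s.p1", ids[clean])
  second <- which(clean)[seq(5, sum(clean), by = 5)]
  orf2 <- sprintf("%s.p2", ids[second])
  orfs <- data.frame(
    transcript_id = c(ids[clean], ids[second]),
    orf_id = c(orf1, orf2),
    aa_length = c(100 + (lens[clean] %% 200), 100 + (lens[second] %% 150)),
    stringsAsFactors = FALSE
  )
  orfs <- orfs[order(orfs$transcript_id, orfs$orf_id), ]
  utils::write.table(orfs, p("orfs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## groups: one per primary ORF, members pinning exactly the true stratum
  gl <- character(sum(clean))
  ci <- which(clean)
  for (j in seq_along(ci)) {
    i <- ci[j]
    st <- truth$stratum[i]
    members <- paste0("NVEC|", ids[i], ".p1")
    if (st == "NEMATOSTELLA") {
      if (j %% 2 == 0) members <- c(members, sprintf("NVJGI|jgi%05d", j))
    } else {
      members <- c(members, sprintf("%s|s%05d", .stratum_partner[st], j))
      if (j %% 3 == 0) members <- c(members, sprintf("ELIN|e%05d", j))
    }
    gl[j] <- sprintf("G%05d: %s", j, paste(members, collapse = " "))
  }
  writeLines(gl, p("groups.txt"))

  ## blastx vs taxon-partitioned protein DB (disjoint exponent ranges)
  good_u <- stats::runif(n, 30, 80)   # exponent of the better side
  weak_u <- stats::runif(n, 1, 10)    # exponent of the worse side
  bx <- character(2 * n)
  for (i in seq_len(n)) {
    e_good <- 10^(-good_u[i]); e_weak <- 10^(-weak_u[i])
    if (truth$is_contaminant[i]) {
      e_m <- e_weak; e_nm <- e_good
    } else {
      e_m <- e_good; e_nm <- e_weak
    }
    bx[2 * i - 1] <- .blast_row(ids[i], sprintf("HSAP|prot%05d", i), 60,
                                150, e_m, 80 + good_u[i])
    bx[2 * i] <- .blast_row(ids[i], sprintf("ECOL|prot%05d", i), 55,
                            140, e_nm, 70 + weak_u[i])
  }
  writeLines(bx, p("blastx.tsv"))

  ## blastn vs genome: qualifying row for rescued contaminants, a failing
  ## row for half the rest, none otherwise
  bn <- character(0)
  for (i in which(truth$is_contaminant)) {
    if (truth$is_rescued[i]) {
      bn <- c(bn, .blast_row(ids[i], "GENOME|scaffold1",
                             stats::runif(1, 80, 99),
                             sample(250:900, 1), 1e-30, 500))
    } else if (i %% 2 == 0) {
      bn <- c(bn, .blast_row(ids[i], "GENOME|scaffold1",
                             stats::runif(1, 30, 60),
                             sample(50:150, 1), 1e-3, 60))
    }
  }
  writeLines(bn, p("blastn_genome.tsv"))

  ## counts: NB draws around the planted means; literal zeros elsewhere for
  ## unique transcripts
  cm <- sim_counts(truth, config)
  tissue_of <- cm$tissue_of
  ctab <- cbind(data.frame(transcript_id = ids, stringsAsFactors = FALSE),
                as.data.frame(cm$counts))
  utils::write.table(ctab, p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stress DB and forward/reverse hit tables with planted RBH pairs
  planted <- which(!is.na(truth$stress_gene))
  db <- data.frame(gene_id = truth$stress_gene[planted],
                   category = truth$stress_category[planted],
                   stringsAsFactors = FALSE)
  extra <- expand.grid(k = seq_len(config$stress_db_extra),
                       category = names(config$stress_category_weights),
                       stringsAsFactors = FALSE)
  if (nrow(extra) > 0) {
    db <- rbind(db, data.frame(
      gene_id = sprintf("SGX%03d", seq_len(nrow(extra))),
      category = extra$category, stringsAsFactors = FALSE))
  }
  db <- db[order(db$gene_id), ]
  utils::write.table(db, p("stress_db.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  fwd <- character(0); rev <- character(0)
  decoys <- db$gene_id[startsWith(db$gene_id, "SGX")]
  for (i in planted) {
    g <- truth$stress_gene[i]; t <- ids[i]
    hi <- stats::runif(1, 180, 220)
    fwd <- c(fwd, .blast_row(t, g, 70, 120, 1e-40, hi))
    rev <- c(rev, .blast_row(g, t, 70, 120, 1e-40, hi))
    if (length(decoys) > 0 && i %% 3 == 0) {
      # weaker forward hit to a decoy gene; never that gene's reverse best
      d <- decoys[1 + (i %% length(decoys))]
      fwd <- c(fwd, .blast_row(t, d, 50, 90, 1e-10,
                               stats::runif(1, 100, 150)))
    }
  }
  # decoy genes point back at a planted transcript that does not reciprocate
  if (length(planted) > 1 && length(decoys) > 0) {
    for (k in seq_along(decoys)) {
      t_other <- ids[planted[1 + (k %% length(planted))]]
      rev <- c(rev, .blast_row(decoys[k], t_other, 45, 80, 1e-5,
                               stats::runif(1, 60, 90)))
    }
  }
  writeLines(fwd, p("stress_fwd.tsv"))
  writeLines(rev, p("stress_rev.tsv"))

  ## maps and truth
  jsonlite::write_json(as.list(sim_taxon_map()), p("taxon_map.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(as.list(tissue_of), p("tissue_map.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  tt <- truth
  tt$baseline_mean <- sprintf("%.6f", tt$baseline_mean)
  utils::write.table(tt, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    fasta = p("transcripts.fa"), orfs = p("orfs.tsv"),
    groups = p("groups.txt"), blastx = p("blastx.tsv"),
    blastn = p("blastn_genome.tsv"), counts = p("counts.tsv"),
    stress_db = p("stress_db.tsv"), stress_fwd = p("stress_fwd.tsv"),
    stress_rev = p("stress_rev.tsv"), taxon_map = p("taxon_map.json"),
    tissue_map = p("tissue_map.json"), truth = p("truth.tsv")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}

#' Derive the ORF-to-group membership from a groups file
#'
#' Members carrying the assembly's own prefix (default `NVEC`) whose suffix
#' matches an ORF id define the membership map used by
#' [assign_transcript_strata()].
#'
#' @param groups list from [read_groups()]
#' @param self_prefix prefix of the assembly's own sequences
#' @param delim prefix delimiter
#' @return named character vector orf_id -> group_id
#' @export
membership_from_groups <- function(groups, self_prefix = "NVEC", delim = "|") {
  out <- character(0)
  for (g in groups) {
    m <- g$members
    own <- m$prefix == self_prefix
    if (!any(own)) next
    suff <- substring(m$member_id[own], nchar(self_prefix) + nchar(delim) + 1)
    out[suff] <- g$group_id
  }
  out
}
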