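mk_hits <- function(q, class, evalue) {
  data.frame(query_id = q, subject_id = paste0(class, "|x"),
             pct_identity = 50, align_length = 100,
             evalue = evalue, bitscore = 100,
             subject_class = class, stringsAsFactors = FALSE)
}

test_that("alien index follows the log E-value ratio with defaults", {
  h <- rbind(mk_hits("q", "METAZOAN_OUTGROUP", 1e-50),
             mk_hits("q", "BACTERIA", 1e-80))
  r <- compute_alien_index(h)
  expect_equal(r$ai, 30 * log(10), tolerance = 1e-6)
  expect_true(r$flagged)

  h <- rbind(mk_hits("q", "METAZOAN_OUTGROUP", 1e-20),
             mk_hits("q", "NONMETAZOAN_EUK", 1e-20))
  r <- compute_alien_index(h)
  expect_equal(r$ai, 0)
  expect_false(r$flagged)  # strict > 0

  # one-sided: missing side defaults to E = 1
  r <- compute_alien_index(mk_hits("q", "METAZOAN_OUTGROUP", 1e-10))
  expect_equal(r$ai, log(1e-10 + 1e-200) - log(1 + 1e-200), tolerance = 1e-9)
  expect_equal(r$ai, -23.026, tolerance = 1e-3)
  expect_false(r$flagged)

  # no hits at all: both defaults, ai = 0
  r <- compute_alien_index(mk_hits("q", "BACTERIA", 1)[0, ], all_ids = "q")
  expect_equal(r$ai, 0)
  expect_false(r$flagged)
})

test_that("alien index is antisymmetric and monotone in the foreign hit", {
  for (seed in 1:5) {
    h <- random_hits(40, paste0("q", 1:8),
                     c("METAZOAN_OUTGROUP", "ANTHOZOAN", "BACTERIA",
                       "NONMETAZOAN_EUK"), seed)
    r <- compute_alien_index(h)
    swapped <- h
    map <- c(METAZOAN_OUTGROUP = "BACTERIA", ANTHOZOAN = "NONMETAZOAN_EUK",
             BACTERIA = "METAZOAN_OUTGROUP", NONMETAZOAN_EUK = "ANTHOZOAN")
    swapped$subject_class <- unname(map[h$subject_class])
    r2 <- compute_alien_index(swapped)
    expect_equal(r2$ai[match(r$transcript_id, r2$transcript_id)], -r$ai,
                 tolerance = 1e-12)

    # a strictly better foreign hit never decreases ai
    extra <- mk_hits(r$transcript_id[1], "BACTERIA",
                     min(h$evalue[h$query_id == r$transcript_id[1]]) / 10)
    r3 <- compute_alien_index(rbind(h, extra))
    expect_gte(r3$ai[r3$transcript_id == r$transcript_id[1]],
               r$ai[r$transcript_id == r$transcript_id[1]])
  }
})

test_that("apply_screen implements the rescue rule and partitions the input", {
  ids <- c("a", "b", "c")
  ai <- compute_alien_index(rbind(
    mk_hits("a", "BACTERIA", 1e-60),  # flagged
    mk_hits("b", "BACTERIA", 1e-60),  # flagged
    mk_hits("c", "METAZOAN_OUTGROUP", 1e-60)))
  genome <- data.frame(query_id = c("a", "b"),
                       pct_identity = c(85, 85),
                       align_length = c(300, 150),  # b fails the 200-bp floor
                       stringsAsFactors = FALSE)
  res <- apply_screen(ids, ai, genome)
  expect_equal(res$removed, "b")
  expect_setequal(res$retained, c("a", "c"))
  expect_setequal(c(res$retained, res$removed), ids)
  expect_length(intersect(res$retained, res$removed), 0)

  # nothing flagged: everything retained
  ai2 <- compute_alien_index(mk_hits("a", "METAZOAN_OUTGROUP", 1e-5),
                             all_ids = ids)
  res2 <- apply_screen(ids, ai2, NULL)
  expect_equal(res2$retained, ids)
  expect_length(res2$removed, 0)

  expect_error(apply_screen(c(ids, "zzz"), ai, genome), "zzz")
})

test_that("identity must exceed 70 strictly; length 200 is inclusive", {
  ai <- compute_alien_index(mk_hits("a", "BACTERIA", 1e-60))
  at_cut <- data.frame(query_id = "a", pct_identity = 70, align_length = 500,
                       stringsAsFactors = FALSE)
  expect_equal(apply_screen("a", ai, at_cut)$removed, "a")
  at_len <- data.frame(query_id = "a", pct_identity = 71, align_length = 200,
                       stringsAsFactors = FALSE)
  expect_length(apply_screen("a", ai, at_len)$removed, 0)
})

test_that("on synthetic data the removed set is exactly contaminants minus rescues", {
  cfg <- sim_config(seed = 11,
                    n_per_stratum = c(NEMATOSTELLA = 30, EDWARDSIIDAE = 5,
                                      ANTHOZOA = 20, CNIDARIA = 10, METAZOA = 60),
                    n_contaminants = 20, rescue_fraction = 0.25)
  truth <- generate_truth(cfg)
  out <- emit_files(truth, cfg, withr::local_tempdir())
  tm <- read_taxon_map(out$taxon_map)
  blastx <- read_blast_tab(out$blastx, tm)
  blastn <- read_blast_tab(out$blastn, tm)
  ai <- compute_alien_index(blastx, all_ids = truth$transcript_id)
  res <- apply_screen(truth$transcript_id, ai, blastn)
  expect_setequal(res$removed,
                  truth$transcript_id[truth$is_contaminant & !truth$is_rescued])
  expect_equal(res$report$n_flagged, 20)
  expect_equal(res$report$n_rescued, 5)
})
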