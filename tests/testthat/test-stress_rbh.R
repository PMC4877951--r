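hit <- function(q, s, bits) {
  data.frame(query_id = q, subject_id = s, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("canonical, tied and one-directional cases behave as specified", {
  db <- c(g1 = "wound", g2 = "pathogen")

  # canonical reciprocal best hit
  pairs <- reciprocal_best_hits(hit("t1", "g1", 200), hit("g1", "t1", 190), db)
  expect_equal(pairs$transcript_id, "t1")
  expect_equal(pairs$stress_gene_ids, "g1")

  # exact tie across two categories: both genes kept
  fwd <- rbind(hit("t1", "g1", 200), hit("t1", "g2", 200))
  rev <- rbind(hit("g1", "t1", 180), hit("g2", "t1", 180))
  pairs <- reciprocal_best_hits(fwd, rev, db)
  expect_equal(pairs$n_genes, 2L)
  expect_equal(pairs$categories, "pathogen,wound")

  # t1's best is g1 but g1's best is t2: no pair for t1
  fwd <- hit("t1", "g1", 200)
  rev <- rbind(hit("g1", "t2", 250), hit("g1", "t1", 100))
  expect_equal(nrow(reciprocal_best_hits(fwd, rev, db)), 0)

  expect_error(reciprocal_best_hits(hit("t1", "mystery", 10),
                                    hit("mystery", "t1", 10), db), "mystery")
})

test_that("RBH is symmetric in direction and monotone in the tie tolerance", {
  set.seed(21)
  for (rep in 1:5) {
    tx <- paste0("t", 1:12); genes <- paste0("g", 1:10)
    fwd <- expand.grid(query_id = tx, subject_id = genes,
                       stringsAsFactors = FALSE)
    fwd <- fwd[sample(nrow(fwd), 40), ]
    fwd$bitscore <- round(runif(40, 50, 250), 1)
    rev <- expand.grid(query_id = genes, subject_id = tx,
                       stringsAsFactors = FALSE)
    rev <- rev[sample(nrow(rev), 40), ]
    rev$bitscore <- round(runif(40, 50, 250), 1)

    flatten <- function(p, swap = FALSE) {
      if (nrow(p) == 0) return(character(0))
      out <- unlist(mapply(function(a, bs) {
        b <- strsplit(bs, ",")[[1]]
        if (swap) paste(b, a, sep = "->") else paste(a, b, sep = "->")
      }, p$transcript_id, p$stress_gene_ids, SIMPLIFY = FALSE))
      sort(unname(out))
    }
    p1 <- reciprocal_best_hits(fwd, rev)
    p2 <- reciprocal_best_hits(rev, fwd)
    expect_equal(flatten(p1), flatten(p2, swap = TRUE))

    # matches the exhaustive oracle
    expect_equal(flatten(p1), unname(oracle_rbh(fwd, rev)))

    # enlarging tie_tol never removes a pair
    p3 <- reciprocal_best_hits(fwd, rev, tie_tol = 25)
    expect_true(all(flatten(p1) %in% flatten(p3)))
    expect_equal(flatten(p3), unname(oracle_rbh(fwd, rev, 25)))
  }
})

test_that("stress census reproduces the printed annotation rates", {
  fx <- stress_fixture()
  pairs <- reciprocal_best_hits(fx$fwd, fx$rev, fx$db)
  cen <- stress_census(fx$upregulated, pairs)
  expect_equal(cen$n_annotated, 116)
  expect_equal(cen$overall_percent, 22)
  bc <- cen$by_category
  expect_equal(bc$count[bc$category == "pathogen"], 87L)
  expect_equal(bc$percent[bc$category == "pathogen"], 75)
  # with no ties, category counts sum exactly to the annotated total
  expect_equal(sum(bc$count), cen$n_annotated)

  # a two-category tie pushes the category sum above the annotated total
  fwd <- rbind(fx$fwd, hit("nem_up_0200", "SG0001", 300),
               hit("nem_up_0200", "SG0088", 300))
  rev <- rbind(fx$rev[-c(1, 88), ], hit("SG0001", "nem_up_0200", 300),
               hit("SG0088", "nem_up_0200", 300))
  pairs2 <- reciprocal_best_hits(fwd, rev, fx$db)
  cen2 <- stress_census(fx$upregulated, pairs2)
  expect_gt(sum(cen2$by_category$count), cen2$n_annotated)

  expect_equal(stress_census("t1", pairs[0, ])$n_annotated, 0)
  expect_error(stress_census(character(0), pairs), "empty")
})

test_that("recovered pairs equal the planted reciprocal pairs on synthetic data", {
  cfg <- sim_config(seed = 13,
                    n_per_stratum = c(NEMATOSTELLA = 40, EDWARDSIIDAE = 10,
                                      ANTHOZOA = 30, CNIDARIA = 20,
                                      METAZOA = 100),
                    n_contaminants = 0, stress_fraction = 0.5)
  truth <- generate_truth(cfg)
  out <- emit_files(truth, cfg, withr::local_tempdir())
  db <- read_stress_db(out$stress_db)
  fwd <- utils::read.delim(out$stress_fwd, header = FALSE)[, c(1, 2, 12)]
  names(fwd) <- c("query_id", "subject_id", "bitscore")
  rev <- utils::read.delim(out$stress_rev, header = FALSE)[, c(1, 2, 12)]
  names(rev) <- c("query_id", "subject_id", "bitscore")
  pairs <- reciprocal_best_hits(fwd, rev, db)
  planted <- truth[!is.na(truth$stress_gene), ]
  expect_setequal(pairs$transcript_id, planted$transcript_id)
  expect_equal(
    pairs$stress_gene_ids[match(planted$transcript_id, pairs$transcript_id)],
    planted$stress_gene)
  # categories recovered through the DB match the planted categories
  expect_equal(
    pairs$categories[match(planted$transcript_id, pairs$transcript_id)],
    planted$stress_category)
})
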