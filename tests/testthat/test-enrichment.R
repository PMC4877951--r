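test_that("crosstab reproduces the printed per-class stratum percentages", {
  fx <- fig8_fixture()
  ct <- crosstab_proportions(fx$strata, fx$sets)

  # reference column: full census percentages
  expect_equal(ct$totals[["all_expressed"]], 17313)
  expect_equal(ct$percent["NEMATOSTELLA", "all_expressed"], 16)
  expect_equal(ct$percent["METAZOA", "all_expressed"], 60)

  # upregulated columns
  expect_equal(ct$counts["NEMATOSTELLA", "upregulated_nematosome"], 135L)
  expect_equal(ct$totals[["upregulated_nematosome"]], 528)
  expect_equal(ct$percent["NEMATOSTELLA", "upregulated_nematosome"], 26)
  expect_equal(ct$percent["NEMATOSTELLA", "upregulated_tentacle"], 31)

  # unique column
  expect_equal(ct$percent["NEMATOSTELLA", "unique_nematosome"], 65)

  # cnidarian-sensu-lato aggregate of the nematosome upregulated column:
  # (528 - 170 metazoan) / 528
  csl <- ct$cnidarian_sensu_lato
  expect_equal(csl$percent[csl$class == "upregulated_nematosome"], 68)

  # column conservation
  expect_equal(unname(colSums(ct$counts)), unname(ct$totals))
  # unique counts never exceed upregulated counts stratum-wise
  for (t in names(fx$sets)) {
    expect_true(all(ct$counts[, paste0("unique_", t)] <=
                    ct$counts[, paste0("upregulated_", t)]))
  }
})

test_that("empty class columns are flagged undefined, missing strata error", {
  strata <- data.frame(transcript_id = c("a", "b"),
                       stratum = c("METAZOA", "NEMATOSTELLA"),
                       stringsAsFactors = FALSE)
  sets <- list(nematosome = list(upregulated = "a", unique = character(0)))
  ct <- crosstab_proportions(strata, sets)
  expect_true(all(is.na(ct$percent[, "unique_nematosome"])))
  expect_equal(sum(ct$counts[, "unique_nematosome"]), 0L)

  sets_bad <- list(nematosome = list(upregulated = c("a", "ghost"),
                                     unique = character(0)))
  expect_error(crosstab_proportions(strata, sets_bad), "ghost")
})

test_that("single-tissue fractions reproduce the printed group percentages", {
  fx <- fig8_fixture()
  stf <- single_tissue_fraction(fx$strata, fx$sets)
  g <- function(x, col) stf[[col]][stf$group == x]
  expect_equal(g("METAZOA", "n_unique"), 62)
  expect_equal(g("METAZOA", "n_de"), 709)
  expect_equal(g("METAZOA", "percent"), 9)
  expect_equal(g("CNIDARIAN_SENSU_LATO", "n_de"), 1632)
  expect_equal(g("CNIDARIAN_SENSU_LATO", "n_unique"), 344)
  expect_equal(g("CNIDARIAN_SENSU_LATO", "percent"), 21)
  # 203/667 rounds to 30 (the arithmetic, not the discrepant caption figure)
  expect_equal(g("NEMATOSTELLA", "n_unique"), 203)
  expect_equal(g("NEMATOSTELLA", "n_de"), 667)
  expect_equal(g("NEMATOSTELLA", "percent"), 30)
  expect_true(all(stf$fraction >= 0 & stf$fraction <= 1))

  # degenerate: a group with no upregulated members is undefined
  strata <- data.frame(transcript_id = "a", stratum = "METAZOA",
                       stringsAsFactors = FALSE)
  sets <- list(x = list(upregulated = "a", unique = "a"))
  stf2 <- single_tissue_fraction(strata, sets)
  expect_true(is.na(stf2$fraction[stf2$group == "NEMATOSTELLA"]))
  expect_equal(stf2$percent[stf2$group == "METAZOA"], 100)
})

test_that("crosstab agrees with a brute-force tally of the synthetic truth", {
  cfg <- sim_config(seed = 9,
                    n_per_stratum = c(NEMATOSTELLA = 40, EDWARDSIIDAE = 10,
                                      ANTHOZOA = 30, CNIDARIA = 20,
                                      METAZOA = 100),
                    n_contaminants = 0)
  truth <- generate_truth(cfg)
  # sets straight from the truth table (planted, not recovered)
  sets <- lapply(setNames(cfg$tissues, cfg$tissues), function(t) {
    de <- truth$transcript_id[!is.na(truth$de_tissue) & truth$de_tissue == t]
    list(upregulated = de,
         unique = de[truth$is_unique[match(de, truth$transcript_id)]])
  })
  strata <- data.frame(transcript_id = truth$transcript_id,
                       stratum = truth$stratum, stringsAsFactors = FALSE)
  ct <- crosstab_proportions(strata, sets)
  for (t in cfg$tissues) {
    for (st in STRATA) {
      brute <- sum(truth$stratum == st & !is.na(truth$de_tissue) &
                   truth$de_tissue == t)
      expect_equal(unname(ct$counts[st, paste0("upregulated_", t)]), brute)
      brute_u <- sum(truth$stratum == st & truth$is_unique &
                     !is.na(truth$de_tissue) & truth$de_tissue == t)
      expect_equal(unname(ct$counts[st, paste0("unique_", t)]), brute_u)
    }
  }
  stf <- single_tissue_fraction(strata, sets)
  expect_equal(stf$n_de[stf$group == "CNIDARIAN_SENSU_LATO"],
               sum(!is.na(truth$de_tissue) & truth$stratum != "METAZOA"))
})
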