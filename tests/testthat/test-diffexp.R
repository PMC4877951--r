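# small helper: counts matrix with the study's 3x3 sample scheme
tissue_of_9 <- sim_sample_map(c("mesentery", "nematosome", "tentacle"), 3)

test_that("median-of-ratios size factors behave on closed-form cases", {
  m <- matrix(rep(c(10L, 20L, 40L), 4), nrow = 3, ncol = 4,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  nf <- normalize_counts(m)
  expect_equal(unname(nf$size_factors), rep(1, 4))  # identical columns

  m2 <- cbind(s1 = c(10L, 20L, 40L), s2 = c(20L, 40L, 80L))
  rownames(m2) <- paste0("t", 1:3)
  nf2 <- normalize_counts(m2)
  expect_equal(unname(nf2$size_factors[2] / nf2$size_factors[1]), 2)
  expect_equal(exp(mean(log(nf2$size_factors))), 1)

  expect_equal(log2(0 / 1 + 1), 0)  # vst of count 0 at factor 1
  expect_equal(unname(nf$vst[1, 1]), log2(10 + 1))

  m3 <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(normalize_counts(m3), "total-count")
})

test_that("pairwise Wald statistics hit the degenerate and exact cases", {
  counts <- rbind(
    fc2 = c(100L, 100L, 100L, 25L, 25L, 25L, 25L, 25L, 25L),
    null = c(50L, 60L, 55L, 50L, 60L, 55L, 50L, 60L, 55L),
    zero = rep(0L, 9)
  )
  colnames(counts) <- names(tissue_of_9)
  norm <- list(normalized = counts)  # factors are 1 by symmetry of columns
  res <- pairwise_wald(counts, tissue_of_9, "mesentery", "nematosome")
  expect_equal(res$log2fc[res$transcript_id == "fc2"], 2)
  expect_equal(res$log2fc[res$transcript_id == "null"], 0)
  expect_gte(res$p[res$transcript_id == "null"], 0.99)
  expect_equal(res$log2fc[res$transcript_id == "zero"], 0)
  expect_equal(res$p[res$transcript_id == "zero"], 1)

  expect_error(pairwise_wald(counts, tissue_of_9, "mesentery", "gut"), "gut")
})

test_that("log2 fold changes are antisymmetric across the contrast order", {
  set.seed(5)
  counts <- matrix(rnbinom(100 * 9, mu = 50, size = 10), nrow = 100,
                   dimnames = list(sprintf("t%03d", 1:100),
                                   names(tissue_of_9)))
  de <- run_de(counts, tissue_of_9)
  ab <- de$contrasts[["mesentery_vs_tentacle"]]
  ba <- de$contrasts[["tentacle_vs_mesentery"]]
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_true(all(ab$fdr >= ab$p - 1e-12))
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification requires both contrasts and strict thresholds", {
  ids <- c("up_both", "up_one", "at_fdr", "uniq")
  mk <- function(fc, fdr) {
    data.frame(transcript_id = ids, log2fc = fc, se = 1, p = fdr, fdr = fdr,
               stringsAsFactors = FALSE)
  }
  tissue_means <- cbind(
    mesentery = c(0.4, 5, 0.4, 0.4),
    nematosome = c(100, 100, 100, 100),
    tentacle = c(0.1, 30, 0.1, 1.9))
  rownames(tissue_means) <- ids
  de <- list(
    tissues = c("mesentery", "nematosome", "tentacle"),
    tissue_means = tissue_means,
    contrasts = list(
      nematosome_vs_mesentery = mk(c(3, 3, 3, 4), c(0.01, 0.01, 0.05, 0.001)),
      nematosome_vs_tentacle = mk(c(3, 1.5, 3, 4), c(0.01, 0.01, 0.01, 0.001)),
      mesentery_vs_nematosome = mk(-c(3, 3, 3, 4), c(0.01, 0.01, 0.05, 0.001)),
      mesentery_vs_tentacle = mk(c(0, 0, 0, 0), c(1, 1, 1, 1)),
      tentacle_vs_nematosome = mk(-c(3, 1.5, 3, 4), c(0.01, 0.01, 0.01, 0.001)),
      tentacle_vs_mesentery = mk(c(0, 0, 0, 0), c(1, 1, 1, 1))
    ))
  sets <- classify_de_sets(de)
  expect_setequal(sets$nematosome$upregulated, c("up_both", "uniq"))
  # log2fc 3 vs one tissue but 1.5 vs the other: not upregulated
  expect_false("up_one" %in% sets$nematosome$upregulated)
  # fdr exactly 0.05 is excluded (strict <)
  expect_false("at_fdr" %in% sets$nematosome$upregulated)
  # unique requires other-tissue means < 2; up_both has mesentery mean 0.4,
  # tentacle 0.1 -> unique; uniq id has tentacle mean 1.9 -> unique too
  expect_setequal(sets$nematosome$unique, c("up_both", "uniq"))
  expect_true(all(sets$nematosome$unique %in% sets$nematosome$upregulated))
  # no transcript lands in two tissues' upregulated sets
  all_up <- unlist(lapply(sets, `[[`, "upregulated"))
  expect_equal(anyDuplicated(all_up), 0L)
})

test_that("PCA separates planted tissues and reports ordered variance", {
  cfg <- sim_config(seed = 2)
  truth <- generate_truth(cfg)
  cm <- sim_counts(truth, cfg)
  de <- run_de(cm$counts, cm$tissue_of)
  pc <- pca_top(de$vst, n_top = 1000)
  expect_length(pc$top_ids, 1000)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_true(all(pc$var_explained >= 0))
  expect_lte(sum(pc$var_explained), 1 + 1e-8)
  # samples of the same tissue are mutual nearest neighbours in PC1-PC2
  xy <- pc$coords[, 1:2]
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  nn <- rownames(d)[apply(d, 1, which.min)]
  expect_equal(unname(cm$tissue_of[nn]), unname(cm$tissue_of[rownames(d)]))

  # duplicated samples coincide in PC space
  v2 <- de$vst[, c(1:9, 1)]
  colnames(v2)[10] <- "dup"
  pc2 <- pca_top(v2, 100)
  expect_equal(unname(pc2$coords[10, ]), unname(pc2$coords[1, ]),
               tolerance = 1e-8)

  hc <- ward_cluster(de$vst, n_top = 200)
  expect_s3_class(hc, "hclust")
  expect_equal(length(hc$order), 200)
})
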