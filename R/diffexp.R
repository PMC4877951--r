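# Negative-binomial differential expression across three tissues.
#
# Counts are normalized by median-of-ratios size factors, tested per ordered
# tissue pair with a Wald statistic on log2 fold change under a
# method-of-moments NB dispersion estimate, BH-adjusted within each
# contrast, and classified into per-tissue "upregulated" (log2FC >= 2 and
# FDR < 0.05 against BOTH other tissues) and "uniquely expressed"
# (upregulated, and mean count < 2 in each other tissue) sets.
# This is a deliberately transparent re-implementation of the decision
# rules; it does not chase the numerics of shrinkage-based NB GLM fitters.

#' Median-of-ratios normalization with a variance-stabilizing log transform
#'
#' Size factors are the per-sample median, over transcripts with all-positive
#' counts, of the ratio of the count to the transcript's geometric mean
#' across samples; factors are rescaled to geometric mean 1. When no
#' transcript is positive in every sample, total-count ratios are used with
#' a warning. The stabilized matrix is `log2(normalized + 1)`.
#'
#' @param counts integer matrix, transcripts x samples
#' @return list with `size_factors`, `normalized`, `vst`
#' @export
normalize_counts <- function(counts) {
  if (is.null(dim(counts)) || ncol(counts) < 2) {
    abort_fmt("need a counts matrix with at least 2 samples")
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    sub <- counts[pos, , drop = FALSE]
    log_geo <- rowMeans(log(sub))
    ratios <- log(sub) - log_geo
    sf <- exp(apply(ratios, 2, stats::median))
  } else {
    warning("no transcript with positive counts in all samples; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  sf <- sf / exp(mean(log(sf)))
  normalized <- sweep(counts, 2, sf, "/")
  list(size_factors = sf, normalized = normalized,
       vst = log2(normalized + 1))
}

#' Pairwise Wald test between two tissues
#'
#' For each transcript, the log2 fold change is `log2(m_A / m_B)` of the
#' tissue means of normalized counts (a zero mean is replaced by 0.5 for the
#' fold change and standard error only). The NB dispersion is estimated per
#' transcript by method of moments on normalized counts, pooling the
#' within-tissue variances of the two tissues:
#' `alpha = max((s2 - m) / m^2, 1e-8)` with `m` the grand mean. The Wald
#' standard error of the log2 fold change is
#' `(1/ln 2) * sqrt((1/n_A)(1/m_A + alpha) + (1/n_B)(1/m_B + alpha))`
#' and the p-value the two-sided normal tail of `log2fc / se`. Transcripts
#' with all-zero counts in both tissues get `log2fc = 0`, `p = 1`.
#'
#' @param normalized normalized count matrix (from [normalize_counts()])
#' @param tissue_of named character vector sample -> tissue
#' @param tissueA,tissueB tissue labels; fold change is A over B
#' @param dispersion_floor lower bound on the MoM dispersion (1e-8)
#' @return data.frame `transcript_id`, `log2fc`, `se`, `p`,
#'   `mean_A`, `mean_B`
#' @export
pairwise_wald <- function(normalized, tissue_of, tissueA, tissueB,
                          dispersion_floor = 1e-8) {
  for (t in c(tissueA, tissueB)) {
    if (!t %in% tissue_of) abort_fmt("unknown tissue label: %s", t)
  }
  sa <- names(tissue_of)[tissue_of == tissueA]
  sb <- names(tissue_of)[tissue_of == tissueB]
  A <- normalized[, sa, drop = FALSE]
  B <- normalized[, sb, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)

  # pooled within-tissue variance (df-weighted) and grand mean for MoM alpha
  vA <- apply(A, 1, stats::var)
  vB <- apply(B, 1, stats::var)
  s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  m <- rowMeans(cbind(A, B))
  alpha <- pmax((s2 - m) / m^2, dispersion_floor)
  alpha[!is.finite(alpha)] <- dispersion_floor

  mA_fc <- ifelse(mA == 0, 0.5, mA)
  mB_fc <- ifelse(mB == 0, 0.5, mB)
  log2fc <- log2(mA_fc / mB_fc)
  se <- (1 / log(2)) * sqrt((1 / nA) * (1 / mA_fc + alpha) +
                            (1 / nB) * (1 / mB_fc + alpha))
  p <- 2 * stats::pnorm(-abs(log2fc / se))

  allzero <- mA == 0 & mB == 0
  log2fc[allzero] <- 0
  p[allzero] <- 1

  data.frame(transcript_id = rownames(normalized),
             log2fc = log2fc, se = se, p = p,
             mean_A = mA, mean_B = mB,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), applied within
#' one contrast at a time.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`
#' @return adjusted values (FDR)
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort_fmt("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Run all three pairwise contrasts
#'
#' @param counts list from [read_counts()] or an integer matrix plus
#'   `tissue_of`
#' @param tissue_of named character vector sample -> tissue (ignored when
#'   `counts` is a list carrying its own)
#' @return list with `size_factors`, `normalized`, `vst`, `tissues`,
#'   `contrasts` (named list of per-pair data.frames with `fdr` added) and
#'   `tissue_means` (matrix of per-tissue mean normalized counts)
#' @export
run_de <- function(counts, tissue_of = NULL) {
  if (is.list(counts) && !is.null(counts$counts)) {
    tissue_of <- counts$tissue_of
    counts <- counts$counts
  }
  validate_tissues(tissue_of)
  norm <- normalize_counts(counts)
  tissues <- sort(unique(unname(tissue_of)))
  contrasts <- list()
  for (a in tissues) for (b in tissues) {
    if (a == b) next
    res <- pairwise_wald(norm$normalized, tissue_of, a, b)
    res$fdr <- bh_adjust(res$p)
    contrasts[[paste(a, b, sep = "_vs_")]] <- res
  }
  tissue_means <- sapply(tissues, function(t) {
    rowMeans(norm$normalized[, names(tissue_of)[tissue_of == t], drop = FALSE])
  })
  list(size_factors = norm$size_factors, normalized = norm$normalized,
       vst = norm$vst, tissues = tissues, contrasts = contrasts,
       tissue_means = tissue_means)
}

#' Classify per-tissue upregulated and uniquely expressed sets
#'
#' A transcript is upregulated in tissue T when, against BOTH other tissues,
#' its log2 fold change (T over other) is at least `fc_thresh` and its
#' BH-adjusted p-value is strictly below `fdr_thresh`. It is uniquely
#' expressed in T when additionally its mean normalized count is strictly
#' below `unique_mean_thresh` in EACH other tissue.
#'
#' @param de result of [run_de()]
#' @param fc_thresh log2 fold-change threshold (2)
#' @param fdr_thresh FDR threshold, strict (0.05)
#' @param unique_mean_thresh other-tissue mean-count ceiling, strict (2)
#' @return named list per tissue, each with `upregulated` and `unique`
#'   character vectors (`unique` is a subset of `upregulated`)
#' @export
classify_de_sets <- function(de, fc_thresh = 2.0, fdr_thresh = 0.05,
                             unique_mean_thresh = 2.0) {
  tissues <- de$tissues
  ids <- de$contrasts[[1]]$transcript_id
  out <- list()
  for (t in tissues) {
    others <- setdiff(tissues, t)
    up <- rep(TRUE, length(ids))
    low_elsewhere <- rep(TRUE, length(ids))
    for (u in others) {
      res <- de$contrasts[[paste(t, u, sep = "_vs_")]]
      up <- up & res$log2fc >= fc_thresh & res$fdr < fdr_thresh
      low_elsewhere <- low_elsewhere & de$tissue_means[, u] < unique_mean_thresh
    }
    out[[t]] <- list(upregulated = ids[up],
                     unique = ids[up & low_elsewhere])
  }
  out
}

#' PCA of samples over the top expressed transcripts
#'
#' Selects the `n_top` transcripts by mean stabilized expression across
#' samples and runs a centered PCA of the samples.
#'
#' @param vst stabilized matrix from [normalize_counts()]
#' @param n_top number of transcripts to keep (1000)
#' @return list with `coords` (samples x PCs), `var_explained` (fractions,
#'   non-increasing) and `top_ids`
#' @export
pca_top <- function(vst, n_top = 1000) {
  if (ncol(vst) < 2) abort_fmt("PCA needs at least 2 samples")
  n_top <- min(n_top, nrow(vst))
  ord <- order(rowMeans(vst), decreasing = TRUE)
  top <- vst[ord[seq_len(n_top)], , drop = FALSE]
  pc <- stats::prcomp(t(top), center = TRUE, scale. = FALSE)
  list(coords = pc$x,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       top_ids = rownames(top))
}

#' Ward clustering of the top expressed transcripts
#'
#' Ward's (D) linkage on Euclidean distances between transcripts' stabilized
#' expression profiles. `hclust` is deterministic; equal-height merges are
#' resolved by lowest row index first.
#'
#' @inheritParams pca_top
#' @return an `hclust` object over the top `n_top` transcripts
#' @export
ward_cluster <- function(vst, n_top = 1000) {
  n_top <- min(n_top, nrow(vst))
  ord <- order(rowMeans(vst), decreasing = TRUE)
  top <- vst[ord[seq_len(n_top)], , drop = FALSE]
  stats::hclust(stats::dist(top), method = "ward.D")
}
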