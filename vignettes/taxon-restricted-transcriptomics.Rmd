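---
title: "Methods: taxon-restricted gene expression analysis across tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon-restricted gene expression analysis across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataseq)
```

# The question and the inference chain

De novo transcriptome assemblies of non-model animals mix three things:
genuine transcripts of the target species, assembly noise, and foreign
sequence (food, symbionts, microbial contamination). Once cleaned, such an
assembly can be interrogated for *taxonomically restricted genes* — genes
with detectable orthologs only within a narrow lineage — and for whether
those young genes are preferentially expressed in lineage-specific tissues.
`strataseq` implements that chain for a three-tissue design: contamination
screening, phylostratum assignment, differential expression, enrichment
reporting, stress-gene annotation, and assembly summary statistics, plus a
seeded simulator that plants ground truth for every stage.

# Contamination screening

## Model

For each transcript we contrast its best protein-level homology E-value
among metazoan database subjects, $E_m$, with its best among non-metazoan
subjects (other eukaryotes, archaea, bacteria), $E_{nm}$:

$$\mathrm{AI} = \ln(E_m + \varepsilon) - \ln(E_{nm} + \varepsilon), \qquad
\varepsilon = 10^{-200}.$$

$\mathrm{AI} > 0$ means the foreign hit is strictly better, and the
transcript is flagged. The alien index is a log contrast rather than a raw
ratio because the flagging threshold "greater than zero" is only meaningful
on a log scale; $\varepsilon$ guards against zero E-values, and a side with
no hit at all defaults to $E = 1$, so a transcript with only metazoan hits
has $\mathrm{AI} \approx \ln E_m < 0$ and is never flagged. Both constants
are arguments of `compute_alien_index()`.

Flagging is deliberately not removal: a genuinely native gene can be
flagged because the relevant metazoan proteomes are sparsely represented.
A flagged transcript is therefore *rescued* when it aligns to the species'
own genome with identity strictly above 70 % over at least 200 bp
(`apply_screen()`, both thresholds configurable). The alignment-length
bound is taken inclusively (`>= 200`). Removed = flagged and not rescued.

Cnidarian and other within-metazoan database classes count on the metazoan
side of the index; the partition is configured entirely through the taxon
map (prefix → lineage class), never hard-coded to a taxon roster.

# Phylostratum assignment

Strata are ordered from most restricted to most conserved:

NEMATOSTELLA < EDWARDSIIDAE < ANTHOZOA < CNIDARIA < METAZOA.

An ortholog cluster's stratum is decided by the broadest lineage class
among its members (`classify_group()`): any metazoan-outgroup member makes
it METAZOA; otherwise any non-anthozoan cnidarian makes it CNIDARIA, then
any anthozoan, then any Edwardsiidae member; a cluster containing only the
species' own sequences is NEMATOSTELLA. Precedence by the broadest class is
the only reading consistent with transcript-level aggregation: a transcript
whose alternative ORFs cluster at different depths takes the *maximum*
(most conserved) ORF stratum, so one conserved ORF is enough to call the
transcript conserved (`assign_transcript_strata()`).

Two conventions were genuinely open and are exposed as arguments:

* **Unclustered singleton ORFs** are classified NEMATOSTELLA. A protein
  with no detectable ortholog anywhere is lineage-restricted by
  definition; `singleton_stratum = NA` drops them instead, for users who
  prefer to treat singletons as unclassifiable.
* **Percentages** in every census are integer round-half-up
  (`round_half_up()`), matching how such tables are conventionally
  printed; base `round()`'s banker's rounding would disagree on exact
  halves.

Only ORFs of at least 100 amino acids participate (shorter ORF predictions
are mostly spurious); transcripts with no qualifying ORF receive no stratum
and are excluded from the enrichment panels.

# Differential expression

## Normalization

Median-of-ratios size factors: for each sample, the median over
all-positive transcripts of the count divided by the transcript's geometric
mean across samples, rescaled to geometric mean 1 (`normalize_counts()`).
When no transcript is positive everywhere the factors fall back to
total-count ratios with a warning. The variance-stabilized matrix used for
PCA and clustering is `log2(normalized + 1)`.

## Test

Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$. Per transcript and ordered tissue pair $(A, B)$ with
$n_A, n_B$ replicates and normalized tissue means $m_A, m_B$:

* dispersion by method of moments on the pooled within-tissue variance
  $s^2$ (degree-of-freedom weighted across the two tissues) and grand mean
  $\bar m$: $\alpha = \max\!\big((s^2 - \bar m)/\bar m^2,\ 10^{-8}\big)$;
* $\log_2\!\mathrm{FC} = \log_2(m_A/m_B)$, with a zero mean replaced by
  0.5 *for the fold change and its standard error only*, so uniquely
  expressed transcripts get a finite fold change while the
  unique-expression mean test below keeps its exact semantics;
* Wald standard error
  $\mathrm{se} = \frac{1}{\ln 2}\sqrt{\tfrac{1}{n_A}(1/m_A + \alpha) +
  \tfrac{1}{n_B}(1/m_B + \alpha)}$ (delta method on the log mean ratio);
* two-sided normal p-value of $\log_2\!\mathrm{FC}/\mathrm{se}$;
  all-zero transcripts get $p = 1$ and fold change 0.

Benjamini–Hochberg adjustment is applied within each pairwise contrast
(three contrasts), not pooled — the per-results-table convention of NB
differential-expression tools. This estimator is intentionally transparent:
no dispersion shrinkage, no fold-change moderation, no outlier replacement.
The contract is the decision thresholds and the recovery properties below,
not numerical equivalence with any particular GLM fitter.

## Compound classification

Upregulated in tissue $T$: $\log_2\!\mathrm{FC} \ge 2$ **and**
$\mathrm{FDR} < 0.05$ against *both* other tissues (both thresholds strict
where stated: an FDR of exactly 0.05 is excluded). Uniquely expressed in
$T$: upregulated, and mean normalized count strictly below 2 in *each*
other tissue. The mean-count test uses normalized counts by default (the
criterion is a biological "not expressed", which should not depend on
library depth); `classify_de_sets(..., unique_mean_thresh =)` and the raw
scale are a one-line change for users who prefer raw means. Requiring
superiority over both other tissues makes the per-tissue upregulated sets
disjoint by construction.

`pca_top()` and `ward_cluster()` summarize sample structure over the top
1000 transcripts by mean stabilized expression (centered PCA of samples;
Ward's-D linkage on Euclidean distances; `hclust` merges are deterministic
with ties resolved by lowest index).

# Enrichment reporting

`crosstab_proportions()` counts each expression class (the full assigned
set, plus per-tissue upregulated and unique sets) by stratum, with integer
percentages per column and a *cnidarian sensu lato* aggregate — all strata
except METAZOA, i.e. everything restricted to cnidarians or narrower,
including the species-specific stratum. `single_tissue_fraction()` reports,
for NEMATOSTELLA, the cnidarian-sensu-lato aggregate, and METAZOA, the
fraction of upregulated transcripts (summed over tissues) that are uniquely
expressed. These groups deliberately overlap (the aggregate contains the
species-specific stratum); column decompositions are also reported
stratum-by-stratum so either reading is recoverable.

# Stress annotation

`reciprocal_best_hits()` uses bit scores, not E-values, as the best-hit
criterion: bit scores are comparable across alignments of different
lengths. The default tie tolerance is 0 — only *exactly* equal bit scores
tie — and a transcript whose tied best hits reciprocate to genes of two
different categories is annotated with both, so category counts may sum to
more than the number of annotated transcripts. `stress_census()` reports
the annotated fraction of an upregulated set and the per-category
composition.

# Assembly metrics

N50 is the largest length $L$ such that sequences of length $\ge L$ hold at
least half the total bases (descending cumulative sum; invariant to input
order and to duplicating the whole set). GC content is reported both pooled
over all non-N bases (length-weighted) and as the unweighted mean of
per-sequence GC, since either convention appears in assembly reports. The
"no expression" census counts ORF-bearing transcripts with total raw count
below 2 summed across all samples; an alternative mode counts transcripts
below the floor within at least one tissue, because both readings exist for
this statistic and they disagree (`no_expression_mode`).

# The synthetic study

`sim_config()` defaults define the simulated study conditions used across
the tests and analysis drivers:

| parameter | default | meaning |
|---|---|---|
| `n_per_stratum` | 322/41/290/144/1203 | 2000 transcripts in the observed census proportions (16/2/14/7/60 %) |
| `n_contaminants` | 50, `rescue_fraction` 0.5 | planted foreign transcripts; half get a qualifying genome alignment |
| `n_replicates` | 3 | three tissues, sample names M3/M4/Mes, N1/N2/Nem, T3/T4/Ten |
| `baseline_log_mean`, `baseline_log_sd` | log 100, 1 | log-normal prior on NB means |
| `dispersion` | 0.1 | NB variance $\mu + 0.1\mu^2$ |
| `de_fraction_per_tissue` | 0.1 | 200 planted upregulated per tissue, disjoint across tissues |
| `de_log2fc` | 3 | planted effect size |
| `de_min_baseline_mean` | 50 | floor on planted-DE baseline means, so the planted effect is identifiable at n = 3 |
| `unique_fraction` | 0.2 | 40 per tissue forced to literal zero counts elsewhere |
| `stress_fraction` | 0.22 | planted reciprocal-best-hit partners among each tissue's DE set |
| `stress_category_weights` | 741 : 1984 : 187 | wound : pathogen : chemical, the published database's composition |

Design choices that make the simulator a reliable oracle:

* **Exact class sizes by assignment**, never Bernoulli sampling, so
  recovery tests have fixed denominators.
* **Disjoint E-value exponent ranges** for the better and worse homology
  side ($10^{-U}$ with $U \in (30, 80)$ vs $U \in (1, 10)$), so the alien
  index sign — and hence the flagged set — is guaranteed, not
  probabilistic.
* **Literal zeros** outside the home tissue for unique transcripts: the
  strongest form of the "mean < 2" criterion, giving unambiguous truth.
* **Groups files constructed to pin exactly the planted stratum** (a
  partner member of the stratum's witness class, never a broader one), so
  stratum recovery is exact by construction.
* A randomized assignment pool decorrelates DE/unique/stress status from
  the stratum blocks.
* All emitted files are byte-identical for identical config + seed; the
  truth table stream is seeded with `seed` and the file-emission stream
  with `seed + 1`.

What the simulator does **not** emulate: read-level noise and assembly
error (sequences are random, not assembled), isoform redundancy, varying
library sizes (size factors are ≈ 1 by construction), correlated genes,
GC- or length-dependent coverage bias, and partially overlapping ortholog
clusters. Passing recovery tests therefore demonstrates that the decision
rules and bookkeeping are implemented correctly under the stated model —
not that the statistical power observed here transfers to real libraries,
where dispersion varies per gene and normalization is load-bearing.

Problem sizes used in the checked properties: recovery runs use the default
2000-transcript configuration over seeds 1–5 (sensitivity and observed
false-discovery proportion of the planted log2FC-3 effects, and a null
configuration with no planted effects); oracle-equivalence checks use 100
random small group instances, length sets up to 1000 sequences for N50, and
a ~200 × 200 hit table for reciprocal best hits. These sizes were chosen as
the smallest at which the stochastic properties are stable.

# Degenerate inputs and numerical conventions

* Empty hit lists → alien index 0, not flagged (both sides at the default
  E = 1).
* Empty expression-class columns → zero counts with percentages flagged
  `NA` rather than 0.
* A stratum group with no upregulated members → undefined (NA) fraction.
* p-values outside [0, 1], negative or non-integer counts, unmapped taxon
  prefixes, duplicate ids, and sub-threshold ORFs are errors at parse or
  call time — parsers never skip records silently.
* Dispersion floor $10^{-8}$ avoids a degenerate Wald statistic when the
  within-tissue variance is at or below the mean.

# Known limitations

* The Wald test with moment dispersion is anti-conservative at very low
  means relative to shrinkage-based fitters; the thresholds (fold change
  ≥ 2, FDR < 0.05) dominate behaviour in the regimes tested.
* Stratum assignment trusts the ortholog clustering; mis-clustered
  proteins propagate directly.
* The single-tissue-restriction groups overlap by design; they should be
  read as contrasts, not as a partition.
* The pipeline assumes exactly three tissues with at least two replicates
  each; other designs require generalizing the compound classification.
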