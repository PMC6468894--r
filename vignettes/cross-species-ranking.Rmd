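---
title: "Cross-species rank comparison of SHH medulloblastoma transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species rank comparison of SHH medulloblastoma transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmb)
library(dplyr)
```

## The problem

Sonic hedgehog (SHH) subtype medulloblastoma is modeled in mice by
hedgehog-pathway mutants (*Ptch1*^+/−^, SmoM2, Gnas-knockout models), but a
gene that marks the mouse tumor need not mark the human one. Asking "which
genes are up in SHH tumors in one species but not the other?" across many
public expression datasets faces three obstacles: datasets come from
different microarray platforms with incomparable intensity scales; human
cohorts contain no healthy cerebellum, only tumors of other molecular
subgroups (WNT, Group 3, Group 4), whereas mouse panels contrast tumors with
normal cerebellum; and probe-level measurements must be reduced to one value
per gene before species can be compared at all.

`crossmb` addresses all three with a deliberately scale-free design: within
each dataset genes are reduced to *quantile ranks* of their SHH-group
overexpression, so that only orderings — which survive platform and
normalization differences — cross dataset boundaries.

## The procedure

For each dataset:

1. **(Optional) between-array normalization.** Arrays are mapped onto a
   common scale with a rank-invariant-set method
   (`invariant_set_normalize()`), needed only when a deposited matrix shows
   array-level distortions.
2. **Group medians.** For every probeset, the median log2 expression per
   tumor/tissue group (`group_medians()`). Medians, not means, so single
   outlier arrays cannot move the summary.
3. **Max-mean collapse.** Each gene is represented by the probeset with the
   highest mean across the group columns (`collapse_to_genes_max_mean()`);
   the highest-expressed probeset is typically the best-hybridizing one.
   Note the collapse operates on the group-median table, not the
   sample-level matrix; a separate helper (`select_max_mean_probe()`) picks
   the max-mean probeset at sample level for single-gene plots.
4. **Overexpression values.** Each row has its across-group mean subtracted
   (`center_rows()`): a positive value means "higher in this group than in
   the other groups of the same dataset". Human datasets thereby contrast
   SHH against other subgroups, mouse datasets against cerebellum — no
   special-casing, the contrast is whatever columns the dataset has.
5. **Quantile ranks.** Genes are ordered ascending by their SHH-group
   overexpression and rank *r* (1-based, average ranks for ties) maps to
   *(r − 1)/(n − 1)* (`quantile_rank()`), so ranks span exactly [0, 1].

Ranks are then averaged per species over homologous gene pairs
(`average_ranks_by_species()`), and the per-gene difference

> diff = mean human SHH rank − mean mouse Shh rank

(`rank_difference()`) orders genes from most human-specific (diff near +1)
to most mouse-specific (near −1). A label column operationalizes "high in
one species, low in the other" with cutoffs ≥ 0.8 / ≤ 0.2 (configurable; the
defaults are our reading of "closer to 1 / closer to 0").

The diff ordering feeds a from-scratch preranked gene set enrichment
analysis (`run_gsea()`): the weighted Kolmogorov–Smirnov-style running sum
(`enrichment_score()`), a null of uniformly random same-size gene sets
(`permutation_null()` — the standard preranked null, since no phenotype
labels exist at this stage), same-sign normalization to NES, and a
max-NES-per-permutation family-wise error rate (`normalize_and_fwer()`).

Two companion analyses probe the structure of the comparison:
`dataset_correlogram()` (pairwise Pearson correlation of SHH overexpression
values between datasets — high within a species, lower between) and
`rank_concordance()` (OLS of the species mean ranks on an external
Gli1-coexpression ranking, asking whether hedgehog-pathway wiring itself is
conserved).

### The cerebellum-normalized variant

Because human cohorts use other tumor subgroups as the contrast, the
pipeline has a robustness mode (`cerebellum_normalize()`, pipeline `mode =
"cerebellum_normalized"`): group medians minus the healthy-cerebellum
median, making the control column identically zero. Datasets without a
cerebellum group fall back to row-centering. The same ranking machinery runs
downstream unchanged.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `log_threshold` | 50 | linear intensity | log2 microarray values rarely exceed ~16; linear intensities always do, so a matrix maximum above 50 flags unlogged data (and the `log2(x+1)` transform can never trigger twice) |
| `prop_threshold` | 0.05 | fraction of features | proportion rank difference below which a feature counts as rank-invariant |
| `window` | 51 | invariant points | running-median width of the normalization smooth |
| quantile-rank formula | (r−1)/(n−1) | — | spans exactly [0,1]; average ranks for ties |
| specificity cutoffs | 0.8 / 0.2 | rank | the "closer to 1 / closer to 0" operationalization |
| GSEA `weight` | 1 | exponent on \|score\| | the cited tool's default weighting |
| GSEA `min_size`/`max_size` | 15 / 500 | genes in list | standard preranked size filter |
| `n_perm` | 1000 | permutations | FWER resolution of 0.001 |

## Numerical choices

* **Ties** in the ranked list before GSEA are broken by gene symbol sort;
  max-mean ties by lexicographically smallest probeset id — determinism
  across platforms.
* **ES sign ties** (|max deviation| equal in both directions) resolve to the
  positive extreme, with a 1e−12 tolerance absorbing floating-point
  accumulation differences.
* The invariant-set smooth uses `runmed(..., endrule = "keep")`: the raw
  invariant pairs anchor the mapping at the window ends, so a clean additive
  or multiplicative distortion is recovered essentially exactly over the
  whole range; Tukey-style end smoothing would bend monotone endpoints.
  Values outside the invariant range map through the nearest smooth point.
* The FWER fraction is computed among permutations contributing at least one
  same-sign family NES — indistinguishable from the all-permutations
  convention for any realistic family, and for a family of one set it makes
  the FWER p equal the nominal p on the NES scale.
* Mouse symbols are matched case-insensitively; the default homolog map is
  the case-convention pairing (Gpr153 ↔ GPR153) restricted to symbols
  present in both species' data, with ambiguous many-to-many entries
  dropped.
* Genes present in only some datasets of a species keep a partial average,
  with the dataset count recorded (`n_datasets`); requiring presence
  everywhere would discard platform-specific genes asymmetrically.
* Missing values: rows are dropped (and counted), never imputed — ranking is
  over complete rows only.

## What the synthetic generator emulates

`generate_suite()` produces the structure the analysis assumes: several
mouse datasets (groups Shh + cerebellum) and several human datasets (SHH +
Group3 + Group4), log2-scale values built as gene baseline
(~Normal(7, 1.5)) + per-array batch shift (~Normal(0, 0.3)) + group effect +
noise (~Normal(0, 0.8)), with 1–3 probesets per gene sharing the gene value
plus a probe offset, title-case mouse / uppercase human symbols, and three
planted memberships: *shared hedgehog targets* (+1.5 log2 in the SHH group
of both species), *human-specific* and *mouse-specific* sets (each
species-restricted). A Gli1-coexpression ranking with the shared targets at
the top (jittered) accompanies the suite, plus a ground-truth table for
recovery tests.

Defaults are 2000 genes, 3 datasets per species, 50-gene planted sets,
human cohorts of 20 samples per subgroup and mouse panels of 10 per group —
magnitudes typical of the published panels this emulates (human SHH cohorts
run tens of samples; mouse panels around ten). An additive log2-normal model
is used throughout because the analysis operates entirely on log2 microarray
values; no count model is needed. The probes-per-gene draw comes from a
fixed internal stream, so changing the seed changes values but never matrix
shapes.

The generator deliberately omits several features of real data:
platform-specific probe affinity biases, missing-at-random values,
correlated gene modules beyond the planted sets, sample contamination and
subgroup misclassification, and any count-based (RNA-seq) noise structure.
Tests passing on this suite therefore demonstrate that the *procedure*
recovers planted cross-species structure under realistic noise — not that
any particular biological claim holds in real cohorts.

Validation problem sizes were chosen to keep the whole suite fast while
leaving clear statistical margin: 2000 genes × 6 datasets for recovery
properties, 200 random sets × 500 permutations for null calibration, 1000
permutations for FWER recovery. The recovery invariant is additionally
exercised at a harsher 4-samples-per-group condition in the unit tests.

## Worked example

```{r example, eval = FALSE}
suite <- generate_suite(synthetic_config(seed = 1))

over  <- lapply(suite$datasets, function(d)
  center_rows(collapse_to_genes_max_mean(group_medians(d),
                                         d$probe_annotation)))
ranks <- lapply(over, quantile_rank, target_group = "SHH")
rd <- rank_difference(
  average_ranks_by_species(ranks, "human", suite$homolog_map),
  average_ranks_by_species(ranks, "mouse", suite$homolog_map))

gmt  <- generate_gmt_with_planted_sets(suite$truth, seed = 1)
gsea <- run_gsea(ranked_list(rd), gmt, n_perm = 1000, seed = 1)
head(gsea)

glance(dataset_correlogram(over, suite$homolog_map, "SHH"))
glance(rank_concordance(suite$coexpression,
                        average_ranks_by_species(ranks, "mouse",
                                                 suite$homolog_map)))
```

Or end-to-end on disk, with a manifest and deterministic TSV outputs:

```{r pipeline, eval = FALSE}
suite <- simulate_command(synthetic_config(seed = 1), out_dir = "sim")
run_pipeline(list(datasets = unname(suite$paths), seed = 1,
                  gmt = "sim/gene_sets.gmt",
                  coexpression = "sim/coexpression_ranks.tsv"),
             out_dir = "results")
```

## Known limitations

* Rank averaging is unweighted: a 20-sample dataset counts as much as a
  200-sample one. This is the simplest reading of "averaged" and keeps any
  single large cohort from dominating, but discards precision differences.
* The correlogram is computed on overexpression *values* by default
  (`on_ranks = TRUE` switches to ranks); values are more sensitive to
  residual scale differences between platforms.
* The preranked permutation null ignores gene–gene correlation, as all
  random-gene-set nulls do; FWER p-values on strongly co-expressed
  collections are anti-conservative in the same way the standard tool's are.
* With concentrated score distributions (a few genes carrying most of the
  signal), weight-1 enrichment lets random sets containing a handful of
  extreme genes score highly; this is inherent to the weighting, not a bug,
  and the weight-0 (classic KS) mode is available.
* The homolog map is symbol-based; genes whose orthology is not a symbol
  pair (different roots, one-to-many families) are dropped rather than
  resolved through a curated orthology resource.
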