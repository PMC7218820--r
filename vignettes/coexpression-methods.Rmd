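---
title: "Methods: provirus co-expression screening with preranked GSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: provirus co-expression screening with preranked GSEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervcoex)
```

## The analysis model

`hervcoex` asks whether the expression of one designated feature — in the
motivating application an endogenous retroviral provirus quantified as one
row of a bulk RNA-seq count matrix — is co-expressed with coherent
biological programs, and whether that co-expression differs between two
sample groups. The design is deliberately simple: no latent-factor model,
no network inference, just a correlation screen feeding a rank-based
enrichment test, each step auditable on its own.

The statistical chain is:

1. counts are made comparable across libraries by **median-of-ratios size
   factors**;
2. the gene universe is reduced to quantifiable, annotated genes by two
   **prefilters**;
3. within each group, every gene is scored by **Pearson correlation** with
   the target, with exact t-based significance;
4. the signed correlations rank the genes for **preranked GSEA** with a
   gene-permutation null;
5. a designated category of terms is tested for **over-representation**
   among the top-k enriched terms with an exact hypergeometric tail.

### Assumptions

The Pearson t test assumes approximate normality of the expression values
within each group; the package exposes `qq_normal_points()` (and
`plot(res, type = "qq")`) as a diagnostic, but normality is never a gate —
the pipeline runs regardless and leaves the judgement to the analyst. The
GSEA permutation null assumes exchangeability of gene labels given the
ranking, which is the only null available at realistic permutation counts
when each group has seven samples (7! = 5,040 phenotype permutations could
never support the default 100,000 draws).

## Normalization

For sample $j$, with $k_{ij}$ the raw count of gene $i$,

$$ s_j = \operatorname{median}_{i \in R}
   \frac{k_{ij}}{\left(\prod_{v=1}^m k_{iv}\right)^{1/m}}, $$

where the reference set $R$ contains the genes with a strictly positive
count in every sample (a single zero makes the geometric mean zero and its
log undefined, so such genes are excluded). The median of an even-length
vector is the midpoint of the two central order statistics
(`stats::median`), and the factors are *not* rescaled to unit geometric
mean — both conventions are stated so that tests are unambiguous.
Normalized expression is $k_{ij}/s_j$. The implementation is checked in
the test suite against an independent reference implementation of the same
estimator and against hand-computed examples. Rescaling one library
rescales the relative factors accordingly; because the factors are not
re-centred, the normalized matrix is invariant to such rescaling only up
to one global constant, which is immaterial to correlations and ranks
downstream.

## Prefilters

Genes with mean normalized count (all samples pooled) below 50 are
removed; the boundary is inclusive, so the post-filter minimum mean equals
the threshold exactly. Genes that belong to no annotation set are removed
next. Both groups share the one resulting gene universe: the screen is
run per group, but the denominator ("out of N total genes") is common.
The target feature is keep-listed through both filters, because a lowly
expressed target would otherwise delete its own analysis. The filter
report records the gene count after each stage separately (the two
reductions are often conflated in summary tables) plus the five
mean-expression quantiles before and after, computed with the
linear-interpolation quantile definition (R type 7; the convention is
stated because published quantile tables rarely say which was used).

## The correlation screen

Within a group with $n$ samples, each non-target gene gets the sample
Pearson coefficient $r$ against the target, $t = r\sqrt{n-2}/\sqrt{1-r^2}$
and the two-sided p from $t_{n-2}$. Zero-variance genes have an undefined
correlation: they are kept in the table flagged `NA` but can never occupy
a rank or be selected as "strong". Screen p-values are deliberately not
multiplicity-adjusted — adjustment happens once, inside GSEA, across the
tested sets.

"Strong" correlators are genes with $|r| \ge 0.7$ by default. The
absolute-value reading (both signs count) is the default because both
co-activation and suppression are biologically informative at this stage;
a signed mode is available (`strong_gene_sets(..., mode = "signed")`) for
analyses that care only about positive co-expression.

## Preranked GSEA

Genes are ranked by signed $r$, descending, ties broken lexicographically
by gene identifier so that reruns are bit-identical. For a set $S$ with
$N_{hits}$ members present in the ranked list of length $N$, the running
sum increments by $|r_i|^w / N_R$ at members ($N_R = \sum_{S} |r_i|^w$,
weight exponent $w = 1$ by default) and decrements by $1/(N - N_{hits})$
at non-members. The enrichment score is the running-sum value of maximal
absolute deviation from zero; an exact tie between a positive peak and a
negative trough resolves to the positive one. The leading edge is the
member prefix up to the peak (suffix from the trough, for negative
scores), and the gene ratio is its size over the restricted set size.

Set-size bounds (default 25–500) are applied *after* restricting each set
to the analyzed universe, so "set size" always refers to genes that could
actually have contributed.

**Null and p-values.** The null draws uniform random same-size gene
subsets; since it depends only on the set size, draws are shared across
sets of equal restricted size (which also guarantees identical sets get
identical p-values under one seed). The one-sided p is add-one smoothed,
$p = (1 + \#\{ES^{null} \ge ES\})/(1 + n_{perm})$ for $ES \ge 0$ and
mirrored otherwise, so p is never zero and the attainable floor is
$1/(n_{perm}+1)$. The NES divides the observed score by the mean
|null score| of the same sign; when the null produced no draw of that
sign the NES is flagged undefined rather than silently zeroed. Both ES
and NES are reported, since "enrichment" columns in published tables are
frequently ambiguous between the two.

**FDR.** Benjamini–Hochberg adjustment is applied across all tested sets
(delegated to `stats::p.adjust`). q-values use the fixed-λ Storey
estimator at λ = 0.5: $\hat\pi_0 = \#\{p > 0.5\}/(0.5\,m)$ clamped to
$[1/m, 1]$, and $q_i = \hat\pi_0 \cdot BH_i$. The lower clamp keeps a
degenerate all-significant input from zeroing every q-value; the original
smoother-based $\hat\pi_0$ estimator is out of scope, and the fixed-λ
variant is documented precisely so its q-values are reproducible by hand.

## The category meta-test

Whether a category (say, the 17 terms of a vocabulary of 29,698 that
describe neutrophil function) is over-represented among the top $k = 20$
enriched terms is an exact hypergeometric question. Both tail conventions
are first-class: `p_inclusive` $= P(X \ge x)$ is the statistically
standard report, while `p_strict` $= P(X > x)$ is what upper-tail software
defaults commonly produce, and the two differ by exactly the point mass
$P(X = x)$. The universe size is a required explicit argument: using the
full term vocabulary versus only the tested sets changes the p-value by
orders of magnitude, so the choice must be visible in the call, never a
hidden default.

## The synthetic-study generator

`generate_study()` emulates the motivating study design: two groups of 7
samples, a target feature whose group mean differs by a configurable fold
(default 1.3), ~2,000 background genes with log-uniform baselines
(default range log 30 – log 3000 counts), negative-binomial noise
(default dispersion 0.1), and `n_sets` gene sets (default 15, sizes
25–60) of which `n_planted_sets` (default 2) carry planted co-expression.

Co-expression is planted through a shared latent variable: within the
planted group, each planted gene's log-mean is
$\log\mu_g + \beta \, z(\text{sample})$, where $z$ is the *standardized
realized target count* of that sample. Coupling to the realized (noisy)
target rather than to a hidden Gaussian means the screen correlates the
genes against exactly the variable they were planted on, which is what
makes strong recovery attainable at $n = 7$: at $\beta = 2$ with small
dispersion (0.05), essentially all planted genes exceed $|r| = 0.7$. In
the other group, and for all non-planted genes, expression is independent
of the target.

Two generator choices deliberately depart from a cosmetic reading of the
motivating study. First, the target's absolute level defaults to a mean
of 100 counts rather than the sub-1 TPM medians published for the
provirus: on an integer count scale a sub-1 median collapses to 0/1
counts and a degenerate screen, so the fold ratio (1.3) is the calibrated
property and the location is chosen for quantifiability. Second, planted
sets are disjoint in membership, so per-set recovery can be scored
without attribution ambiguity. What the generator does *not* emulate:
transcriptome-wide correlation structure, batch effects, library-size
confounding, compositional effects. Passing recovery tests therefore
demonstrates the pipeline's statistical machinery, not robustness to
those real-data phenomena.

Randomness is consumed in three fixed phases seeded as `seed`, `seed+1`,
`seed+2` (design, target counts, gene counts), so identical
configurations are byte-identical and single phases can be regenerated.

## Numerical and design choices

- Ranking ties: lexicographic by gene id, for bit-reproducibility.
- ES ties between a positive peak and equal-magnitude trough: positive wins.
- All-zero member scores ($N_R = 0$): increments fall back to uniform
  $1/N_{hits}$ instead of dividing by zero.
- Zero-variance genes: excluded from ranking, never assigned $r = 0$.
- Correlation of exactly $\pm 1$: p reported as 0 (the t transform
  diverges).
- Pipeline stage failures raise classed conditions
  (`hervcoex_config_error`, `hervcoex_data_error`) which the command-line
  wrapper maps to exit codes 2/3/4; partial outputs are kept with the
  manifest marked incomplete.

## Problem sizes used in validation

The calibration and recovery test blocks run 20 replicate studies each at
the generator defaults (2,000 genes, 15 sets, 7 + 7 samples) with 10,000
permutations — about two to three minutes per block on one core. The
null-calibration block checks that ~5% of sets reach raw $p < 0.05$ and
that planted (but unexpressed, $\beta = 0$) sets are almost never called
at FDR 0.05; the recovery block checks that at $\beta = 2$ planted genes
pass the $|r| \ge 0.7$ screen at $\ge 80\%$ and planted sets head the
GSEA table. Exhaustive-enumeration oracles (all $\binom{5}{2}$ or
$\binom{8}{3}$ placements) pin the permutation machinery exactly on small
lists.

## Known limitations

- With 7 samples per group, individual correlations are noisy; the
  pipeline's value is in the set-level aggregation, and single-gene
  "strong" calls should be read with that in mind.
- The gene-permutation null ignores inter-gene correlation, which can
  make set-level p-values anti-conservative on real data.
- The fixed-λ q-value estimator is coarser than the smoother-based
  original; q-values equal BH-adjusted values whenever
  $\hat\pi_0$ hits its cap.
- Normalization assumes most genes are not associated with the target;
  extremely pervasive planted signal (a large fraction of all genes)
  perturbs the size factors and attenuates correlations on the
  normalized scale.
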