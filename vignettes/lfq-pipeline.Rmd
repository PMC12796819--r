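---
title: "Methods: LFQ differential analysis and gene-set mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LFQ differential analysis and gene-set mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: what is
modelled, which parameters matter, which choices were genuinely open and how
they were resolved, and what the synthetic-data tests do and do not
demonstrate about real data.

## The data and its missingness

MaxQuant's `proteinGroups.txt` reports one LFQ intensity per protein group
per sample; a value of 0 means "not quantified", not "abundance zero". The
package stores 0 as missing throughout — the convention of the Perseus and
DEP ecosystems — because treating dropout as a measured zero would wreck
both the log transform and the variance estimates.

LFQ dropout is predominantly missing-not-at-random (MNAR): proteins near
the detection limit drop out preferentially. Two consequences shape the
pipeline:

1. **Detection filter.** A protein is kept when at least one condition
   has it detected in all replicates; the integer threshold `t` relaxes
   this by `t` detections (keep iff ∃ condition *c* with detections ≥
   *n_c* − *t*). The threshold must stay below the smallest replicate
   count: at `t = min(n_c)` the rule would degenerate to "detected
   anywhere", which is rejected as meaningless rather than silently
   accepted.
2. **Left-censored imputation.** Each missing entry in sample *s* is drawn
   from N(μ_s, σ) with μ_s the `downshift_quantile` (default 0.01) quantile
   of the sample's observed log2 values and σ = `width` (default 0.3) × the
   median per-protein observed SD. This is the "MinProb-like" family used
   for MNAR dropout: imputed values land in the sample's low tail rather
   than at its centre, so imputation cannot manufacture spurious positive
   fold changes for proteins missing in only one group. A sample with
   fewer than two observed values has no estimable censoring distribution
   and is a fatal error. MAR imputation (kNN, MLE) is deliberately out of
   scope.

Median alignment of samples is available (`normalize_median()`) but **off
by default**: the pipeline makes no claim about which normalization the
data need, and variance-stabilizing normalization was considered and not
implemented — it changes the scale on which fold changes are read, and LFQ
intensities from a single MaxQuant run are already co-normalized by the
LFQ algorithm itself. Consequently, counts of differentially expressed
proteins from this package need not match tools that normalize by default;
exact reproduction of any particular deployed pipeline's DEP count is not
guaranteed, since imputation method and normalization choices there are
generally unstated.

## Moderated differential testing

Every unordered pair of conditions is tested per protein. For one contrast
with group sizes n₁, n₂, the pooled residual variance s² has d = n₁+n₂−2
degrees of freedom. Across proteins, true variances are modelled as scaled
inverse-chi-squared with prior degrees of freedom d₀ and prior variance
s₀², giving the posterior (shrunken) variance

s̃² = (d₀ s₀² + d s²) / (d₀ + d)

and t = Δmean / (s̃ √(1/n₁ + 1/n₂)) on d + d₀ degrees of freedom. The
hyperparameters are estimated by method of moments on e = log s², using

E[e] = log s₀² + ψ(d/2) − log(d/2) − ψ(d₀/2) + log(d₀/2),
Var[e] = ψ′(d/2) + ψ′(d₀/2),

(ψ digamma, ψ′ trigamma); ψ′ is inverted by Newton iteration with
asymptotic shortcuts at both extremes. When the observed spread of log s²
does not exceed pure sampling noise, d₀ = ∞ and every protein gets s₀² —
the correct limit for homogeneous variances. `moderated = FALSE` sets
d₀ = 0, recovering the ordinary pooled t-test exactly; the test suite
verifies both limits and cross-checks the moderated statistics against an
independent empirical-Bayes implementation (limma) on heterogeneous-variance
data.

Open choices resolved here:

- **FDR scope.** "FDR-corrected t-test between every condition" admits
  pooling p-values across contrasts or adjusting within each contrast.
  Benjamini–Hochberg **within each contrast** was chosen — the limma/DEP
  convention — so adding an unrelated contrast never changes an existing
  contrast's calls.
- **Contrast direction.** Lexicographic by default (pair {a, b}, a < b, is
  `a_vs_b` with log2FC = mean(a) − mean(b)); explicit numerator/denominator
  pairs override. Reversing a contrast negates log2FC bitwise and leaves p
  unchanged (tested).
- **Significance rule.** p_adj < α **and** |log2FC| > cutoff, both strict:
  a protein exactly at either boundary is not called. Defaults α = 0.05,
  cutoff = 0.5.

## Global visualisations

**PCA** runs on the top-N proteins ranked by row variance of the imputed
log2 values (N default 500, clamped to the proteins available with a
warning). "Most variable" is the ranking statistic because nothing else is
implied by "top N proteins" in standard LFQ practice; ranking by
differential-expression statistics instead would entangle the ordination
with the testing. Rows are centered but not scaled — z-scaling is a display
concern for heat maps, not part of the ordination — and each PC's sign is
fixed (largest-magnitude loading positive) so results are reproducible
across platforms.

**Heat maps** z-score each protein across samples (constant rows become
all-zero with a warning rather than NaN), cluster rows by k-means with 10
restarts under a derived seed, renumber clusters by descending size, order
rows within a cluster by correlation with the cluster centroid, and clamp
the *display* to ±`z_cap` (default 2) while exporting unclamped values.
When k exceeds the number of distinct rows, the distinct rows define the
attainable cluster count. The cluster count k is left to the user (a
typical published example uses 9); no default is imposed in the API, and
the command-line default of 9 follows that example.

## Gene-set and consensome mining

Matching between gene sets and the dataset is case-insensitive and ignores
the `.1`, `.2`… suffixes that uniquify duplicate gene symbols, so a set
containing PKLR matches both `Pklr` and `Pklr.1`. Matched genes and
not-detected genes always partition the (converted) set — an invariant the
tests enforce on random fixtures.

Human→mouse conversion uses a supplied two-column ortholog table when
available (one-to-many orthologs contribute all mouse symbols) and
otherwise a case heuristic (CYP4A14 → Cyp4a14). True orthology is not
inferable from symbols alone; the heuristic is correct for the
large majority of mouse symbols but misses gene-family splits such as
CYP4A11 → Cyp4a10/Cyp4a14, which is why the table takes precedence. The
shipped `inst/extdata` gene sets are synthetic placeholders for offline
use, marked as such in their filenames; a tested library cannot depend on a
live pathway service.

Consensome percentile thresholding is **inclusive** ("top 95th percentile"
reads as score ≥ 95); thresholding is monotone in the cutoff by
construction and by test. Enrichment summaries round the way the field
reports them: base rate to one decimal, up/down percentages to the nearest
integer. The one-sided hypergeometric p-values are an extension beyond the
informal base-rate comparison and are labelled as such in the API docs.

## The synthetic-data generator

The generator emulates: four conditions × three replicates (two diets ×
two treatments, the common design for this kind of study), per-protein
baseline log2 intensities N(25, 2), replicate noise SD 0.5, planted log2
shifts of ±2 on disjoint protein subsets (50 up, 30 down of 1000 by
default), logistic MNAR dropout centred two baseline SDs below the mean
(midpoint 21, slope 1.2) plus a 2% MAR rate, and 20 decoy + 10 contaminant
rows written in the MaxQuant "+" flag dialect. Two gene symbols are
intentionally duplicated to exercise identifier uniquification end to end.
These defaults were fixed once as a realistic emulation of a mouse-liver
LFQ experiment and are not tuned per test.

What it does **not** emulate: peptide-level structure and shared-peptide
protein grouping, intensity-dependent mean–variance trends, batch effects,
correlated proteins (co-regulation), or real consensome score
distributions. Passing tests therefore demonstrate that the algorithms are
implemented correctly and calibrated under the stated model — not that any
particular biological dataset will yield a given DEP count.

## Numerical and reproducibility choices

- One master seed governs a run; each stochastic step (imputation,
  k-means, simulation) derives its own substream seed from it with a
  label hash, so steps are independent and insertion of a new step does
  not reshuffle the others.
- TSV exports format doubles with `%.6g`, making repeated runs
  byte-identical and round-trips exact *as formatted*.
- BH adjustment delegates to `stats::p.adjust` after validating inputs;
  the step-up formula is enforced against an O(m²) oracle in tests.
- Degenerate inputs fail loudly: all-zero residual variance, empty
  detected set, out-of-range percentiles, thresholds at or above the
  smallest replicate count.

## Problem sizes used by the test suite

The suite runs entirely on generated data: exhaustive detection-pattern
enumeration for 2–4 conditions × 2–4 replicates; 1000 random vectors for
the BH oracle; 500 global-null simulations (2000 proteins, 2 × 3 design)
for type-I-error calibration of the moderated test; 200 simulations at
planted log2FC 1.5 (n = 4, σ = 0.5) for bias and power; 200 Monte-Carlo
draws for the left-censoring contract; and 12-seed end-to-end runs at 300
proteins for recall/false-discovery behaviour. These sizes were chosen to
give stable Monte-Carlo estimates at interactive runtimes.

## Known limitations

- Single-factor designs only: no covariates, pairing, or multi-factor
  models; every condition needs ≥ 2 replicates.
- The acquisition-order column of the design is parsed and carried for
  provenance but used by no analysis step.
- The consensome schema (long or wide TSV) is this package's own; public
  consensome resources must be exported to it first.
- Live pathway-database access is intentionally absent; gene sets come
  from files.
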