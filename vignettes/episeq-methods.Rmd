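---
title: "Methods: comparing perturbation transcriptomes with episeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing perturbation transcriptomes with episeq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episeq)
```

## The question the package answers

When two gene knockouts produce overlapping transcriptomes, the natural
epistasis question is whether one factor acts *through* the other: does the
upstream knockout look like a weaker copy of the downstream knockout's
transcriptional program? episeq operates entirely at the level of
differential-expression (DE) summaries — per-gene log2 fold change oriented
wild-type over knockout, an adjusted *P*, and a mean-expression value — so
any DE engine can feed it. Four statistics address the question from
different angles: phase-rank enrichment (which cell-cycle programs move),
regulated-set overlap (do the same genes move), bootstrap-calibrated
concordance (do they move coherently), and the attenuation slope (by how
much). A fifth component handles proliferation (EdU incorporation) counts
from the accompanying imaging experiments.

## The statistics and their assumptions

### Percentile-rank phase enrichment

All genes with a usable log2 fold change are converted to percentile ranks.
The package uses the Hazen definition $r_i = (\mathrm{rank}_i - 0.5)/N$ with
average ranks for ties, chosen because the median Hazen rank of any
distinct-valued vector is *exactly* 0.5 — the anchor the test compares
against, so the whole-genome "phase" is exactly null by construction. The
percent-rank variant $(\mathrm{rank}-1)/(N-1)$ is available via
`rank_method = "percent"` for compatibility with tools that use it; it moves
the all-gene median only by $O(1/N)$.

Each phase set's ranks are tested against 0.5 with a two-sided one-sample
Wilcoxon signed-rank test. Numerical conventions: differences exactly equal
to the anchor are dropped (the classical zero-handling); the exact null
distribution is used for $n \le 25$ after zero removal when the absolute
differences are tie-free, otherwise the normal approximation with tie and
continuity correction. The exact/approximate boundary matters little in
practice — the mean absolute gap between the two *P* values on simulated
data is below 0.01, though single configurations at $n \le 8$ can differ by
up to ~0.04 — and 25 keeps the exact path cheap. BH correction is applied
across the phases tested in one call (one panel = one family); cross-dataset
pooling is deliberately not performed. Genes belonging to several phases are
tested in each phase independently, because curated phase lists allow
multi-phase membership. Phases with fewer than two usable genes are flagged
untestable rather than dropped.

The test assumes exchangeability of a phase's ranks under the null; it is
exact under a genuinely random gene set, which is what the type-I
simulations verify.

### Regulated sets and hypergeometric overlap

Up-/downregulated sets use strict inequalities (`log2fc > 0` or `< 0`,
`padj < alpha`), so boundary values are excluded — this mirrors the usual
printed definitions. An `lfc_threshold` argument supports the stricter
"downregulated below −0.1" dialect used for GO input lists. Genes with
missing `padj` are treated as non-significant everywhere, but remain in
rank-based statistics as long as their fold change is present, since ranks
need only log2fc.

Overlap significance is the upper-tail hypergeometric probability
$P(X \ge k)$, computed through the survival function at $k-1$ to avoid the
off-by-one that the "$\ge k$" formulation invites. The universe is the set
of genes expressed in *both* merged datasets: a union universe would count
genes that had no chance to appear in one dataset's regulated set and so
inflate enrichment. (Whether the original analyses used the merged or a
single dataset's expressed set is not documented; the universe is an
explicit argument.) Gene-id matching throughout is exact and case-sensitive
— symbol tables from a single annotation should agree exactly, and silent
case-folding risks false joins.

### Bootstrap-null concordance

The Spearman ρ of the two datasets' fold changes over the selected
(predictor-dependent) genes is compared with an empirical null: `n_iter`
random gene sets of the same size, drawn from all merged genes without
replacement within a draw (a gene set cannot contain a gene twice) and with
replacement across draws. The selected set is *not* excluded from the
sampling frame — the null is "a random gene set", not "a random
non-dependent set". The observed ρ becomes
$Z = (\rho - \hat\mu_0)/\hat\sigma_0$, and the one-sided upper-tail normal
probability is reported on the natural-log scale and never exponentiated
internally, so a $|Z|$ of 30 still yields a finite, comparable number.
The default `n_iter` of 100,000 makes the null moments stable to well past
two significant figures; calibration simulations in the test suite use
10,000, which is already stable to ~2 figures. The selection rule for
"dependent genes" is `padj < alpha` in the predictor dataset regardless of
direction.

Two degenerate cases are handled explicitly: a selected set equal to the
whole universe makes every null draw identical (zero null SD) and raises an
error rather than an infinite Z; a draw whose fold changes are all tied has
undefined ρ and is scored 0, the centre of the permutation null — relevant
only in the noise-free-predictor simulation mode, where non-regulon
predictor fold changes are exactly zero and an all-tied draw occurs with
probability below $10^{-6}$.

### Attenuation slope

The central estimand is the OLS coefficient in
$\mathrm{log2FC}_{A} \sim \beta_0 + \beta\,\mathrm{log2FC}_{B}$ over the
dependent genes: the response-dataset fold change per unit predictor fold
change. The 95% CI comes from the t distribution with $n-2$ df — at
thousands of genes this is indistinguishable from the normal, but the
synthetic small-$n$ tests need the exact small-sample form. Plain OLS is
the estimand on purpose: with measurement noise in the predictor the slope
is attenuated below the true activity fraction by the predictor's
reliability ratio, and an errors-in-variables "correction" (Deming
regression) would change what is being estimated. Axis clipping of extreme
points (displayed at 0.1 outside the limit) affects `plot()` only, never
the statistics.

### Proliferation counts

Genotype × EdU± tables get the Pearson chi-squared test of homogeneity,
with Yates continuity correction for 2×2 tables only — the convention of
R's `chisq.test`, which downstream comparisons assume — and post-hoc
pairwise 2×2 tests BH-corrected within the table. Proportion CIs use the
Wilson score interval, which stays inside $[0,1]$ and behaves at observed
proportions of 0 and 100% where the Wald interval collapses; the interval
method behind published error bars is rarely stated, so `method = "wald"`
is available for comparison.

## The synthetic generator

`simulate_perturbation_pair()` emulates the *statistical* structure of a
DE-table pair and nothing below it. A gene universe `g000001…` contains a
regulon (default fraction 0.25 of 2000 genes) whose effects
$\beta_g \sim N(0, \mathrm{effect\_sd}^2)$ drive the downstream dataset;
the upstream dataset retains the fraction `attenuation_f` of each effect.
Non-regulon genes are pure noise. Adjusted *P* values are produced from a
two-sided normal z-statistic
$\mathrm{log2fc}/(\mathrm{noise\_sd}/\sqrt{n_\mathrm{reps}})$ followed by
the *same* BH operation the analysis path uses — one source of truth for
the correction.

Defaults (2000 genes, regulon fraction 0.25, effect SD 1, noise SD 0.2,
3 replicates per group) describe a mid-sized bulk RNA-seq knockout
experiment with a strong, broad regulon; the effect-size distribution of
any real regulon is unknown, so effect SD 1 — fold changes mostly within
±2 — is a documented free choice, made once. Two noise modes exist:
the default adds noise to the upstream (response) dataset only, making the
OLS slope an unbiased estimator of `attenuation_f` so that CI-coverage
claims are testable; `predictor_noise = TRUE` adds noise to both sides and
reproduces the reliability-ratio attenuation discussed above.

Determinism contract: identical parameters (including seed) give
byte-identical outputs, and the generator's draws come from fixed
substreams of the master seed (`seed + k·48271 mod 2³¹−1` for component
`k`), so adding a new simulated component never perturbs existing draws.
All simulation helpers restore the caller's RNG state.

What the generator does *not* emulate: read counts, library-size effects,
dispersion estimation, gene–gene correlation, or the mean–variance
relationship of real RNA-seq. Passing recovery tests therefore show that
the statistics are correct for data matching their assumptions — not that
real datasets satisfy those assumptions. In real tables, correlated genes
make the bootstrap null wider than an independence null would be, which is
exactly why the concordance test builds its null from the data at hand
rather than from theory.

`simulate_phase_sets()` plants disjoint phase sets with additive
fold-change shifts (shift 0 = true null); `simulate_edu_counts()` draws
binomial EdU-positive counts per genotype.

## Simulation sizes used by the tests

The verification suite runs, as the package's own study conditions:
slope recovery and CI coverage with 200 repeats per planted coefficient
(0.34, 0.43, 1.0) at 2000 genes; phase-enrichment type-I over 500 null
simulations of a random 50-gene set (tolerance three binomial SEs around
α); bootstrap-Z calibration over 200 independent-column simulations at
10⁴ null draws; and planted-concordance detection (f = 0.5, noise 0.2)
over 200 repeats at 10³ draws, where every repeat must give positive Z
with one-sided ln *P* below ln(0.001). `scripts/acceptance.R` recomputes
the same quantities from scratch at an arbitrary seed.

## Known limitations

- The attenuation slope is a regression, not a causal estimate; it
  quantifies proportionality of fold changes over a selected set whose
  selection (predictor significance) is itself noisy in real data.
- With predictor noise the slope under-estimates the true activity
  fraction; the package reports the OLS estimand by design.
- The bootstrap null inherits whatever structure the merged table has; it
  calibrates "random gene set of this size", nothing finer (e.g. matched
  expression strata).
- BH families are per call. Analyses that mix batteries should think about
  the family they want before calling.
- Ortholog mapping, transcript-to-gene aggregation and DE fitting are out
  of scope: the package starts from finished DE tables.
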