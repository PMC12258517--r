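# episeq

Statistical machinery for comparing the transcriptomes of two perturbations —
typically wild-type-versus-knockout differential-expression (DE) results for
an upstream regulator and for its downstream effector — to ask whether one
perturbation's transcriptional program is an attenuated copy of the other's.
It was built for regulatory-hierarchy (epistasis) questions of the kind that
arise at the mitosis-to-meiosis transition in fetal germ cells, where knockouts
of a signaling receptor, an RNA-binding protein and a meiotic transcription
factor produce overlapping transcriptomes, but it applies to any pair of DE
tables oriented wild-type over knockout.

## What it computes

Given per-gene DE summaries (log2 fold change WT/KO, adjusted *P*, mean
expression) for a *response* dataset A and a *predictor* dataset B:

- **Cell-cycle-phase percentile-rank enrichment.** Every gene is mapped to its
  Hazen percentile rank `(rank − ½)/N` of log2 fold change; each phase gene
  set (G1/S, S, G2, M, M/G1) is tested against the genome-wide median of 0.5
  with a two-sided one-sample Wilcoxon signed-rank test, BH-corrected across
  phases. Median rank > 0.5 means the perturbed factor downregulates that
  phase's program.
- **Regulated-set overlap.** Up-/downregulated sets (`log2FC > 0` resp. `< 0`
  and adjusted *P* < 0.05, strict) are compared with one-tailed hypergeometric
  tests, `P(X ≥ k)` over the genes expressed in both datasets, BH-corrected
  per battery.
- **Bootstrap-null concordance.** Spearman ρ of the two datasets' fold changes
  over the B-dependent genes (adjusted *P* < 0.05 in B), calibrated against
  ρ's of many random same-size gene sets drawn from all merged genes:
  `Z = (ρ − mean₀)/sd₀`, with the one-sided upper-tail normal probability
  reported on the natural-log scale so it never underflows.
- **Attenuation slope.** OLS fit of

  ```
  log2FC_A ~ β₀ + β · log2FC_B
  ```

  over the B-dependent genes, with a t-based 95% CI. β = 1 means the A
  perturbation reproduces B's program in full; β ∈ (0, 1) means partial
  retention (attenuation).
- **Proliferation counts.** Chi-squared homogeneity of genotype × EdU±
  count tables, post-hoc pairwise 2×2 tests with BH correction, and Wilson
  score CIs for per-group proportions.

A seeded synthetic generator (`simulate_perturbation_pair()`) emulates DE
tables with a planted regulon and attenuation coefficient *f*, so slope
recovery, CI coverage and test calibration are all verifiable.

## Worked example

```r
library(episeq)

# synthetic pair: 2000 genes, planted attenuation f = 0.43, plus phase sets
# with planted rank shifts on the response table
sim    <- simulate_perturbation_pair(sim_params(n_genes = 2000,
                                                attenuation_f = 0.43,
                                                seed = 101))
phases <- simulate_phase_sets(sim$downstream$gene, 5, 50,
                              shift = c(0.8, 0.4, 0, 0, -0.4), seed = 101)
up     <- apply_phase_shifts(sim$upstream, phases$sets, phases$shifts)

res <- epistasis(up, sim$downstream, labels = c("meiocKO", "stra8KO"),
                 phase_sets = phases$sets, n_iter = 10000, seed = 101,
                 quiet = TRUE)
res
#> Epistasis comparison: meiocKO (response) vs stra8KO (predictor)
#>   2000 merged genes, 367 stra8KO-dependent genes selected
#>   Spearman rho = 0.815, Z = 7.93 (ln P = -34.48, 10000 null draws)
#>   attenuation slope = 0.452 (95% CI 0.419-0.485)

print(res$phase$meiocKO, digits = 3)
#>   phase n_genes_tested median_rank     q1    q3    p_raw    p_adj
#> 1  G1/S             50      0.9772 0.9432 0.992 2.30e-09 1.15e-08
#> 2     S             50      0.9240 0.6756 0.966 1.53e-06 2.55e-06
#> 3    G2             50      0.5628 0.1905 0.922 3.90e-01 4.88e-01
#> 4     M             50      0.4895 0.1390 0.900 7.25e-01 7.25e-01
#> 5  M/G1             50      0.0552 0.0164 0.395 8.95e-07 2.24e-06
```

The fitted slope 0.452 (CI 0.419–0.485) recovers the planted attenuation
coefficient 0.43: the response perturbation retains roughly 45% of the
predictor factor's transcriptional program. The concordance Z of 7.9 says the
ρ of 0.815 on the dependent genes is far beyond what random gene sets achieve
(null ln *P* ≈ −34). The phase table reflects the planted shifts: strong
positive shifts on G1/S and S push their median ranks toward 1 (those
programs are downregulated in the knockout), the −0.4 shift pushes M/G1 below
0.5, and the unshifted G2 and M phases are correctly non-significant.

`summary(res)` adds the overlap battery, `plot(res)` draws the fold-change
scatter with the fitted slope, and `write_epistasis_report(res, dir)` emits a
deterministic JSON + TSV report. `run_pair_analysis("config.yaml")` drives
the same analysis from a YAML file describing input paths and thresholds.

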