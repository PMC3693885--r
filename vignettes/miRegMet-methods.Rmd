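---
title: "Methods: miRNA target-set regulation, methylation coupling, and expression-driven selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA target-set regulation, methylation coupling, and expression-driven selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRegMet)
```

## The model

`miRegMet` asks, for every miRNA *m* and every ordered pair of tissue
regions (ℓ, ℓ′) sampled from the same subjects, three nested questions:

1. **Is the miRNA's target-gene set coordinately shifted between the two
   regions?** For subject *j* the per-gene difference is
   Δ_g = log x_gℓ − log x_gℓ′ on expression layers (natural log,
   signals floored at ε = 10⁻⁸) and Δ_g = β_gℓ − β_gℓ′ on the
   methylation beta scale. The directional statistic is a one-sided
   two-sample comparison of {Δ_g : g targeted by m} against
   {Δ_g : g not targeted by m}, giving the pair
   (P_less, P_greater) per miRNA and subject. Computed on the mRNA layer
   this measures miRNA-mediated regulation; on the methylation layer it
   measures miRNA-targeting-specific promoter methylation.
2. **Are the two layers coupled?** Within each subject the P-values are
   ranked across miRNAs and rescaled to (0, 1]; the per-miRNA means of
   these rescaled ranks over subjects form one profile per layer, and
   ρ is their Spearman correlation across miRNAs. The per-subject
   Spearman correlations ρ_j between the two layers' P columns are
   summarised by Δρ = √(mean ρ_j²). Because Δρ is an RMS it always
   dominates |mean(ρ_j)| (Jensen), so it stays informative when
   subject-level correlations are strong but of mixed sign.
3. **Does regulation track the miRNA's own differential expression?**
   Each directional pair is collapsed to a signed score
   z = Φ⁻¹(P_less) − Φ⁻¹(P_greater), and per miRNA the regulation score
   is regressed by OLS on the methylation score, the subject's miRNA
   log-ratio (`dmir`), gender and centred age. Selection is by the
   BH-adjusted `dmir` coefficient P-value at α; the coefficient's sign
   labels the miRNA *reciprocal* (negative: miRNA up ⟹ targets down)
   or *nonreciprocal*. The pooled targets of selected miRNAs are then
   tested for pathway enrichment with an upper-tail hypergeometric test.

### Assumptions

- Signals are processed array intensities (expression, positive scale)
  and beta values (methylation, [0, 1]); no count model and no
  renormalisation is applied.
- The pairing unit is the subject: the per-subject index in every
  statistic refers to the same individual measured in both regions of a
  pair, in all three layers.
- Non-targets for miRNA *m* are all universe genes not targeted by *m*
  (not "genes targeted by no miRNA"), matching the per-miRNA contrast.
- The target map is an external input; its provenance (prediction
  database, confidence cutoffs) is outside the model.

## Test-family choice

The exact two-sample family behind the directional P-values is exposed
rather than fixed, because the appropriate family depends on what is
known about the signal scale:

- `ranksum_normal` — Mann–Whitney with tie correction and continuity
  correction; robust to monotone rescaling of the signals.
- `ranksum_exact` — the exact Mann–Whitney null; used automatically
  (method `"auto"`, the default) when the smaller group has ≤ 10
  members, the pooled size is ≤ 200 and there are no ties. The exact
  null is combinatorial in n_t·n_o, so against thousands of non-targets
  the normal approximation is used; the convergence of the two is a
  tested property (max |ΔP| < 0.01 at group sizes ≥ 30).
- `ttest` — one-sided Welch, for users who prefer a location test; its
  two tails are exactly complementary (P_less + P_greater = 1).

Both rank variants are implemented so that swapping the region order
exchanges P_less and P_greater *bit-for-bit*: each pair of tails is
computed from a single lower-tail primitive using the reflection
U ↔ n_t·n_o − U (exact) or negation of the centred statistic (normal).
All P-values are kept in (0, 1] — never exactly 0 — so that downstream
quantile transforms stay finite before clamping.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `method` | `"auto"` | directional test family (see above) |
| ε (log floor) | 1e-8 | floor applied to signals before `log`; processed intensities can be ≤ 0 after background correction |
| aggregation | median | per-miRNA summary of per-subject P-values; robust, order-preserving |
| `correction` | `"BH"` | multiple-testing correction across miRNAs (and across pathways) |
| `alpha` | 0.05 | significance level for counts, selection, enrichment |
| `direction` | `"greater"` | directional channel entering the coupling correlation (both channels are computed; the choice only fixes sign conventions) |
| score clamp | ±8 | per-term bound on Φ⁻¹(P) in the signed score, so a P of exactly 1 (or the numerical floor) maps to a finite value |
| `criterion` | `"dmir"` | selection by the miRNA-expression coefficient; `"dmir_or_meth"` also admits methylation-driven miRNAs |

## The synthetic generator

`generate_study()` emulates the structure the analysis assumes: a shared
cohort (default 50 subjects; ages uniform on [20, 90], gender
Bernoulli(0.5)) measured in every region (default the four labels
CRBLM/FCTX/PONS/TCTX, fully crossed; a `dropout` fraction exercises
incomplete designs). Gene and miRNA baselines are log-normal
(log-mean 6, log-sd 1) with Gaussian log-scale noise (sd 0.5);
methylation baselines are uniform on [0.2, 0.8] with Gaussian beta-scale
noise (sd 0.05), clipped to [0, 1] — under these defaults clipping
touches < 1% of entries (reported when exceeded). Planted effects are
per-miRNA, per-region-pair shifts: target-gene log-expression (δ_reg),
target-promoter beta (δ_meth), the miRNA's own log-expression (δ_mir),
and a *coupling* mechanism in which each subject's target shift equals
β times that subject's realized miRNA log-ratio plus N(0, σ_β) noise —
the causal link that the regression stage is designed to detect. A
Gaussian noise model (rather than counts) matches processed array
signals. The generator emits the ground truth alongside the study, and
the all-null configuration `default_null_config()` yields directional
P-values that are Uniform(0, 1) (KS distance < 0.02 at 10,000 values, a
tested property).

For the coupling stage specifically, planting a *calibrated* Spearman
correlation ρ* between the two layers' mean-rank profiles through the
full generator is not analytically controllable, so
`simulate_coupled_tables()` generates coupled P-value table pairs
directly from a latent Gaussian copula: per-miRNA latent scores with
Pearson correlation r = 2·sin(πρ*/6) (the value at which the population
Spearman of a bivariate normal equals ρ*), mixed with per-subject noise
of weight w = 0.3. With 50 subjects the mean ranks average the noise
away and the recovered ρ is within ±0.1 of ρ* on average.

What the generator does **not** emulate: real platform artifacts, probe
redundancy, the correlation structure of a real transcriptome
(co-expression modules, shared targets between miRNA families beyond
random overlap), batch effects, or realistic effect-size distributions.
Passing recovery tests therefore demonstrates that the statistics
measure what they claim under their own assumptions — not that any
particular biological dataset satisfies those assumptions.

## Numerical choices and degenerate inputs

- Genes with a missing value in either sample of a subject's pair are
  dropped from that subject's comparison; a miRNA whose targets are all
  dropped gets an NA entry, excluded from rank profiles and medians.
- Within-subject ranks are rescaled by the number of non-missing
  miRNAs, so subjects with different missingness contribute comparable
  profiles.
- Ties take average ranks everywhere (test statistic, Spearman,
  mean-rank profiles).
- Degenerate comparisons (empty target set or complement, zero rank
  variance) yield NA at table level rather than an error; a constant
  vector in the Spearman estimator yields NA with a warning; |ρ| = 1 in
  the correlation P-value returns exactly 0 with a `degenerate` flag.
- Rank-deficient regression designs raise an error naming the collinear
  columns; designs need at least p + 2 = 7 subjects.
- The enrichment universe is the union of pathway genes intersected
  with the study's genes; query genes outside it are dropped (counted),
  which keeps overlaps k and the query size n consistent.
- All pipeline outputs are written by a single deterministic TSV writer
  and a sorted-name JSON writer; identical config + seed gives
  byte-identical output trees, and running the five stages separately
  reproduces the one-shot run exactly.

## Design choices where the design was open

- **Aggregation of per-subject P-values** into a per-miRNA call uses
  the median, then BH across miRNAs: robust to outlying subjects and
  order-preserving. Mean aggregation would weight extreme subjects more.
- **The coupling channel** defaults to P_greater on both layers; using
  one consistent channel keeps the sign of ρ interpretable, and the
  opposite channel is a configuration switch.
- **The regression response transform** is the signed z-score rather
  than a raw P-value: raw directional P-values are bounded and bimodal
  under signal, which breaks linear-model residual assumptions, while
  the score is approximately Gaussian under the null, symmetric, and
  direction-preserving.
- **Reciprocal/nonreciprocal** is operationalised as the sign of the
  `dmir` coefficient — the only binary, testable reading of a
  suppression-consistent (reciprocal) versus co-directional
  relationship between miRNA expression and target regulation.

## Problem sizes used by the test suite

The property checks run at sizes chosen to make their tolerances sharp
while keeping the suite quick: null calibration at 200 miRNAs × 50
subjects (10,000 pooled P-values); exact-test enumeration on 500
instances of ≤ 10 genes; coupling recovery at M = 500 over 20 seeds and
null calibration over 100 seeds; regression recovery with 10 planted
miRNAs (|β| = 1.5, σ_β = 0.5) among 200 at 50 subjects over 100 seeds
(30 seeds in `scripts/acceptance.R`); and the structural/determinism
checks on a 4-region, 25-miRNA pipeline run.

## Known limitations

- The directional statistic treats genes as exchangeable within target
  and non-target groups; gene–gene correlation inflates the effective
  variance and is not modelled (a per-subject permutation null would
  be the extension).
- Overlapping target sets make per-miRNA tests dependent across
  miRNAs; BH remains valid under the resulting positive dependence but
  counts of significant miRNAs should be read as descriptive.
- The hypergeometric enrichment is a local stand-in for web-tool
  pathway analyses whose universe and statistic may differ; results
  depend on the pathway database and the universe convention.
- OLS with Gaussian theory P-values is used for the per-miRNA
  regression; with few paired subjects (< ~15) those P-values are
  approximate for the non-Gaussian score response.
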