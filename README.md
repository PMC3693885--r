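# miRegMet

Integrative analysis of miRNA-mediated gene regulation, promoter
methylation and differential miRNA expression between paired tissue
groups — with a synthetic multi-omics generator that makes every stage
verifiable by exact oracles and parameter recovery.

## The scientific problem

miRNAs suppress their target genes post-transcriptionally, and promoter
methylation suppresses transcription; whether the two act on the same
genes in a coordinated, tissue-specific way is a question that can be
asked directly of multi-layer array data (mRNA expression, miRNA
expression, promoter methylation beta values) collected from the same
subjects across several tissue regions. `miRegMet` implements the full
statistical pipeline for that question, for anyone with three
feature-by-sample matrices, a sample annotation table, a miRNA→target
map, and (optionally) a GMT pathway database.

## The statistics

For each miRNA *m*, subject *j* and ordered region pair (ℓ, ℓ′):

- **Directional target-set P-values** `P_less` / `P_greater`: one-sided
  tests of whether the per-gene differences
  Δ_g = log x_gℓ − log x_gℓ′ (expression; natural log, signals floored
  at 1e-8) or Δ_g = β_gℓ − β_gℓ′ (methylation) of *m*'s target genes are
  stochastically shifted relative to all non-target genes. Default is a
  Mann–Whitney rank-sum test (exact null for small target sets,
  tie-/continuity-corrected normal approximation otherwise); a one-sided
  Welch *t* variant is also exposed.
- **Direction counts**: per-miRNA median P over subjects, BH correction
  across miRNAs, counts of significantly up-/down-shifted target sets
  and a net "arrow" call per region pair (larger count wins).
- **Coupling** between the regulation and methylation layers:
  ρ = Spearman correlation, across miRNAs, of the per-miRNA mean
  P-value ranks (ranks taken within subject, rescaled to (0,1], averaged
  over subjects), with a *t*-based P-value; and
  Δρ = root-mean-square of the per-subject Spearman correlations ρ_j,
  which can stay large when positive and negative ρ_j cancel in the mean.
- **Per-miRNA regression**: the signed regulation score
  z = Φ⁻¹(P_less) − Φ⁻¹(P_greater) (per-term clamp ±8) is regressed on
  the methylation score, the subject's miRNA log-ratio
  log(x_mℓ/x_mℓ′), gender and centred age (OLS). miRNAs whose
  BH-adjusted miRNA-expression coefficient is ≤ α are selected and
  labelled **reciprocal** (negative coefficient: miRNA up ⟹ targets
  down) or **nonreciprocal**.
- **Pathway enrichment**: upper-tail hypergeometric test of the selected
  miRNAs' pooled target genes against each pathway, BH across pathways,
  plus a pathway × (region pair × label) presence/absence matrix.

The synthetic generator (`synthetic_config()` / `generate_study()`)
emits a fully crossed subject-by-region study with planted regulation,
methylation, miRNA differential-expression and coupling effects, and the
matching ground truth for recovery tests.

## Worked example

Three miRNAs are planted whose target-gene regulation tracks their own
differential expression (slopes ±2); all other miRNAs are null:

```r
library(miRegMet)

cfg <- synthetic_config(
  n_genes = 1500, n_mirnas = 100, n_subjects = 40,
  region_labels = c("CRBLM", "FCTX"),
  coupling_effects = data.frame(
    mirna_id = c("mir0001", "mir0002", "mir0003"),
    ell = "CRBLM", ellprime = "FCTX",
    beta = c(2, -2, 2), sigma_beta = 0.4),
  seed = 101)
gen <- generate_study(cfg)

mt <- compute_pvalue_table(gen$study, "mrna",        c("CRBLM", "FCTX"))
ht <- compute_pvalue_table(gen$study, "methylation", c("CRBLM", "FCTX"))
coupling_correlation(mt, ht)
#> <coupling_summary> CRBLM vs FCTX (direction=greater)
#>   rho_mean_rank = -0.0688 (P = 0.497, M = 100)
#>   delta_rho (RMS of 40 per-subject rho_j) = 0.0801

res <- select_mirnas(fit_all_regressions(
  build_design(gen$study, mt, ht, c("CRBLM", "FCTX"))))
res[res$selected, c("mirna_id", "coef_dmir", "p_dmir_adj", "label")]
#>   mirna_id coef_dmir   p_dmir_adj         label
#> 1  mir0001  13.71207 2.765230e-11 nonreciprocal
#> 2  mir0002 -14.26121 7.063906e-14    reciprocal
#> 3  mir0003  12.96605 6.731476e-10 nonreciprocal
```

Exactly the three planted miRNAs are recovered; no coupling between the
layers was planted, so `rho_mean_rank` is consistent with zero. The
regression coefficients are on the signed-score scale (score units per
log-unit of miRNA change), so their magnitude reflects how sharply the
rank-sum score saturates, not the planted slope itself; their sign gives
the reciprocal/nonreciprocal label.

The same analysis runs end-to-end from a YAML config:

```sh
exec/miregmet all --config my_run.yaml --outdir results/run1 --seed 7
```

with subcommands `simulate | stats | couple | regress | enrich | all`,
each stage reading the previous stage's TSV outputs.

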