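# glistat

Quantitative analysis of cooperative Hedgehog/GLI and JAK/STAT signaling
driving the immunosuppressive enzyme **IDO1** (indoleamine
2,3-dioxygenase 1) in skin cancer transcriptomes.

Constitutive Hedgehog (HH) signaling through GLI transcription factors is
the oncogenic driver of basal cell carcinoma and contributes to melanoma;
pro-inflammatory IL6/STAT3 and IFNγ/STAT1 signaling can cooperate with it.
`glistat` asks, in data, whether the two pathway families induce IDO1 *more
than additively* — the transcriptional signature of synergy and a candidate
immune-evasion mechanism — and provides everything needed to test that
question end to end on bulk and single-cell RNA-seq, including a
synthetic-data generator with known planted effects so every stage is
verifiable without patient-level data access.

## What it computes

**Bulk pipeline** (`run_bulk_pipeline()`):

1. **Normalization** — trimmed-mean-of-M-values (TMM) scaling factors,
   implemented from the published procedure, and the log2-cpm transform
   `log2((count + 0.5) / (libsize · factor + 1) · 10⁶)`.
2. **Pathway activity** — each gene z-scaled across samples; a signature's
   per-sample score is the mean z over its genes:
   `score_s = (1/|G|) Σ_{g∈G} z_gs`.
3. **Stratification** — samples split into pathway-high/low at a cutoff
   (−0.5 for the HH signature, 0 for the IL6 signature; ties go to high).
4. **Synergy model** — ordinary least squares for
   `IDO1 ~ β₀ + β_H·HH + β_I·IL6 + β_int·(HH × IL6)`,
   with IL6 binary (high/low) and HH binary or continuous; `β_int > 0`
   means more-than-additive induction. Welch's t tests compare IDO1 between
   strata; Spearman correlation is available for gene–gene association.

**Single-cell pipeline** (`run_sc_pipeline()`), per patient, never pooled:
presence-based classification (GLI-active ⇔ any of GLI1/GLI2/GLI3 detected;
STAT1-active ⇔ STAT1 *and* IRF1 detected; IDO1-positive ⇔ any detectable
IDO1), the IDO1 × GLI/STAT1-double-positive 2×2 table with per-state
percentages, and Fisher's exact test (minimum-likelihood two-sided p; sample
odds ratio with Haldane–Anscombe correction when a cell is zero).

**Assay arithmetic** (`relative_expression()`, `synergy_score()`,
`percent_input()`, `metabolite_fold()`): 2^−ΔΔCt qPCR fold changes, the
factorial synergy score `((fold_A − 1) + (fold_B − 1)) / (fold_AB − 1)`
(score < 1 ⇒ synergy), ChIP-qPCR percent of input chromatin, and
internal-standard-normalized metabolite fold changes.

**Formats** — delimited count tables, Broad-dialect GMT gene sets, and
MatrixMarket sparse single-cell triples (`read_count_matrix()`,
`read_gmt()`, `read_sparse_cells()`, plus writers).

## Worked example

```r
library(glistat)

# a synthetic 83-sample cohort with a planted interaction effect of 1.5
sim <- simulate_bulk(bulk_sim_config(), seed = 11)
report <- run_bulk_pipeline(sim$data, sim$gene_sets, data_type = "expression")
print(report)
```

```
Bulk synergy pipeline report (glistat 0.1.0)
 - normalization: skipped (input already log2-cpm scale)
 - scaling: 241 gene rows z-scaled across 83 samples
 - signature 'HH': 20 genes -> 60 high / 23 low
 - signature 'IL6': 20 genes -> 38 high / 45 low
 - comparison 'HH' high vs low: p = 9.47e-16
 - comparison 'IL6' high vs low: p = 0.00115
 - interaction fit (HH binary): interaction p = 8.17e-08
Two-pathway interaction model (n = 83, HH encoding: binary)
          estimate     se       t      p
intercept   2.8214 0.3222  8.7571 0.0000
hh          2.1415 0.3821  5.6050 0.0000
il6        -0.8187 0.4886 -1.6756 0.0978
hh:il6      3.3917 0.5737  5.9123 0.0000
Residual df: 79  R-squared: 0.7559
```

The positive, significant `hh:il6` row is the synergy readout: IDO1 is
induced in HH-high/IL6-high samples beyond the sum of the two single-pathway
effects. (The estimate exceeds the planted continuous-scale 1.5 because the
pipeline's default binary HH encoding re-parameterizes the effect across the
two mixture components.)

```r
sc <- simulate_cells(sc_sim_config(), seed = 12)
print(run_sc_pipeline(sc$cells))
```

```
Single-cell co-activity report (glistat 0.1.0)
-- patient_1 : 5000 tumor cells, 525 IDO1-positive
Fisher's exact test (two-sided, minimum-likelihood)
         double_pos not_double_pos
IDO1_pos        164            361
IDO1_neg        102           4373
odds ratio (sample) = 19.48, p = 2.396e-100
```

IDO1-positive tumor cells are strongly enriched for GLI/STAT1
double-positivity (the generator planted a conditional-positivity odds ratio
of 28.5; the capture-thinned estimate is 19.5).

```r
synergy_score(2, 3, 7)
#> Synergy score = 0.5 (synergistic); folds: a=2, b=3, ab=7
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full synthetic end-to-end analysis from the given seed — the
83-sample bulk cohort through the Poisson count layer (TMM, scoring,
stratification, Welch comparisons, interaction fit) and two independently
simulated single-cell patients (classification, contingency, Fisher) — and
writes the JSON result file.

## Documentation

See the methods vignette (`vignettes/glistat-methods.Rmd`) for the model,
its assumptions, what the synthetic generator does and does not emulate,
and the numerical conventions (tie rules, two-sided p-value convention,
odds-ratio estimators, degenerate-input handling).
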