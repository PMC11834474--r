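---
title: "Methods: pathway co-activity and transcriptional synergy in glistat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway co-activity and transcriptional synergy in glistat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glistat)
```

# The scientific question

Oncogenic Hedgehog signaling acts through GLI transcription factors;
pro-inflammatory cytokine signaling acts through STAT3 (IL6) or STAT1
(IFNγ). When both converge on the regulatory region of a target such as
IDO1 — the tryptophan-degrading, T-cell-suppressing enzyme — induction can
exceed the sum of the single-pathway effects. `glistat` operationalizes
"more than additive" at three scales: a factorial synergy score for
bench qPCR experiments, an interaction linear model for patient-scale bulk
RNA-seq, and a co-positivity enrichment test for single tumor cells.

# Bulk model and assumptions

## Normalization

Raw counts are scaled with trimmed-mean-of-M-values (TMM) factors computed
from the published procedure: the reference sample is the one whose
upper-quartile count fraction is closest to the cohort mean; for each
sample, log2 expression ratios against the reference (M) and mean log2
abundances (A) are formed over genes non-zero in both samples; 30% of M
values and 5% of A values are trimmed symmetrically by rank; the factor is
2 to the precision-weighted mean of the surviving M values, with
delta-method inverse variances as weights; factors are rescaled to
geometric mean 1. Counts then become
`log2((count + 0.5) / (libsize * factor + 1) * 1e6)`.

Two deliberate simplifications:

* **No per-observation precision weights.** The downstream synergy model is
  ordinary least squares on one gene, so the variance-trend weights used by
  weighted-regression workflows would have no consumer here. This is a
  recorded simplification, not a claim that the weights never matter.
* **Scalar-scaling invariance is approximate, not exact.** M values are
  scale free, but the delta-method weights depend on library size, so
  multiplying one sample's counts by a constant moves its factor in the
  fourth decimal. The established reference implementation drifts
  identically; the test suite pins both behaviors. The two exact special
  cases — identical libraries, and a library that is a per-gene doubling of
  another — return factors of exactly 1 via the all-M-zero short circuit.

## Signature scores and stratification

Each gene row of the log2-cpm matrix is centered and scaled to unit
standard deviation (n − 1 denominator). A pathway signature's per-sample
activity is the unweighted mean of z-values over its genes; genes absent
from the matrix are dropped with a warning (never imputed), because the
score is defined as the average over available signature genes.
Zero-variance genes cannot be z-scaled and become all-zero rows with a
warning — they then dilute, but cannot bias, any score they belong to.

Samples are stratified at a score cutoff: −0.5 for the HH-like signature
and 0 for the IL6-like one by default. The HH cutoff is below zero because
in a mixed tumor/normal cohort the tumor (HH-active) fraction dominates,
pulling the score distribution's upper mode past zero. **Tie rule:** a
score exactly at the cutoff is called *high*. The boundary case is
measure-zero for continuous scores, but a decided, documented rule keeps
the partition deterministic; `ties = "low"` gives the open-bound variant.

## The interaction model

With per-sample target expression `y` (log2-cpm), an HH predictor `h` and a
binary IL6 indicator `i`:

`y = b0 + bH * h + bI * i + bint * h * i + e,  e ~ N(0, s^2)`

fitted by QR-based ordinary least squares with classical standard errors
and two-sided t p-values on n − 4 degrees of freedom (95% confidence level
throughout). `bint > 0` is the synergy readout. A rank-deficient design
(constant predictor, empty factorial cell) is a hard error rather than a
silent coefficient drop, because a silently reduced model would change the
meaning of the reported interaction.

**HH encoding.** The IL6 predictor is defined as binary; for HH both a
binary high/low encoding (default — it matches the 2×2 group comparison
reading of the analysis) and a continuous score encoding are provided. The
fit always records which encoding produced it, so reported coefficients are
never ambiguous. The two encodings estimate different (both legitimate)
parameterizations of the same planted effect; they are not expected to
agree numerically.

Group contrasts accompanying the model use Welch's unpaired t test
(Satterthwaite degrees of freedom). If both groups have zero variance the
statistic is 0/0 and the call is rejected with a message; a single
zero-variance group is handled by the formula's natural limit. Spearman
correlation uses mid-ranks for ties and the t approximation on n − 2
degrees of freedom for its p-value.

# Single-cell model

Classification is presence-based on raw counts, with no normalization:
droplet capture is the dominant noise source and the rules are defined on
detectability, so a cell is GLI-active if any of GLI1/GLI2/GLI3 has a count
at or above the detection threshold (default 1, i.e. any detectable
transcript), STAT1-active if STAT1 *and* IRF1 both do, and IDO1-positive if
IDO1 does. The threshold is configurable for sensitivity analyses but the
default is the published presence rule.

Enrichment of GLI/STAT1 double positivity among IDO1-positive cells is
tested per patient with Fisher's exact test. Two conventions are fixed and
documented because alternatives exist:

* **Two-sided p-value:** minimum-likelihood convention — the sum of
  probabilities of all tables with the observed margins whose
  hypergeometric probability does not exceed the observed table's (relative
  tolerance 1e-7 guards floating-point ties). This matches R's `fisher.test`,
  the environment the published cutoffs come from; doubling-the-one-sided-p
  is a different convention and gives different values.
* **Odds ratio:** the sample estimate `ad/bc` by default, with the
  Haldane–Anscombe +0.5 correction applied only when some cell is zero; the
  conditional maximum-likelihood estimate (what `fisher.test` prints) is
  available as `or_method = "conditional_mle"`. The result object always
  states which estimator produced it.

Patients are analyzed strictly separately: pooling cells across patients
would let between-patient composition differences masquerade as
within-tumor co-activity (Simpson's pattern). The report also emits the
four-state (double-positive / GLI-only / STAT1-only / double-negative)
percentage breakdown within each IDO1 group, so both the 2×2 test reading
and the percentage-bar reading of the analysis are reproducible from one
run.

# Assay arithmetic

* **Relative qPCR expression:** replicate Ct values are averaged per
  condition *before* differencing (the variance of per-replicate folds is
  asymmetric; averaging Ct first is the convention the arithmetic assumes,
  and the alternative is configurable at the data level). Fold change is
  `eff^-(ddCt)` with amplification efficiency fixed at 2.0 per cycle and
  exposed as a parameter.
* **Synergy score:** `((fold_A - 1) + (fold_B - 1)) / (fold_AB - 1)` — each
  treatment's induction in excess of the untreated baseline (fold 1),
  single agents summed and compared with the combination. Below 1 ⇒
  more-than-additive; exactly 1 ⇒ additive; above 1 ⇒ sub-additive. The
  source that originally defined the score is not freely available, so this
  form — the natural factorial statistic satisfying the published
  score-below-1-means-synergy reading and the additive boundary — is
  isolated behind a single function and labelled in its result, making it
  swappable without touching callers. The score is undefined (error) when
  the combination does not induce (`fold_AB <= 1`).
* **ChIP percent of input:** the input Ct is first shifted by
  `log2(1/input_fraction)` cycles to undo the input dilution, then
  `%input = 100 * 2^(adjusted_input_ct - ct_ip)`; one IP cycle above the
  adjusted input halves the percentage.
* **Metabolite folds:** peak areas are divided by the internal-standard
  area per injection, replicate ratios averaged per condition, and each
  condition divided by its analyte's control — so instrument drift that
  scales all areas cancels exactly.

# The synthetic world

The generators state one fixed world, chosen once:

* **Bulk** (`bulk_sim_config()`): 83 samples — 59/83 in the HH-high mixture
  component and an even IL6 split, mirroring the cohort structure the
  analysis was designed for (59 tumors vs 24 normals, IL6 activity
  distributed across both). Latent activities are two-component Gaussian
  mixtures (means ±1, within-component sd 0.5) so that cutoff-based
  stratification has a well-defined target; 20 signature genes per pathway
  load on their activity with coefficient 1 over Gaussian noise (sd 0.5);
  200 background genes are pure noise; the target gene follows
  `4 + 1*a_HH + 1*[IL6 high] + 1.5*a_HH*[IL6 high]` plus noise. The default
  emits log2-cpm-scale values directly (the scale the analysis operates
  on); a Poisson layer inverts them through sampled library sizes when the
  normalization path itself is under test.
* **Single cell** (`sc_sim_config()`): 5,000 cells, 30% GLI-program and 30%
  STAT1-program marginals (couplable through an odds-ratio parameter),
  IDO1-positivity 0.6 in double-active cells vs 0.05 elsewhere, marker
  capture probabilities 0.6 (GLI genes) / 0.8 (STAT1/IRF1) as a realistic
  droplet dropout level. Inactive programs emit structural zeros, so
  imperfect capture can only lower sensitivity, never specificity — a
  property the tests assert. `planted_coactivity_or()` returns the
  population odds ratio the configuration implies, the convergence target
  under perfect capture.

Seeds are mandatory, and each generator component draws from its own
deterministic sub-stream, so enlarging the gene panel never perturbs
sample-level draws and identical configurations are byte-identical.

What the generators do **not** emulate: mean–variance trends and
overdispersion of real RNA-seq beyond Poisson, batch effects, doublets,
ambient RNA, cell-type mixtures (all simulated cells are tumor cells), and
correlated background genes. A green pipeline run on synthetic data
therefore establishes the *statistical machinery* — recovery, calibration,
determinism — not robustness to those artifacts.

# Numerical conventions and degenerate inputs

* Identifier matching is case-sensitive and whitespace-stripped.
* Readers preserve file order exactly; MatrixMarket indices are 1-based on
  disk (the format standard), 0-based semantics never leak to the user.
* Missing single-cell annotations become `"unassigned"` rather than errors
  (portal exports are routinely partial); an annotation for an unknown
  barcode *is* an error, since it indicates a file mismatch.
* Counts must be non-negative integers; validation errors name the
  offending gene and sample.
* All p-values are two-sided; no multiple-testing correction is applied
  anywhere in the package — single-model, per-patient results are reported
  as such.

# Limitations

The interaction model assumes homoscedastic Gaussian errors on the log2
scale and estimates a single target gene at a time. Signature quality is
the user's responsibility: scores are means over user-supplied gene sets,
and the package ships no curated signatures (the synthetic generator emits
its own, labelled as such). The single-cell rules are presence-based by
design and inherit the capture-rate ceiling of the data; the estimated
odds ratio under heavy dropout is attenuated relative to the latent one,
as the calibration tests demonstrate quantitatively.
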