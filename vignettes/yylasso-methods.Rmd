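---
title: "Methods: sample-specific lasso models of Yin/Yang gene regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-specific lasso models of Yin/Yang gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yylasso)
```

## The model and its assumptions

`yylasso` explains, tumor by tumor, the log2 expression fold change of each
modelled gene against the mean normal profile as a linear combination of
four feature blocks: the gene's copy-number score `C_g` (discrete GISTIC2
values, −2…+2), its methylation beta value `D_g` (a fraction in [0, 1]),
the binding-site counts `N_g,TF` of every transcription factor in the
gene's promoter, and the binding-site counts `N_g,miR` of the admitted
miRNAs in the gene's 3'UTR:

$$y_g \;=\; W_{CN} C_g + W_{DM} D_g + \sum_{TF} W_{TF}\, N_{g,TF}
      + \sum_{miR} W_{miR}\, N_{g,miR}.$$

One model is fitted per tumor, with genes as observations. The modelled
genes are the Yin (up) and Yang (down) genes selected from the
tumor-vs-normal comparison, so the response captures the strongest
coordinated expression programs rather than genome-wide noise. The
assumptions are the usual ones of a sparse linear model: regulatory effects
add on the log2 scale, only a small number of regulators carry signal in
any one tumor, and binding-site counts are an adequate (static,
sample-independent) proxy for potential regulation. The per-tumor framing
means no information is shared across tumors at fitting time; subtype
structure enters only afterwards, through scoring.

Two choices depart from the bare equation and deserve a note:

* **Intercept.** The fitted model includes an unpenalised intercept even
  though the equation above has none. The response is a fold change whose
  mean over genes is not zero (tumor-wide shifts, normalisation offsets),
  and forcing the fit through the origin would leak that shift into the
  coefficients. `fit_lasso_path(..., intercept = FALSE)` restores the
  strict form.
* **Internal standardisation.** Features are standardised (zero mean, unit
  1/n-variance) inside the solver so a count-scaled TF column and a
  beta-scaled methylation column feel the same penalty; coefficients are
  reported back on the original scale.

## Identifying Yin and Yang genes

Differential expression between tumors and normals uses a per-gene Welch
t-test on the log2 scale with Benjamini-Hochberg adjustment across all
tested genes. A moderated-variance test would differ slightly at small
sample sizes; the Welch test was chosen as a dependency-free, well-calibrated
default (its size is verified on null simulations in the test suite). Yin
genes satisfy FDR < 0.05 and logFC ≥ 1, Yang genes FDR < 0.05 and
logFC ≤ −1 — both fold-change boundaries inclusive, the FDR boundary
strict. Genes with fewer than two observations in either group are
untestable and reported as such. The per-tumor response uses the mean over
all normal samples as the reference; normals in TCGA-style cohorts are not
matched one-to-one to tumors, so a population reference is the only option
that exists for every tumor.

## Fitting: coordinate descent, penalty grid, cross-validation

The lasso is solved by pathwise coordinate descent (in C++) over a
decreasing penalty grid with warm starts: 100 log-spaced values from
λ_max — the smallest penalty at which every coefficient is zero — down four
decades. Convergence is declared when the largest coefficient update in a
sweep falls below 10⁻⁹ (10⁻⁷ inside permutation refits); solutions are
verified against the Karush-Kuhn-Tucker conditions and against an
independent implementation (glmnet) in the test suite. Constant columns
are frozen at zero rather than producing 0/0 standardisation artifacts.

The per-tumor penalty is chosen by 10-fold cross-validation over genes —
fold membership from a seeded shuffle of gene indices — at the CV-minimum
rule. The one-standard-error rule would give sparser models; the minimum
rule is the better choice here because the downstream leave-regulator-out
score already separates signal from borderline coefficients, and
over-shrinking at fitting time costs recall.

A miRNA enters a tumor's design only when its own tumor-vs-normal fold
change is measured and exceeds the admission threshold in magnitude
(default 0: any nonzero fold change). The threshold is exposed
(`mirna_threshold`) because no canonical cutoff exists; the default admits
everything measurable and lets the penalty do the filtering.

## Scoring regulators and the permutation null

For subtype *S*, regulator *r*'s score is the increase in total squared
loss over all of the subtype's tumors and all modelled genes when `W_r` is
set to zero in every model — predictions change, nothing is refitted. A
regulator never selected by any model of the subtype scores exactly zero;
a selected one scores positively (zeroing an active coefficient of an
optimal fit cannot reduce training loss).

The null distribution permutes each binding column over genes
independently — preserving every regulator's count distribution while
destroying gene associations — then retrains every tumor's model on the
permuted design and recomputes every score. One randomization permutes
*all* columns jointly and yields a null draw for every regulator at the
cost of one retrain, rather than one retrain per regulator. Two details:

* **Penalty reuse.** By default each tumor's observed λ is reused in the
  permutation refits (`retune_lambda = FALSE`). Column permutation leaves
  every column's mean and variance — the statistics the penalty scale
  responds to — unchanged, so re-tuning mostly reproduces the same λ at
  ten times the cost. `retune_lambda = TRUE` re-runs the full CV per
  permutation for users who want the strictly identical procedure.
* **Reproducibility contract.** Each permutation draws from its own
  pre-derived seed substream, so results are identical for any
  `n_workers`.

Empirical p-values use the standard pseudocount form
`(1 + #{null ≥ observed}) / (1 + n_permutations)`, which cannot return
zero; BH adjustment is applied within each subtype across the combined
TF+miRNA list, and FDR < 0.05 selects the key regulators. With 200
permutations the smallest attainable p is 1/201 ≈ 0.005 — adequate for
testing and for cohorts of tens of regulators; full-scale analyses should
use 5000 permutations. Selected regulators are cross-classified by the
exact combination of subtypes selecting them (common → subtype-specific).

## Enrichment, network, signatures

Target enrichment uses the upper-tail hypergeometric probability with BH
adjustment. The universe defaults to the union of the collection's gene
sets — the convention of the widely used over-representation tools — and is
overridable. Pathway collections are tested at set sizes 2–500,
GO-biological-process collections at 10–500; the pathway analysis uses
FDR < 0.01, the GO analysis FDR < 0.05 (both exposed as arguments). The
network table keeps (regulator, Yin/Yang target, hit-count) triples with
nonzero hits whose target lies in at least one chosen pathway, ordered
deterministically, and exports to TSV or SIF.

The YMR signature is the per-patient ratio of mean Yin to mean Yang
expression, stratified at the mean score; the CRS is the per-patient sum of
expression times univariate Cox log-hazard-ratio coefficients, stratified
at the 65th-percentile cutoff. "Above the cutoff" is interpreted strictly
(ties go to the low-risk group) for both cutoffs, uniformly. The quantile
uses the linear-interpolation convention (type 7) — the named helper the
cutoff imitates does not pin down a convention, so the R default is used
and the `type` argument exposed. Cox models handle ties by Breslow's
method (the simplest standard choice; the synthetic survival times are
continuous, so ties are measure-zero anyway), and group separation is
assessed by Kaplan-Meier curves and the two-group log-rank test.
Fixed-horizon analyses (e.g. five-year survival) are implemented by
administrative censoring at the horizon (`censor_at_horizon`,
`evaluate_signature(..., horizon = 5)`). Cox fitting, the product-limit
estimator and the log-rank statistic are delegated to the `survival`
package; the test suite re-derives them by hand (grid-searched partial
likelihood, explicit risk-set bookkeeping, permutation nulls) to pin the
wrappers down.

## The synthetic cohort generator

`generate_dataset()` emulates the statistical shape of a multi-platform
breast-cancer cohort:

| knob | default | what it emulates |
|---|---|---|
| `n_tumors_per_subtype` | 25 | four-subtype cohort (100 tumors) |
| `n_normals` | 30 | adjacent-normal expression panel |
| `n_genes`, `n_tfs`, `n_mirnas` | 300 / 20 / 30 | desk-scale gene and regulator sets |
| `binding_density`, `max_binding_count` | 0.1 / 5 | sparse nonnegative motif-hit matrices: Bernoulli(0.1) × (1 + Poisson(1)), truncated |
| `n_active_per_subtype`, `effect_size` | 5 / 1.0 | planted regulatory program per subtype, random coefficient signs |
| `noise_sd` | 0.5 | Gaussian noise on the fold-change response |
| `n_yin`, `n_yang`, `de_effect` | 25 / 25 / 2.5 | planted differential-expression offsets (log2) |
| `cnv_weight_mean/sd` | 0.6 / 0.1 | per-tumor copy-number dosage effect |
| `dm_weight_mean/sd` | −2 / 0.2 | per-tumor methylation silencing effect |
| `censor_rate` | 0.3 | independent censoring fraction |

Methylation is Beta(2, 2), copy number categorical on {−2…2} centred at 0.
Each tumor's response is the linear predictor under its subtype's planted
coefficients plus noise; the methylation contribution is centred
(beta − ½) so that the planted Yin/Yang offsets, not a global methylation
shift, determine each gene's mean fold change (the per-tumor intercept
absorbs the constant either way). Planted-active miRNAs are guaranteed a
fold-change magnitude ≥ 0.5 in their subtype so the admission rule cannot
silently drop planted signal. Normal-sample noise is centred per gene,
which makes `tumor_fold_changes()` reproduce the generative response
exactly — the property the noiseless-identity and parameter-recovery tests
rely on. Survival times are exponential with rate
`hazard_scale · exp(score)` and censoring calibrated per patient to the
requested fraction.

What the generator does **not** emulate: copy-number segmentation and
arm-level correlation, probe-level methylation structure, read-count noise,
batch effects, correlated binding profiles between related regulators, and
matched tumor-normal pairs. Passing tests on this generator therefore
demonstrate that the machinery is correct and powerful under the stated
generative model — not that real cohorts satisfy that model.

## Problem sizes and seeds used by the test suite

The packaged tests run the full selection pipeline at the default study
conditions (4 × 25 tumors, 300 genes, 50 regulators, 200 permutations):
planted-regulator recovery averaged over 5 seeded cohorts, type-I control
averaged over 20 seeded null cohorts, the feature-ladder comparison
(miRNA → +TF → +CNV → +DM against a randomized-response baseline), and
40 seeded survival replicates at 200 patients for the YMR power check.
Oracle checks (soft-threshold closed form, KKT, naive score recomputation,
hypergeometric tail summation, BH step-up, KM/log-rank hand computation,
signed-rank enumeration) run at small sizes where brute force is exact.
All seeds are fixed in the test files; a single master seed fans out to
per-stage substreams via pre-derived integer seeds.

## Known limitations

* Binding matrices are static: one count matrix serves every tumor, so
  sample-specific chromatin context is invisible to the model.
* The leave-one-out score is computed without refitting; correlated
  regulators can share credit, and zeroing one of a correlated pair
  understates its joint contribution.
* Empirical p-value resolution is bounded by the permutation count;
  selection near the FDR boundary is unstable below ~200 permutations.
* The Welch-test DE stage will diverge from moderated-variance approaches
  for very small normal panels.
* `xtile`-style cutoff selection here is a fixed quantile, not an optimised
  cutpoint search; an optimised search would require multiplicity
  correction that a fixed quantile avoids.
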