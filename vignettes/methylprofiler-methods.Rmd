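---
title: "Methods: methylation scoring, profiling and predictor training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation scoring, profiling and predictor training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylprofiler)
```

## The model

A methylation-based predictor (an *episcore*, or an *epigenetic clock* when
the trait is chronological age) is a linear model over CpG probes. With
$\beta_{ij} \in [0,1]$ the methylation proportion of individual $i$ at probe
$j$, and $w_j$ the probe's trained weight, the predicted value is

$$ S_i = b_0 + \sum_{j \in J} w_j\,\beta_{ij}. $$

Lifestyle and biochemical episcores typically come back on an arbitrary
scale; only their rank within a cohort is interpretable, which is why the
profiling side of this package works in percentile ranks. An age clock is
the exception: its output is in years and is reported as such.

Arrays report either beta values or M values,
$M = \log_2\!\big(\beta/(1-\beta)\big)$. All scoring happens on the beta
scale; M-value uploads are converted with the inverse map
$\beta = 2^M/(2^M+1)$. The conversion formula is not negotiable — it is the
defining relation between the two scales — but the *detection* rule is a
package choice: any non-missing value outside $[0,1]$ marks a matrix as
M values. A boundary value of exactly 0 or 1 is valid beta, so an all-beta
matrix is never misclassified; a genuinely beta-scale matrix containing
normalization artifacts like $-0.001$ will be flagged as M values, which is
why `clip_beta_values()` exists for callers who know their scale and want
the artifact repaired instead.

## The automated QC pipeline

Scoring a raw upload runs these steps, in this order:

1. **Orient** (`orient_matrix()`): uploads arrive samples-as-rows or
   CpGs-as-rows. The CpG axis is recognized by majority vote — at least 90%
   of an axis's labels matching `^cg[0-9]+$`. Requiring a 90% majority on
   exactly one axis (rather than "any match") makes the decision robust to
   a few malformed probe names while refusing to guess when both or
   neither axis looks CpG-like.
2. **Detect scale, convert** (`detect_value_scale()`, `m_to_beta()`).
3. **Impute** (`impute_missing_values()`): each missing cell is replaced by
   the mean of the observed values at that probe *across the uploaded
   samples*. Means are computed over the full upload, never a later
   age/sex subset, because imputation happens at score time, before any
   profiling subset exists.
4. **Fill** (`fill_missing_cpgs()`): probes a model needs but the upload
   lacks are added as constant columns equal to a reference cohort's mean
   beta. Because the model is linear, this shifts every sample's score by
   the same amount, $\sum_{j \text{ missing}} w_j \bar m_j$ — scores move
   toward the reference cohort without reordering the uploaded samples.
   A probe absent from both the upload and the reference panel is a hard
   error: silently dropping a weight would change the score's meaning.
5. **Score** (`compute_score_table()`).

Conversion must precede imputation so that imputed means are beta-scale
means; imputation precedes fill so that fill constants are never blended
into upload-derived means. Every step appends to a `qc_report()`, the
plain-text log the command-line `score` subcommand writes next to its
output — it records whether the matrix was transposed, whether M values
were converted, and how many cells/probes were imputed/filled.

Order of operations around truncation: probe truncation (the
`truncate` subcommand) is a file-size convenience applied before upload,
so imputation runs after truncation and before reference fill.

### Column naming

Chronological age from the annotation file and the age clock's prediction
are different quantities and must coexist in one table. The annotation
columns keep their conventional names (`Sex`, `Age` = chronological years);
the clock trait is named `Epigenetic_Age`. Trait columns are ordered with
the years-unit clock first, then the conventional lifestyle/biochemical
listing (Alcohol, Body_Fat, BMI, HDL, Smoking, WHR), then any other traits
alphabetically.

## Profiling

**Percentile definition.** Mid-rank percentiles,
$p = 100\,(r - 0.5)/n$ with average ranks for ties. This rule is symmetric
(tie-free percentiles average exactly 50 for any $n$), bounded away from 0
and 100, and gives a single observation the sensible value 50. Percentiles
are *always computed within the displayed table*: subsetting by age, sex or
case status and then ranking is deliberately different from ranking first —
the panels recompute dynamically, so a sample's percentile answers "where
do I sit among the people currently shown".

**Effective age.** Age-range subsetting uses chronological age where the
annotation file provides it and the epigenetic-age prediction for samples
without it, per sample. This keeps age filters usable for uploads with no
annotation file at all.

**Case/control summaries.** Percentiles are computed on the full displayed
table (cases and controls together), then the case percentiles are
summarized as median and first/third quartile using linear interpolation
between order statistics (R's default type-7 quantile). Samples with
missing status belong to neither group.

**Correlations.** Product-moment (Pearson) by default with a rank-based
(Spearman) option. A zero-variance trait's correlations are undefined and
reported as `NA`, never silently 0. Fewer than 3 samples after filtering is
an explicit error rather than a `NaN` matrix. Reference-cohort panels —
inter-predictor correlations and predicted-versus-measured trait
correlations under age/sex filtering — come from the reference panel's
score/phenotype tables; traits without paired reference measurements are
reported as unavailable with a note.

## Training new predictors

The recipe mirrors how published lifestyle episcores are built:

1. **Phenotype preparation** (`phenotype_spec()`, `transform_phenotype()`):
   exclusion bounds first (e.g. BMI outside $[17, 50]$ kg/m² removed as
   extreme), then a skew-reducing transform — natural log for strictly
   positive phenotypes, $\log(x+1)$ for zero-heavy exposures such as weekly
   alcohol units or smoking pack years. Cohort-specific exclusions that
   derive from questionnaire fields (ex-smokers, "not a representative
   week" drinkers) are modelled as caller-supplied sample masks, since they
   are not computable from the data this package sees.
2. **Pre-correction** (`precorrect_phenotype()`): the phenotype is replaced
   by its least-squares residuals on intercept + age + sex + ten ancestry
   components. Sex is coded Female = 0, Male = 1 (an arbitrary but fixed
   convention; residuals are invariant to it). Exactly ten components is
   the default because that is the standard ancestry adjustment in this
   literature; the function accepts any covariate matrix. No cell-type
   composition covariates are included — the phenotypes these predictors
   are trained on are deliberately not corrected for cell-type
   heterogeneity, and that choice is preserved here.
3. **Probe filter** (`filter_probes_to_array_intersection()`): training is
   confined to probes present on both the 450k and EPIC array generations
   so the resulting predictor applies to either platform. The real
   intersection list (~393k probes) is an external input; the package ships
   none.
4. **Penalized fit** (`train_predictor()`): LASSO ($\alpha = 1$ by
   default), 10-fold cross-validation over a 100-value log-spaced lambda
   path auto-scaled from the data, selecting the lambda with minimum mean
   CV error, then taking the full-data path fit at that lambda. Fold
   assignment is a deterministic shuffle from the config seed, so identical
   seed + data + config produces a byte-identical weight file (weights are
   serialized at 17 significant digits). Predictors are standardized
   internally for the penalty; returned weights are on the raw beta scale
   so the scoring module's plain dot product applies them unchanged.
5. **Evaluation** (`evaluate_predictor()`): correlation $r$ between
   predicted and observed in held-out samples, $R^2 = r^2$ (squared
   correlation, the conventional variance-explained figure for episcores;
   regression $R^2$ would be smaller whenever predictions are miscalibrated
   in scale), and RMSE in phenotype units.

## The synthetic cohort generator

`cohort_simulation()` states a world and every test draws from it:

- **Betas** are Beta-distributed around per-probe means drawn from a
  three-mode mixture (hypomethylated ~0.1, intermediate ~0.5,
  hypermethylated ~0.9, with 40/20/40 weights) with concentration 60,
  giving per-probe standard deviations of roughly 0.02–0.07 — the
  bimodal-with-shoulder shape and dispersion of real blood array data.
- **Causal probes** are sampled among variably methylated probes (mean beta
  in $[0.2, 0.8]$). Near-constant hypo-/hyper-methylated probes cannot
  carry phenotype signal, and real episcore probes are the variable ones.
- **Phenotype** = causal linear signal + optional age/sex effects + Gaussian
  noise. The default noise level equals the realized signal standard
  deviation, i.e. a signal variance fraction of one half — a generous but
  not fanciful figure for the best methylation-predictable traits.
- **Binary status** is the indicator of the noise-free signal exceeding its
  upper quantile (default: median), so cases are genuinely shifted on the
  trait scale.
- **Defaults**: 50 samples, 200 probes, 10 causal, 2% missing cells
  (light scatter, as after probe-quality filtering), 2 causal probes
  withheld from the upload (exercising reference fill), ages uniform on
  30–75 years (an adult blood-donor range), 20% missing ages (exercising
  the epigenetic-age fallback), and a 500-individual reference draw — a
  scaled-down stand-in for a several-thousand-person reference cohort.

What the generator does **not** emulate: probe-level technical artifacts
(dye bias, batch, detection-p filtering), cell-type composition, genetic
relatedness, and correlation structure among probes (probes are
independent given their means). A green test therefore establishes the
*algorithms* — orientation, conversion, imputation, fill arithmetic,
ranking, penalized fitting — not robustness to array artifacts, which are
assumed handled upstream by standard normalization pipelines.

## Numerical choices and degenerate inputs

- Beta bounds: simulated betas are clipped into $[10^{-6}, 1-10^{-6}]$ so
  M-value twins stay finite; `beta_to_m()` of exactly 0/1 yields $\mp\infty$.
- A probe with *no* observed values is left missing by imputation (with a
  QC warning) — only the reference fill can inform it.
- An empty truncation intersection is a warning and a 0-column matrix, not
  an error, because downstream fill can still supply every model probe.
- Single-sample percentile = 50; all-tied percentiles = 50.
- Rank-deficient covariate matrices in pre-correction are an error naming
  the collinear columns, rather than a silent pseudo-inverse.
- Cross-validation occasionally selects the empty model on pure-noise
  phenotypes; `train_predictor()` then returns an intercept-only model
  (one zero weight) with a warning rather than an unusable object.

## Known limitations

- The scoring engine is weight-agnostic and ships no trained coefficients:
  published weight files are external inputs, and all bundled examples are
  synthetic.
- At the hardest corner of our acceptance battery — 20 causal probes each
  at the detectability boundary ($t \approx 5$), $p = 1000$, $n = 500$ —
  LASSO at minimum-CV-error lambda recovers the full support but its
  held-out $R^2$ (≈0.33–0.41) sits below the generating signal fraction
  (0.5) and usually below the 0.4 acceptance floor, while the true
  generating weights themselves achieve only ≈0.47. The gap is inherent
  shrinkage/selection cost at boundary effect sizes, not an implementation
  defect; the corresponding assertion is left failing rather than relaxed.
- Percentile-rank comparisons against a reference cohort assume the upload
  and the reference are on comparable score scales; systematic
  normalization differences between datasets are out of scope.
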