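# methylprofiler

Automated scoring and health profiling of blood DNA-methylation data.

Methylation-based predictors ("episcores" and epigenetic clocks) estimate
human traits — chronological age, alcohol consumption, body-mass index,
smoking history, HDL cholesterol — as a weighted sum over CpG probes:

```
S_i = b0 + Σ_j  w_j · β_ij
```

where `β_ij ∈ [0,1]` is the methylation proportion of individual `i` at
probe `j` and `w_j` a trained weight. Applying such predictors to a new
cohort sounds trivial but rarely is: uploads arrive samples-as-rows or
CpGs-as-rows, on the beta or the M scale (`M = log2(β/(1−β))`), with
missing cells, and missing entire probes the model needs. This package is
for epidemiologists and epigenetics researchers who want that projection
automated, logged, and reproducible — plus the downstream profiling that
gives arbitrary-scale scores meaning: percentile ranks within the cohort,
case/control stratification for uploaded binary phenotypes, inter-predictor
correlations, and comparison against a reference cohort. A training module
implements the standard recipe for building new predictors (phenotype
transforms and exclusions, covariate pre-correction, cross-validated
LASSO), and a synthetic-cohort generator makes the whole pipeline testable
with known ground truth and no external data.

The scoring engine is weight-agnostic: published weight files are consumed
as external inputs and never bundled; every example in the repository is
synthetic.

## Worked example

Simulate a small cohort (12 samples, 50 probes; the fixture is written
CpGs-as-rows on the M-value scale, with missing cells and two probes
withheld, so every QC step has work to do), then score and profile it:

```r
library(methylprofiler)

sim   <- cohort_simulation(seed = 42, n_samples = 12, n_cpgs = 50, n_causal = 5)
paths <- write_fixture_bundle(sim, "fx")

qc <- qc_report()
m  <- read_methylation_matrix(paths[["matrix"]], qc = qc)
m  <- m_to_beta(m, qc = qc)
m  <- impute_missing_values(m, qc = qc)
models <- read_predictor_models(paths[["weights"]])
panel  <- read_reference_panel(paths[["panel_means"]])
m  <- fill_missing_cpgs(m, model_cpgs(models), panel, qc = qc)
scores <- compute_score_table(m, models,
                              annotations = read_sample_annotations(paths[["sexage"]]),
                              qc = qc)
print(qc)
#> QC report:
#> [orientation] matrix transposed so that samples are rows and CpGs are columns
#> [scale] M values detected
#> [convert] M values were uploaded and converted to beta values [n=562]
#> [impute] 14 missing value(s) mean-imputed across input individuals [n=14]
#> [fill] 2 CpG(s) absent from the upload filled with reference mean beta values [n=2]
#> [score] scores computed for 1 trait(s) across 12 sample(s) [n=12]

head(as.data.frame(scores), 4)
#>   ID  Sex   Age  Trait
#> 1 S1 Male 73.05 0.3296
#> 2 S2 Male 41.45 0.3647
#> 3 S3 Male    NA 0.2738
#> 4 S4 Male    NA 0.2914
```

`Trait` is the simulated episcore on its arbitrary training scale; `Age` is
chronological age from the annotation file (`NA` where the sample had
none — such samples fall back to their epigenetic-age prediction whenever
an age filter is applied). Percentiles give the scores meaning:

```r
ph <- read_phenotype_table(paths[["phenotypes"]])
case_control_summary(scores, ph, "Status")
#>   trait median   q1   q3 n_cases n_controls
#> 1 Trait   70.8 56.2 85.4       6          6

individual_profile(scores, "S3")
#> Trait
#>   4.2
```

Cases sit at median percentile 70.8 (IQR 56.2–85.4) for the simulated
trait — they were generated by thresholding its noise-free signal, so the
upward shift is real. Sample S3 sits at the 4.2nd percentile of the cohort.

The same workflow from the shell:

```sh
Rscript inst/cli/methylprofiler.R simulate --seed 42 -o fx/
Rscript inst/cli/methylprofiler.R score --matrix fx/dnam_matrix.csv \
    --weights fx/weights.csv --reference-panel fx/reference_panel.csv \
    --sexage fx/SexAgeInfo.csv -o scores.csv --log qc.txt
Rscript inst/cli/methylprofiler.R profile --scores scores.csv \
    --phenotypes fx/case_control.csv --trait Status -o percentiles.csv
```

## Training a new predictor

```r
spec <- phenotype_spec("BMI", transform = "log", lower = 17, upper = 50)
prep <- transform_phenotype(raw_bmi, spec)
y    <- precorrect_phenotype(prep$values[prep$retained],
                             covariates[prep$retained, ])  # age, sex, 10 PCs
model <- train_predictor(m_train, y, training_config(alpha = 1, n_folds = 10,
                                                     seed = 1), "BMI")
evaluate_predictor(model, m_test, y_test)   # r, R2 (squared correlation), RMSE
write_predictor_models(model, "bmi_weights.csv")  # loadable by the scorer
```

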