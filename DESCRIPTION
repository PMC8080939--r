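Package: methylprofiler
Title: Automated Scoring and Health Profiling of Blood DNA Methylation Data
Version: 0.1.0
Authors@R:
    person("Methylprofiler", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated quality control and linear scoring of blood
    DNA-methylation matrices against CpG weight sets (episcores and epigenetic
    clocks), percentile-rank health profiling with case/control stratification
    and reference-cohort comparison, and a LASSO recipe for training new
    methylation-based trait predictors. Uploaded matrices are tolerantly
    oriented, M values are converted to beta values, missing probe values are
    mean-imputed across samples, and probes absent from an upload are filled
    with reference-cohort mean beta values so that every weight in a predictor
    is always used. A synthetic-cohort generator produces every input the
    pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
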