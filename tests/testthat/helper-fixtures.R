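# Shared fixture builders. Everything is generated in code; no files on
# disk beyond tempfiles created per test.

# A random beta-scale methyl_matrix with reproducible contents.
random_beta_matrix <- function(n = 4, p = 6, seed = 1, prefix = "S") {
  withr::with_seed(seed, {
    values <- matrix(stats::runif(n * p, 0.02, 0.98), n, p,
                     dimnames = list(paste0(prefix, seq_len(n)),
                                     sprintf("cg%07d", seq_len(p))))
    methyl_matrix(values, scale = "beta")
  })
}

# Write a labelled numeric grid as CSV with base R only, independently of
# the package's writers: oracle input for the readers.
write_grid_csv <- function(values, path) {
  df <- data.frame(ID = rownames(values), values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

# A small score table built directly (not via scoring), for profiling
# tests where scores are arbitrary numbers.
make_score_table <- function(scores, ids = paste0("S", seq_along(scores[[1]])),
                             sex = NULL, age = NULL,
                             years_traits = character()) {
  df <- data.frame(ID = ids, stringsAsFactors = FALSE)
  if (!is.null(sex)) df$Sex <- sex
  if (!is.null(age)) df$Age <- age
  for (tr in names(scores)) df[[tr]] <- scores[[tr]]
  score_table(df, traits = names(scores), years_traits = years_traits)
}
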