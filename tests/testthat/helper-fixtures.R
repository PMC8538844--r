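# Small fixture builders shared by the test files. All data is generated in
# code; nothing is read from disk except files the tests write themselves.

toy_expression <- function(n_genes = 6, n_samples = 4, seed = 42,
                           cohorts = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (is.null(cohorts)) cohorts <- rep("A", n_samples)
  expression_matrix(m, setNames(cohorts, colnames(m)))
}

write_toy_clinical <- function(path, n = 4) {
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   os_time = c(120, 300, 45, 500)[seq_len(n)],
                   os_event = c(1, 0, 1, 0)[seq_len(n)],
                   stage = c("III", "II", "IV", "I")[seq_len(n)],
                   cohort = "ACC")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

# deterministic labeled-sample fixture for group comparisons
two_group_labels <- function(nA, nB, labelA = "ALT", labelB = "NDTMM") {
  data.frame(
    sample_id = sprintf("S%04d", seq_len(nA + nB)),
    label = c(rep(labelA, nA), rep(labelB, nB)),
    z_tel = 0, z_alt = 0, cohort = "X",
    stringsAsFactors = FALSE)
}
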