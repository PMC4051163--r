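# Small in-code fixtures shared across test files.

# expression matrix where every sample is its own condition (the layout the
# network code ranks over)
rand_expression <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    v <- matrix(exp(rnorm(n_genes * n_samples, log(500), 0.5)),
                n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    expression_matrix(
      v, setNames(sprintf("c%03d", seq_len(n_samples)), colnames(v)))
  })
}

# replicate summary built directly from per-condition means (n = 1 each)
summary_from_means <- function(means, A = 0) {
  v <- means
  colnames(v) <- paste0(colnames(means), "_r1")
  x <- expression_matrix(
    v, setNames(colnames(means), colnames(v)), average_signal_A = A)
  summarize_replicates(x)
}

rna_complement_of <- function(s) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  paste(rev(unname(comp[strsplit(chartr("T", "U", toupper(s)), "")[[1]]])),
        collapse = "")
}
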