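# Small in-code fixtures shared across test files.

# tiny abundance table: features x samples, optionally normalized
tiny_table <- function(m, features = NULL, samples = NULL, type = "other") {
  features <- features %||% rownames(m) %||% sprintf("f%02d", seq_len(nrow(m)))
  samples <- samples %||% colnames(m) %||% sprintf("smp%02d", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  abundance_table(m, type = type)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# metadata for a vector of (subject, week, diagnosis) triples
tiny_metadata <- function(subject, week, diagnosis, sample_id = NULL, ...) {
  data.frame(sample_id = sample_id %||% sprintf("%s_w%02d", subject, week),
             subject_id = subject, week = week, diagnosis = diagnosis,
             ..., stringsAsFactors = FALSE)
}

# brute-force Bray-Curtis double loop (independent oracle)
bc_brute <- function(mat) {
  n <- ncol(mat)
  D <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(abs(mat[, i] - mat[, j])) / sum(mat[, i] + mat[, j])
    }
  }
  D
}

# a small quick cohort configuration for pipeline-level tests
quick_config <- function(...) {
  cohort_config(n_subjects_per_group = c(nonIBD = 12, UC = 6, CD = 6),
                n_taxa = 60, seed = 101, ...)
}
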