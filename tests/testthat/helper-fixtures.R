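# Small in-code fixtures shared across test files.

# genes-by-samples matrix with ids
toy_matrix <- function(values, n_genes = NULL) {
  m <- if (is.matrix(values)) values else
    matrix(values, nrow = n_genes %||% length(values))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_metadata <- function(groups, survival = NULL) {
  data.frame(sample_id = sprintf("s%02d", seq_along(groups)),
             group = groups,
             survival_days = survival %||% NA_real_,
             stringsAsFactors = FALSE)
}

# random strictly-positive vectors for distance property tests
rand_pos <- function(n) exp(stats::rnorm(n))
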