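# Shared fixture builders (all generated in code; no stored data files).

random_sequence <- function(L, seed = NULL) {
  draw <- function() paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# write a toy PSSM file with the given integer score matrix
write_toy_pssm_file <- function(scores, path = tempfile(fileext = ".pssm"),
                                residues = NULL) {
  p <- new_pssm(scores, residues = residues, protein_id = "toy")
  write_pssm(p, path)
  path
}

# a small 4-class feature tibble with gaussian class-shifted features
make_blob_data <- function(n_per_class = 5, n_features = 6, shift = 3, seed = 1) {
  withr::with_seed(seed, {
    cls <- rep(structural_classes(), each = n_per_class)
    n <- length(cls)
    x <- matrix(rnorm(n * n_features), n, n_features)
    # shift each class along its own axis (features 1..4)
    for (k in 1:4) {
      x[cls == structural_classes()[k], min(k, n_features)] <-
        x[cls == structural_classes()[k], min(k, n_features)] + shift
    }
    colnames(x) <- paste0("feat_", seq_len(n_features))
    dplyr::bind_cols(
      tibble::tibble(protein_id = sprintf("B%03d", seq_len(n)),
                     class = factor(cls, levels = structural_classes())),
      tibble::as_tibble(x)
    )
  })
}

# direct Toeplitz normal-equation solve: the LPC oracle
lpc_direct_solve <- function(signal, p) {
  r <- autocorr_sequence(signal, p)
  if (r[[1]] == 0) return(numeric(p))
  solve(stats::toeplitz(r[seq_len(p)]), r[2:(p + 1)])
}
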