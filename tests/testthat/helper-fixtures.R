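# Shared fixtures, generated in code (no stored data files).

# A 12-nt barcode set with min pairwise distance >= 4, built once per file.
fix_barcode_set <- function(k = 20, seed = 101) {
  pool <- random_barcodes(6 * k, 12, seed = seed)
  select_barcodes(pool, k = k, d_min = 4, seed = seed)
}

fix_sheet <- function(scheme, n, k = 24, seed = 7) {
  assign_samples(scheme, sprintf("S%02d", seq_len(n)),
                 fix_barcode_set(k, seed = 101), seed = seed)
}

# Small mock reference with controllable variant count / abundances.
fix_mock <- function(n_var = 6, len = 80, seed = 5) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_var), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  ab <- 2^(-(seq_len(n_var)))
  mock_reference(data.frame(
    variant_id = sprintf("v%02d", seq_len(n_var)),
    species = sprintf("sp%02d", ceiling(seq_len(n_var) / 2)),
    seq = seqs, abundance = ab / sum(ab)), normalize = TRUE)
}

# Substitute n random positions of a string (ambient RNG).
mutate_string <- function(s, n, region = seq_len(nchar(s))) {
  chars <- strsplit(s, "")[[1]]
  for (p in sample(region, n)) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}
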