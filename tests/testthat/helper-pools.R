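# shared fixtures, built in code

uniform_probs <- alphabet_probs(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))

# random string over the nucleobase alphabet
rand_string <- function(l) {
  paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
}

# random probability vector on the 4-simplex, bounded away from 0
rand_probs <- function(min_p = 0.02) {
  x <- runif(4, min = min_p)
  alphabet_probs(x / sum(x))
}

# small planted-motif pool for search/clustering tests
small_planted_pool <- function(seed, n_reads = 2000, motif = "TATGGACTTC",
                               prevalence = 0.3, nominal_length = 25) {
  generate_pool(synthetic_pool_spec(
    n_reads = n_reads, nominal_length = nominal_length,
    off_length_fraction = 0.2, base_probs = c(A = 0.3, C = 0.2,
                                              G = 0.3, T = 0.2),
    motifs = list(list(string = motif, prevalence = prevalence)),
    seed = seed))
}

# write a FASTA file from raw records (no dereplication) for IO tests
write_raw_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">r", seq_along(seqs), "\n", seqs), path)
  path
}
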