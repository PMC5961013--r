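# Shared fixtures, built in code.

linear_design <- function(k = 3) {
  library_design(paste0("L", k), n_random_codons = k)
}

constrained_design <- function(k = 10) {
  library_design(paste0("C", k, "C"), n_random_codons = k, constrained = TRUE)
}

# Assemble a full-layout read around an insert.
make_read <- function(insert, design) {
  paste0(design$upstream_flank, insert, design$downstream_flank)
}

# Substitute the base at 1-based position p with a different one.
mutate_at <- function(read, p) {
  b <- substr(read, p, p)
  substr(read, p, p) <- if (b == "A") "C" else "A"
  read
}

# Independent translation oracle via Biostrings (no amber handling).
oracle_translate <- function(seqs) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                     no.init.codon = TRUE))
}

# Enumerate all NNK inserts of n codons (32^n sequences).
enumerate_nnk_inserts <- function(n) {
  codons <- nnk_codons()
  out <- codons
  for (i in seq_len(n - 1)) {
    out <- as.vector(outer(out, codons, paste0))
  }
  out
}
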