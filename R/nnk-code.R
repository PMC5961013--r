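# NNK genetic-code machinery. NNK = any base (N) at codon positions 1-2 and
# G or T (K) at position 3: 32 codons covering all 20 amino acids. TAG
# (amber) is the single stop codon reachable by NNK -- TAA and TGA both end
# in A and are excluded by construction. They can still enter a library
# through synthesis or sequencing artifacts, so stop classification and
# fitness handle them defensively.

NNK_N_BASES <- c("A", "C", "G", "T")
NNK_K_BASES <- c("G", "T")

#' The 32 NNK codons
#'
#' Enumerates every codon of the degenerate NNK scheme (third base G or T),
#' in lexicographic order.
#'
#' @return Character vector of 32 DNA codons.
#' @examples
#' length(nnk_codons())  # 32
#' @export
nnk_codons <- function() {
  g <- expand.grid(b3 = NNK_K_BASES, b2 = NNK_N_BASES, b1 = NNK_N_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

# Translate DNA codons with the standard code; optionally read amber (TAG)
# through as glutamine, the supE44 phenotype.
.translate_codons <- function(codons, amber_as_q = TRUE) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  if (amber_as_q) aa[codons == "TAG"] <- "Q"
  aa
}

# Residue classes used by the normalized amino-acid distribution: the 20
# amino acids plus the amber-derived glutamine as its own class "q" (the
# "additional glutamine" arising from UAG suppression); TGA maps to "*".
.nnk_class_of_codon <- function(codons) {
  cls <- unname(Biostrings::GENETIC_CODE[codons])
  cls[codons == "TAG"] <- "q"
  cls
}

#' NNK codon degeneracy per residue
#'
#' Counts how many of the 32 NNK codons encode each residue, under one of two
#' conventions for the amber codon: `amber_as_q` translates TAG as glutamine
#' (the supE44 suppression phenotype), so glutamine has degeneracy 2
#' (CAG + TAG) and no stop remains; `amber_as_stop` keeps TAG as a stop,
#' giving 20 amino-acid classes plus one stop codon. TAG is the only stop
#' reachable by NNK: TAA and TGA end in A.
#'
#' @param variant `"amber_as_q"` or `"amber_as_stop"`.
#' @return Named integer vector of codon counts per residue (one-letter
#'   codes, `"*"` for stop), summing to 32.
#' @examples
#' nnk_degeneracy_table("amber_as_q")[["Q"]]     # 2
#' nnk_degeneracy_table("amber_as_stop")[["*"]]  # 1
#' @export
nnk_degeneracy_table <- function(variant = c("amber_as_q", "amber_as_stop")) {
  variant <- match.arg(variant)
  aa <- .translate_codons(nnk_codons(), amber_as_q = variant == "amber_as_q")
  tab <- table(aa)
  out <- as.integer(tab)
  names(out) <- names(tab)
  # put the stop class last for readability
  ord <- c(setdiff(names(out), "*"), intersect("*", names(out)))
  out[ord]
}

# Degeneracy over the 21 normalization classes (20 AA + amber-Gln "q").
# Each class count is the number of NNK codons mapping to it; the counts
# sum to 32 (every NNK codon codes under amber suppression).
.nnk_class_degeneracy <- function() {
  cls <- .nnk_class_of_codon(nnk_codons())
  tab <- table(cls[cls != "*"])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Split equal-length sequences into a (n x k) codon matrix.
.codon_matrix <- function(x) {
  L <- unique(nchar(x))
  if (length(L) != 1L || L %% 3L != 0L) {
    stop("sequences must share a length divisible by 3")
  }
  k <- L %/% 3L
  starts <- 3L * seq_len(k) - 2L
  m <- vapply(starts, function(s) substr(x, s, s + 2L), character(length(x)))
  matrix(m, nrow = length(x), ncol = k)
}

# For each sequence, does any codon belong to `codons`? Vectorized over
# equal-length inserts; used for stop classification and fitness.
.has_any_codon <- function(x, codons) {
  if (length(x) == 0L) return(logical(0))
  cm <- .codon_matrix(x)
  hit <- matrix(cm %in% codons, nrow = nrow(cm))
  rowSums(hit) > 0L
}
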