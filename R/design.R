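# Library designs: the amplicon layout of one NNK peptide library.
# Reads have the fixed forward layout
#   upstream_flank (containing the barcode) + [cys] + insert + [cys] + downstream_flank
# where the insert is n_random_codons NNK codons, optionally flanked by fixed
# cysteine codons for disulfide-constrained (CXnC) designs. All sequence
# offsets are 0-based, half-open.

.check_dna <- function(x, what, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single string")
  }
  if (!allow_empty && nchar(x) == 0L) stop(what, " must be non-empty")
  if (grepl("[^ACGT]", x)) stop(what, " must be over {A,C,G,T}: ", x)
  x
}

#' Describe an NNK phage-display library
#'
#' Bundles the amplicon layout of a single library: number of random NNK
#' codons, whether the insert is cysteine-constrained (CXnC), the fixed
#' cysteine codon used for the constraint, the constant flanks, and the
#' sample barcode. The barcode must occur verbatim inside the upstream flank
#' at `barcode_offset` (0-based position within the read), mirroring amplicon
#' designs where the barcode sits between the adapter and the cloning site.
#'
#' @param name Text label, e.g. `"C10C"`.
#' @param n_random_codons Number of random NNK codons (>= 1).
#' @param constrained Logical; `TRUE` for cysteine-looped CXnC designs.
#' @param cys_codon Codon used for the fixed flanking cysteines of
#'   constrained designs; must translate to Cys. Default `"TGT"` (third base
#'   T, so it is itself NNK-compatible).
#' @param upstream_flank Constant sequence immediately 5' of the insert
#'   (includes the barcode).
#' @param downstream_flank Constant sequence immediately 3' of the insert.
#' @param barcode Sample barcode (may be empty).
#' @param barcode_offset 0-based position of the barcode within the read.
#' @return An object of class `nnk_design`.
#' @examples
#' d <- library_design("C10C", 10, constrained = TRUE)
#' insert_length(d)   # 36 = 3*10 + 6
#' @export
library_design <- function(name,
                           n_random_codons,
                           constrained = FALSE,
                           cys_codon = "TGT",
                           upstream_flank = "ACGTCCAACGTGGC",
                           downstream_flank = "GGCCCCAGAGGC",
                           barcode = "ACGTC",
                           barcode_offset = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  n_random_codons <- as.integer(n_random_codons)
  if (is.na(n_random_codons) || n_random_codons < 1L) {
    stop("n_random_codons must be a positive integer")
  }
  stopifnot(isTRUE(constrained) || isFALSE(constrained))
  .check_dna(upstream_flank, "upstream_flank")
  .check_dna(downstream_flank, "downstream_flank")
  .check_dna(barcode, "barcode", allow_empty = TRUE)
  .check_dna(cys_codon, "cys_codon")
  if (nchar(cys_codon) != 3L ||
      !identical(unname(Biostrings::GENETIC_CODE[cys_codon]), "C")) {
    stop("cys_codon must be a cysteine codon (TGT or TGC)")
  }
  barcode_offset <- as.integer(barcode_offset)
  if (is.na(barcode_offset) || barcode_offset < 0L) {
    stop("barcode_offset must be a non-negative integer")
  }
  if (nchar(barcode) > 0L) {
    end <- barcode_offset + nchar(barcode)
    if (end > nchar(upstream_flank) ||
        substr(upstream_flank, barcode_offset + 1L, end) != barcode) {
      stop("barcode must occur in upstream_flank at barcode_offset")
    }
  }
  structure(
    list(name = name,
         n_random_codons = n_random_codons,
         constrained = constrained,
         cys_codon = cys_codon,
         upstream_flank = upstream_flank,
         downstream_flank = downstream_flank,
         barcode = barcode,
         barcode_offset = barcode_offset),
    class = "nnk_design"
  )
}

#' @export
print.nnk_design <- function(x, ...) {
  cat("NNK library design '", x$name, "'\n", sep = "")
  cat("  random codons: ", x$n_random_codons,
      if (x$constrained) paste0(" (constrained, cys codon ", x$cys_codon, ")"),
      "\n", sep = "")
  cat("  insert length: ", insert_length(x), " nt; read length: ",
      read_length(x), " nt\n", sep = "")
  cat("  barcode: ", if (nchar(x$barcode)) x$barcode else "<none>",
      " at offset ", x$barcode_offset, "\n", sep = "")
  invisible(x)
}

#' Expected insert length in nucleotides
#'
#' `3 * n_random_codons`, plus 6 for the two fixed cysteine codons of
#' constrained designs. Validated inserts include the cysteine codons.
#'
#' @param design An `nnk_design`.
#' @return Integer number of nucleotides.
#' @export
insert_length <- function(design) {
  stopifnot(inherits(design, "nnk_design"))
  3L * design$n_random_codons + if (design$constrained) 6L else 0L
}

#' Expected read length in nucleotides
#'
#' @param design An `nnk_design`.
#' @return Integer: flanks plus insert.
#' @export
read_length <- function(design) {
  nchar(design$upstream_flank) + insert_length(design) +
    nchar(design$downstream_flank)
}

#' Theoretical library complexity
#'
#' Number of distinct peptides the design can encode at the amino-acid
#' level: `20^n` over the random positions (fixed cysteines excluded).
#' This is the conventional "theoretical complexity" quoted for display
#' libraries. The nucleotide-level NNK diversity `32^n` is available via
#' [nnk_nucleotide_complexity()].
#'
#' @param design An `nnk_design`, or a plain integer number of random codons.
#' @return A double (values overflow integer range quickly).
#' @examples
#' theoretical_complexity(7)   # 1.28e9
#' @export
theoretical_complexity <- function(design) {
  n <- if (inherits(design, "nnk_design")) design$n_random_codons
       else as.integer(design)
  stopifnot(!is.na(n), n >= 1L)
  20^n
}

#' Nucleotide-level NNK complexity
#'
#' `32^n` distinct nucleotide inserts over the random positions.
#'
#' @inheritParams theoretical_complexity
#' @return A double.
#' @export
nnk_nucleotide_complexity <- function(design) {
  n <- if (inherits(design, "nnk_design")) design$n_random_codons
       else as.integer(design)
  stopifnot(!is.na(n), n >= 1L)
  32^n
}

# Vectorized insert validation. Returns NA_character_ for valid inserts,
# otherwise the first failing reason in the fixed order
# wrong_length -> non_nnk -> missing_cys -> ambiguous_base.
.validate_inserts <- function(x, design) {
  stopifnot(inherits(design, "nnk_design"))
  reason <- rep(NA_character_, length(x))
  if (length(x) == 0L) return(reason)
  if (any(grepl("[^ACGTN]", x))) {
    stop("inserts must be over {A,C,G,T,N}")
  }
  L <- insert_length(design)
  reason[nchar(x) != L] <- "wrong_length"
  live <- which(is.na(reason))
  if (length(live)) {
    off <- if (design$constrained) 3L else 0L
    third <- off + 3L * seq_len(design$n_random_codons)
    bad <- rep(FALSE, length(live))
    for (p in third) {
      b <- substr(x[live], p, p)
      bad <- bad | !(b %in% NNK_K_BASES)
    }
    reason[live[bad]] <- "non_nnk"
    live <- live[!bad]
  }
  if (length(live) && design$constrained) {
    cys <- design$cys_codon
    bad <- substr(x[live], 1L, 3L) != cys | substr(x[live], L - 2L, L) != cys
    reason[live[bad]] <- "missing_cys"
    live <- live[!bad]
  }
  if (length(live)) {
    bad <- grepl("N", x[live], fixed = TRUE)
    reason[live[bad]] <- "ambiguous_base"
  }
  reason
}

#' Validate a candidate NNK insert
#'
#' Checks a nucleotide insert against a design: expected length, fixed
#' cysteine codons for constrained designs, G/T at every random third
#' position, and no ambiguous base calls. Reads whose inserts fail any check
#' are the "aberrant" reads removed during pre-processing. Filters run in a
#' fixed order and a single (first-failing) reason is reported.
#'
#' @param seq A single nucleotide string over `{A,C,G,T,N}`.
#' @param design An `nnk_design`.
#' @return A list with `valid` (logical) and `reason` (`NA` when valid,
#'   otherwise one of `"wrong_length"`, `"non_nnk"`, `"missing_cys"`,
#'   `"ambiguous_base"`).
#' @examples
#' d <- library_design("L3", 3)
#' is_valid_nnk_insert("GGTTAGATG", d)$valid           # TRUE
#' is_valid_nnk_insert("GGTTAAATG", d)$reason          # "non_nnk"
#' @export
is_valid_nnk_insert <- function(seq, design) {
  stopifnot(is.character(seq), length(seq) == 1L)
  r <- .validate_inserts(seq, design)
  list(valid = is.na(r), reason = r)
}

#' Load a library design from a YAML file
#'
#' The file holds one document with the fields of [library_design()]
#' (`name`, `n_random_codons`, `constrained`, and optionally `cys_codon`,
#' `upstream_flank`, `downstream_flank`, `barcode`, `barcode_offset`).
#'
#' @param path Path to a YAML file.
#' @return An `nnk_design`.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(library_design))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown design field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(library_design, cfg)
}
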