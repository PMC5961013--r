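# Translation of validated inserts and stop-codon accounting.

#' Translate NNK inserts
#'
#' Standard genetic code per codon; when `amber_as_q = TRUE` the amber codon
#' TAG is read as glutamine (`Q`), modelling supE44 suppression. TGA always
#' yields `*` (no opal suppressor).
#'
#' @param insert Character vector of validated inserts (equal length,
#'   divisible by 3).
#' @param amber_as_q Logical; translate TAG as Gln.
#' @return Character vector of peptides over the 20 amino acids plus `*`.
#' @examples
#' translate_nnk("TAGGGT")                      # "QG"
#' translate_nnk("TAGGGT", amber_as_q = FALSE)  # "*G"
#' @export
translate_nnk <- function(insert, amber_as_q = TRUE) {
  if (length(insert) == 0L) return(character(0))
  cm <- .codon_matrix(insert)
  aa <- matrix(.translate_codons(cm, amber_as_q = amber_as_q), nrow = nrow(cm))
  do.call(paste0, lapply(seq_len(ncol(aa)), function(j) aa[, j]))
}

#' Classify stop-codon content of inserts
#'
#' Three mutually exclusive classes: `other_stop` if any codon is TGA or TAA
#' (abortive termination with no suppressor in any host), else `uag_only` if
#' any codon is TAG (translated as Gln under suppression), else `no_stop`.
#' `other_stop` takes precedence when both occur. TAA cannot survive NNK
#' validation but is handled for robustness.
#'
#' @param insert Character vector of equal-length inserts.
#' @return Factor with levels `no_stop`, `uag_only`, `other_stop`.
#' @examples
#' classify_stops(c("GGTGGT", "TAGGGT", "TGATAG"))
#' @export
classify_stops <- function(insert) {
  cls <- rep("no_stop", length(insert))
  if (length(insert)) {
    cls[.has_any_codon(insert, "TAG")] <- "uag_only"
    cls[.has_any_codon(insert, c("TGA", "TAA"))] <- "other_stop"
  }
  factor(cls, levels = c("no_stop", "uag_only", "other_stop"))
}

#' Translate an insert table into a peptide table
#'
#' Translates each distinct insert, classifies its stop content, and
#' computes totals and stop-class fractions under both weightings reported
#' for sequenced libraries: by read count and by unique (nucleotide-level)
#' sequence. Uniqueness is at the nucleotide level, since synonymous NNK
#' codons encode the same peptide.
#'
#' @param x An [insert_table()].
#' @param amber_as_q Logical; translate TAG as Gln.
#' @return An object of class `nnk_peptide_table`: list with `peptides`
#'   (data.frame `insert`, `peptide`, `count`, `stop_class`, `n_amber`),
#'   `design`, `amber_as_q`, `total_peptides`, `unique_peptides`, and
#'   `class_fractions` (list of `reads` and `unique` named fractions; NaN
#'   on an empty table).
#' @export
tabulate_peptides <- function(x, amber_as_q = TRUE) {
  stopifnot(inherits(x, "nnk_insert_table"))
  df <- x$data
  if (nrow(df)) {
    cm <- .codon_matrix(df$insert)
    pep <- translate_nnk(df$insert, amber_as_q = amber_as_q)
    n_amber <- rowSums(matrix(cm == "TAG", nrow = nrow(cm)))
    cls <- classify_stops(df$insert)
  } else {
    pep <- character(0)
    n_amber <- integer(0)
    cls <- classify_stops(character(0))
  }
  peptides <- data.frame(insert = df$insert, peptide = pep,
                         count = df$count, stop_class = cls,
                         n_amber = n_amber)
  total <- sum(peptides$count)
  uniq <- nrow(peptides)
  frac <- function(w) {
    tot <- sum(w)
    if (tot == 0) {
      stats::setNames(rep(NaN, nlevels(cls)), levels(cls))
    } else {
      tapply(w, peptides$stop_class, sum, default = 0) / tot
    }
  }
  structure(
    list(peptides = peptides, design = x$design, amber_as_q = amber_as_q,
         total_peptides = total, unique_peptides = uniq,
         class_fractions = list(reads = frac(peptides$count),
                                unique = frac(rep(1, uniq)))),
    class = "nnk_peptide_table"
  )
}

#' @export
print.nnk_peptide_table <- function(x, ...) {
  cat("NNK peptide table (design '", x$design$name, "', amber as ",
      if (x$amber_as_q) "Q" else "stop", ")\n", sep = "")
  cat("  total peptides: ", x$total_peptides,
      "; unique (nt-level): ", x$unique_peptides, "\n", sep = "")
  fr <- x$class_fractions$reads
  cat(sprintf("  stop classes (read-weighted): no_stop %.3f, uag_only %.3f, other_stop %.3f\n",
              fr[["no_stop"]], fr[["uag_only"]], fr[["other_stop"]]))
  invisible(x)
}
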