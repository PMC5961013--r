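# Randomness diagnostics: per-position composition with analytic
# expectations, degeneracy-normalized amino-acid distribution, amber-content
# expectation, and over-representation screening.

# Random-position core of validated inserts (fixed cysteines stripped).
.random_core <- function(inserts, design) {
  if (design$constrained) {
    L <- insert_length(design)
    substr(inserts, 4L, L - 3L)
  } else {
    inserts
  }
}

#' Per-position nucleotide composition
#'
#' Read-count-weighted base fractions at every random position of the
#' design (3 per random codon; fixed cysteines excluded). Under an ideal
#' synthesis, N slots (codon positions 1-2) are 25% per base and K slots
#' (position 3) are 50% G / 50% T.
#'
#' @param x A non-empty [insert_table()].
#' @return An object of class `nnk_composition`: a data.frame with `codon`
#'   (1-based codon index), `slot` (1-3), fraction columns `A`, `C`, `G`,
#'   `T`, and `n` (total read weight), with the design as attribute.
#' @export
nucleotide_composition <- function(x) {
  stopifnot(inherits(x, "nnk_insert_table"))
  df <- x$data
  if (nrow(df) == 0L) stop("empty insert table")
  core <- .random_core(df$insert, x$design)
  w <- df$count
  m <- 3L * x$design$n_random_codons
  frac <- matrix(0, nrow = m, ncol = 4L,
                 dimnames = list(NULL, NNK_N_BASES))
  for (p in seq_len(m)) {
    b <- factor(substr(core, p, p), levels = NNK_N_BASES)
    frac[p, ] <- tapply(w, b, sum, default = 0) / sum(w)
  }
  out <- data.frame(codon = rep(seq_len(x$design$n_random_codons), each = 3L),
                    slot = rep(1:3, x$design$n_random_codons),
                    frac, n = sum(w))
  structure(out, class = c("nnk_composition", "data.frame"),
            design = x$design)
}

#' Composition deviation from NNK expectation
#'
#' Per position, the Pearson chi-square statistic of the observed base
#' counts against the ideal NNK expectation (equimolar A/C/G/T at N slots;
#' equimolar G/T at K slots), plus per-base fold over expected. Reported as
#' descriptive statistics only -- no p-values or multiplicity correction.
#'
#' @param profile An `nnk_composition`.
#' @return A data.frame with `codon`, `slot`, `chisq`, and `fold_A` ..
#'   `fold_T` (fold is `NA` for A/C at K slots, where the expectation is 0).
#' @examples
#' d <- library_design("L1", 1)
#' it <- insert_table("GGG", 100, d)
#' composition_deviation(nucleotide_composition(it))
#' @export
composition_deviation <- function(profile) {
  stopifnot(inherits(profile, "nnk_composition"))
  n <- profile$n
  stopifnot(all(n > 0))
  obs <- as.matrix(profile[, NNK_N_BASES])
  is_k <- profile$slot == 3L
  expd <- matrix(0.25, nrow = nrow(profile), ncol = 4L,
                 dimnames = list(NULL, NNK_N_BASES))
  expd[is_k, ] <- rep(c(0, 0, 0.5, 0.5), each = sum(is_k))
  dev2 <- (obs - expd)^2 / ifelse(expd > 0, expd, NA)
  chisq <- n * rowSums(dev2, na.rm = TRUE)
  fold <- obs / ifelse(expd > 0, expd, NA)
  colnames(fold) <- paste0("fold_", NNK_N_BASES)
  data.frame(codon = profile$codon, slot = profile$slot,
             chisq = chisq, fold)
}

#' Degeneracy-normalized amino-acid distribution
#'
#' Read-weighted residue frequencies over all random positions, translated
#' with amber suppression (TAG as Gln), divided by each residue's NNK codon
#' degeneracy and renormalized to sum to 1. The amber-derived glutamine is
#' kept as its own class (`"q"`) alongside the 20 amino acids -- 21 classes
#' in all -- so a perfectly codon-uniform NNK library scores exactly
#' 1/21 = 0.048 for every class. Positions carrying a non-suppressible stop
#' (TGA; impossible in a validated NNK insert but tolerated defensively) are
#' excluded from the tally and its denominator. Raw (un-normalized)
#' frequencies are attached as attribute `"raw"`.
#'
#' @param peps A non-empty `nnk_peptide_table` built with `amber_as_q = TRUE`.
#' @return Named numeric vector over the 21 residue classes, summing to 1.
#' @examples
#' d <- library_design("L1", 1)
#' it <- insert_table(nnk_codons(), rep(1, 32), d)
#' normalized_aa_distribution(tabulate_peptides(it))  # flat 1/21
#' @export
normalized_aa_distribution <- function(peps) {
  stopifnot(inherits(peps, "nnk_peptide_table"))
  if (!peps$amber_as_q) {
    stop("normalized distribution is defined under amber suppression; ",
         "build the peptide table with amber_as_q = TRUE")
  }
  df <- peps$peptides
  if (nrow(df) == 0L) stop("empty peptide table")
  core <- .random_core(df$insert, peps$design)
  cm <- .codon_matrix(core)
  cls_m <- matrix(.nnk_class_of_codon(cm), nrow = nrow(cm))
  deg <- .nnk_class_degeneracy()
  counts <- stats::setNames(numeric(length(deg)), names(deg))
  for (j in seq_len(ncol(cls_m))) {
    cj <- factor(cls_m[, j], levels = names(deg))  # "*" drops to NA
    cnt <- as.numeric(tapply(df$count, cj, sum, default = 0))
    counts <- counts + cnt
  }
  if (sum(counts) == 0) stop("no coding positions in table")
  raw <- counts / sum(counts)
  norm <- raw / deg
  norm <- stats::setNames(as.numeric(norm / sum(norm)), names(deg))
  attr(norm, "raw") <- raw
  norm
}

#' Expected amber-containing fraction of an equimolar NNK library
#'
#' Probability that an insert of `n_codons` independent equimolar NNK codons
#' contains at least one TAG: `1 - (31/32)^n`. For n = 10 this is 0.272,
#' the "about 27%" benchmark for a 10-mer library.
#'
#' @param n_codons Non-negative integer count of random codons.
#' @return Probability in `[0,1]`.
#' @examples
#' expected_uag_fraction(10)  # 0.2718...
#' @export
expected_uag_fraction <- function(n_codons) {
  stopifnot(is.numeric(n_codons), all(n_codons >= 0),
            all(n_codons == floor(n_codons)))
  1 - (31 / 32)^n_codons
}

#' Bias-adjusted expected amber fraction
#'
#' Secondary expectation that drops the equimolarity assumption: per codon,
#' the TAG probability is the product of the observed T, A, G fractions at
#' its three slots; the insert-level expectation is
#' `1 - prod(1 - p_TAG(codon))`.
#'
#' @param profile An `nnk_composition`.
#' @return Probability in `[0,1]`.
#' @export
adjusted_uag_expectation <- function(profile) {
  stopifnot(inherits(profile, "nnk_composition"))
  p_tag <- vapply(unique(profile$codon), function(j) {
    rows <- profile[profile$codon == j, ]
    rows$T[rows$slot == 1L] * rows$A[rows$slot == 2L] * rows$G[rows$slot == 3L]
  }, numeric(1))
  1 - prod(1 - p_tag)
}

#' Over-represented peptide report
#'
#' Ranks peptides by read count to surface clones amplified far beyond the
#' mean copy number ("parasitic" growth/assembly advantages rather than
#' affinity). Counts are aggregated at the peptide level; fold is count over
#' the mean copy number `total / unique`. Ties break lexicographically.
#'
#' @param peps An `nnk_peptide_table`.
#' @param top_k Number of rows to return (>= 1); the full table if fewer.
#' @return A data.frame with `peptide`, `count`, `fold`, ordered by
#'   decreasing count.
#' @export
overrepresentation_report <- function(peps, top_k = 25L) {
  stopifnot(inherits(peps, "nnk_peptide_table"), top_k >= 1L)
  df <- peps$peptides
  if (nrow(df) == 0L) {
    return(data.frame(peptide = character(0), count = numeric(0),
                      fold = numeric(0)))
  }
  agg <- stats::aggregate(count ~ peptide, data = df, FUN = sum)
  mean_copy <- sum(agg$count) / nrow(agg)
  agg$fold <- agg$count / mean_copy
  agg <- agg[order(-agg$count, agg$peptide), , drop = FALSE]
  rownames(agg) <- NULL
  utils::head(agg, top_k)
}

#' Assemble the full bias report for a sequenced library
#'
#' One object carrying every randomness diagnostic: per-position
#' composition and its chi-square deviation, the degeneracy-normalized
#' amino-acid distribution, stop-class fractions (both weightings),
#' observed vs expected amber content, library totals and theoretical
#' complexity, and the over-representation ranking.
#'
#' @param x A non-empty [insert_table()].
#' @param amber_as_q Logical; translate TAG as Gln (default TRUE).
#' @param top_k Rows in the over-representation report.
#' @return An object of class `nnk_bias_report`.
#' @export
build_bias_report <- function(x, amber_as_q = TRUE, top_k = 25L) {
  stopifnot(inherits(x, "nnk_insert_table"))
  if (nrow(x$data) == 0L) stop("empty insert table")
  peps <- tabulate_peptides(x, amber_as_q = amber_as_q)
  comp <- nucleotide_composition(x)
  w <- x$data$count
  has_amber <- .has_any_codon(.random_core(x$data$insert, x$design), "TAG")
  structure(
    list(design = x$design,
         report = x$report,
         composition = comp,
         deviation = composition_deviation(comp),
         aa_normalized = normalized_aa_distribution(peps),
         stop_class = peps$class_fractions,
         total_peptides = peps$total_peptides,
         unique_peptides = peps$unique_peptides,
         uag_observed = sum(w[has_amber]) / sum(w),
         uag_observed_unique = mean(has_amber),
         uag_expected = expected_uag_fraction(x$design$n_random_codons),
         uag_expected_adjusted = adjusted_uag_expectation(comp),
         complexity = theoretical_complexity(x$design),
         top_overrepresented = overrepresentation_report(peps, top_k)),
    class = "nnk_bias_report"
  )
}

#' @export
print.nnk_bias_report <- function(x, ...) {
  cat("NNK library bias report -- design '", x$design$name, "'\n", sep = "")
  cat("  reads accepted: ", x$report$accepted, "/", x$report$total,
      "; unique inserts: ", x$unique_peptides,
      "; theoretical complexity: ", format(x$complexity, digits = 3),
      "\n", sep = "")
  cat(sprintf("  amber content: observed %.3f (read-weighted) vs expected %.3f (equimolar), %.3f (bias-adjusted)\n",
              x$uag_observed, x$uag_expected, x$uag_expected_adjusted))
  fr <- x$stop_class$reads
  cat(sprintf("  stop classes (reads): no_stop %.3f, uag_only %.3f, other_stop %.3f\n",
              fr[["no_stop"]], fr[["uag_only"]], fr[["other_stop"]]))
  cat(sprintf("  max position chi-square: %.1f; max |normalized AA - 1/21|: %.4f\n",
              max(x$deviation$chisq), max(abs(x$aa_normalized - 1 / 21))))
  invisible(x)
}
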