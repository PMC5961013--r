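# Simulation of library synthesis, host passage and sequencing.
#
# Two bias mechanisms are modelled:
#  (1) chemistry: each phosphoramidite is incorporated with probability
#      proportional to stock molar ratio x relative efficiency, so unequal
#      efficiencies skew the per-position base composition;
#  (2) biology: in type-88 vectors an insert stop codon aborts only the
#      recombinant Protein 8, yielding a wild-type-phenotype phage that
#      escapes the display burden and out-grows displaying clones unless the
#      host suppresses the amber codon.

#' Phosphoramidite synthesis model
#'
#' Stock molar ratios for the N-position (A/C/G/T) and K-position (G/T)
#' mixes, together with relative incorporation efficiencies per base
#' (dimensionless; only ratios matter). The effective probability of
#' incorporating base b at an N position is
#' `stock_n[b] * efficiency[b] / sum(stock_n * efficiency)`, and analogously
#' over {G,T} at K positions.
#'
#' @param stock_n Named positive numeric over A,C,G,T: N-mix molar ratios.
#' @param stock_k Named positive numeric over G,T: K-mix molar ratios.
#' @param efficiency Named positive numeric over A,C,G,T: relative
#'   incorporation efficiencies (conventionally G-relative).
#' @return An object of class `nnk_synthesis_model`.
#' @examples
#' # an idealized equimolar, equal-efficiency synthesis
#' synthesis_model()
#' # G incorporates more efficiently than the others
#' synthesis_model(efficiency = c(A = 2/3, C = 0.625, G = 1, T = 2/3))
#' @export
synthesis_model <- function(stock_n = c(A = 1, C = 1, G = 1, T = 1),
                            stock_k = c(G = 1, T = 1),
                            efficiency = c(A = 1, C = 1, G = 1, T = 1)) {
  .check_ratio <- function(x, nm, what) {
    if (!is.numeric(x) || !setequal(names(x), nm)) {
      stop(what, " must be a named numeric over {", paste(nm, collapse = ","), "}")
    }
    x <- x[nm]
    if (any(!is.finite(x)) || any(x <= 0)) stop(what, " must be positive and finite")
    x
  }
  structure(
    list(stock_n = .check_ratio(stock_n, NNK_N_BASES, "stock_n"),
         stock_k = .check_ratio(stock_k, NNK_K_BASES, "stock_k"),
         efficiency = .check_ratio(efficiency, NNK_N_BASES, "efficiency")),
    class = "nnk_synthesis_model"
  )
}

#' @export
print.nnk_synthesis_model <- function(x, ...) {
  p <- incorporation_probs(x)
  cat("NNK synthesis model\n")
  cat("  stock N  :", paste(sprintf("%s=%.3g", names(x$stock_n), x$stock_n),
                            collapse = " "), "\n")
  cat("  stock K  :", paste(sprintf("%s=%.3g", names(x$stock_k), x$stock_k),
                            collapse = " "), "\n")
  cat("  efficiency:", paste(sprintf("%s=%.3g", names(x$efficiency), x$efficiency),
                             collapse = " "), "\n")
  cat("  effective N:", paste(sprintf("%s=%.3f", names(p$N), p$N), collapse = " "),
      "\n")
  cat("  effective K:", paste(sprintf("%s=%.3f", names(p$K), p$K), collapse = " "),
      "\n")
  invisible(x)
}

#' Effective incorporation probabilities
#'
#' @param model An `nnk_synthesis_model`.
#' @return A list with `N` (probabilities over A,C,G,T) and `K`
#'   (probabilities over G,T), each summing to 1.
#' @export
incorporation_probs <- function(model) {
  stopifnot(inherits(model, "nnk_synthesis_model"))
  wn <- model$stock_n * model$efficiency
  wk <- model$stock_k * model$efficiency[NNK_K_BASES]
  list(N = wn / sum(wn), K = wk / sum(wk))
}

#' Host strain model for phage passage
#'
#' Captures the genetics that drive amber-codon enrichment: whether the host
#' carries supE44 (amber suppression inserting Gln), the suppression
#' efficiency, the per-generation fitness cost of assembling the recombinant
#' Protein 8 (the display burden), and the number of growth generations.
#'
#' Clone fitness per generation:
#' \itemize{
#'   \item insert contains UGA (or UAA): always abortive termination, pure
#'     wild-type phenotype, fitness 1 (no opal suppressor in either host);
#'   \item insert contains UAG only: fitness
#'     `1 - suppression_efficiency * display_burden` (readthrough imposes the
#'     burden; abortive termination escapes it);
#'   \item stop-free insert: fitness `1 - display_burden`.
#' }
#'
#' @param supE44 Logical; `FALSE` models MC1061-like non-suppressing hosts,
#'   in which `suppression_efficiency` is forced to 0.
#' @param suppression_efficiency Probability in `[0,1]` that an amber codon
#'   is read through as Gln. Default 0.9 for supE44 hosts (suppression is
#'   known to be less than complete).
#' @param display_burden Per-generation fitness cost in `[0,1]` of displaying
#'   the recombinant Protein 8 fusion. Default 0.1.
#' @param generations Positive number of growth generations. Default 19
#'   (roughly one generation per hour of overnight growth).
#' @return An object of class `nnk_host_model`.
#' @export
host_model <- function(supE44,
                       suppression_efficiency = if (supE44) 0.9 else 0,
                       display_burden = 0.1,
                       generations = 19) {
  stopifnot(isTRUE(supE44) || isFALSE(supE44))
  if (!supE44 && suppression_efficiency != 0) {
    stop("suppression_efficiency must be 0 when supE44 is FALSE")
  }
  stopifnot(is.numeric(suppression_efficiency),
            suppression_efficiency >= 0, suppression_efficiency <= 1,
            is.numeric(display_burden),
            display_burden >= 0, display_burden <= 1,
            is.numeric(generations), generations >= 0)
  structure(
    list(supE44 = supE44,
         suppression_efficiency = suppression_efficiency,
         display_burden = display_burden,
         generations = generations),
    class = "nnk_host_model"
  )
}

#' @export
print.nnk_host_model <- function(x, ...) {
  cat("Host model: supE44", if (x$supE44) "+" else "-",
      sprintf(" (suppression %.2f), display burden %.2f, %g generations\n",
              x$suppression_efficiency, x$display_burden, x$generations),
      sep = "")
  invisible(x)
}

#' Draw random NNK inserts
#'
#' Samples nucleotide inserts for a design, drawing every random-position
#' base independently from the synthesis model's effective incorporation
#' distribution; constrained designs receive their fixed cysteine codons.
#' Uses the current RNG state (`set.seed()` for reproducibility).
#'
#' @param design An `nnk_design`.
#' @param model An `nnk_synthesis_model`.
#' @param n Number of inserts to draw.
#' @return Character vector of `n` inserts of length [insert_length()].
#' @examples
#' set.seed(1)
#' sample_nnk_inserts(library_design("L3", 3), n = 2)
#' @export
sample_nnk_inserts <- function(design, model = synthesis_model(), n = 1L) {
  stopifnot(inherits(design, "nnk_design"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(character(0))
  p <- incorporation_probs(model)
  k <- design$n_random_codons
  b1 <- sample(NNK_N_BASES, n * k, replace = TRUE, prob = p$N)
  b2 <- sample(NNK_N_BASES, n * k, replace = TRUE, prob = p$N)
  b3 <- sample(NNK_K_BASES, n * k, replace = TRUE, prob = p$K)
  codons <- matrix(paste0(b1, b2, b3), nrow = n, ncol = k)
  ins <- do.call(paste0, lapply(seq_len(k), function(j) codons[, j]))
  if (design$constrained) {
    ins <- paste0(design$cys_codon, ins, design$cys_codon)
  }
  ins
}

#' Build a naive clone population
#'
#' `n_clones` independent inserts, each with abundance weight 1 -- the state
#' of a library immediately after electroporation, before any growth bias.
#'
#' @inheritParams sample_nnk_inserts
#' @param n_clones Number of clones (>= 1).
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is
#'   called first.
#' @return An object of class `nnk_population`: a list with `clones`
#'   (data.frame of `insert`, `weight`), `design`, `synthesis`, `host`
#'   (NULL until [passage()]), and `seed`.
#' @export
build_naive_pool <- function(design, model = synthesis_model(), n_clones,
                             seed = NULL) {
  stopifnot(n_clones >= 1)
  if (!is.null(seed)) set.seed(seed)
  ins <- sample_nnk_inserts(design, model, n_clones)
  structure(
    list(clones = data.frame(insert = ins, weight = rep(1, length(ins))),
         design = design, synthesis = model, host = NULL,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "nnk_population"
  )
}

#' @export
print.nnk_population <- function(x, ...) {
  cat("NNK clone population: ", nrow(x$clones), " clones, total weight ",
      format(sum(x$clones$weight)), "\n", sep = "")
  cat("  design: ", x$design$name,
      if (!is.null(x$host)) " (passaged)", "\n", sep = "")
  cat(sprintf("  UAG-bearing weight fraction: %.4f\n", uag_fraction(x)))
  invisible(x)
}

.clone_fitness <- function(inserts, host) {
  has_opal <- .has_any_codon(inserts, c("TGA", "TAA"))
  has_amber <- .has_any_codon(inserts, "TAG")
  s <- if (host$supE44) host$suppression_efficiency else 0
  f <- rep(1 - host$display_burden, length(inserts))
  f[has_amber] <- 1 - s * host$display_burden
  f[has_opal] <- 1
  f
}

#' Grow a clone population in a host
#'
#' Deterministic expectation dynamics: every clone's weight is multiplied by
#' `fitness^generations`, with fitness from the [host_model()] rules. No
#' clones are created or destroyed and no demographic noise is added, so the
#' weighted amber fraction follows the closed form
#' `f' = f * w_uag^g / (f * w_uag^g + (1 - f) * w_rec^g)` when all
#' amber clones share a fitness. In a non-suppressing host with a positive
#' display burden the amber fraction rises with generations; with full
#' suppression (or zero burden) it is unchanged.
#'
#' @param pop An `nnk_population`.
#' @param host An `nnk_host_model`.
#' @return A new `nnk_population` with updated weights and `host` recorded.
#' @examples
#' set.seed(7)
#' pool <- build_naive_pool(library_design("C10C", 10, constrained = TRUE),
#'                          n_clones = 1000)
#' grown <- passage(pool, host_model(supE44 = FALSE))
#' uag_fraction(pool); uag_fraction(grown)
#' @export
passage <- function(pop, host) {
  stopifnot(inherits(pop, "nnk_population"), inherits(host, "nnk_host_model"))
  if (host$generations < 0) stop("generations must be non-negative")
  stopifnot(all(is.finite(pop$clones$weight)))
  f <- .clone_fitness(pop$clones$insert, host)
  pop$clones$weight <- pop$clones$weight * f^host$generations
  pop$host <- host
  pop
}

#' Weighted amber-codon fraction of a population
#'
#' Fraction of total clone weight carried by clones whose insert contains at
#' least one TAG codon (regardless of other stop codons) -- the quantity
#' tracked when comparing suppressing and non-suppressing hosts over time.
#'
#' @param pop An `nnk_population`.
#' @return A fraction in `[0,1]` (NaN for zero total weight).
#' @export
uag_fraction <- function(pop) {
  stopifnot(inherits(pop, "nnk_population"))
  w <- pop$clones$weight
  sum(w[.has_any_codon(pop$clones$insert, "TAG")]) / sum(w)
}

.other_bases <- function(b) {
  lapply(b, function(x) setdiff(NNK_N_BASES, x))
}

.apply_defect <- function(read, defect, design) {
  ul <- nchar(design$upstream_flank)
  il <- insert_length(design)
  if (defect == "insert_indel") {
    if (stats::runif(1) < 0.5) {
      p <- ul + sample.int(il, 1L)  # insert after position p-1
      paste0(substr(read, 1L, p - 1L), sample(NNK_N_BASES, 1L),
             substr(read, p, nchar(read)))
    } else {
      p <- ul + sample.int(il, 1L)
      paste0(substr(read, 1L, p - 1L), substr(read, p + 1L, nchar(read)))
    }
  } else if (defect == "wrong_barcode") {
    p <- design$barcode_offset + sample.int(nchar(design$barcode), 1L)
    b <- substr(read, p, p)
    substr(read, p, p) <- sample(setdiff(NNK_N_BASES, b), 1L)
    read
  } else if (defect == "non_nnk") {
    j <- sample.int(design$n_random_codons, 1L)
    p <- ul + (if (design$constrained) 3L else 0L) + 3L * j
    substr(read, p, p) <- sample(c("A", "C"), 1L)
    read
  } else {
    stop("unknown defect: ", defect)
  }
}

.substitute_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  nmut <- stats::rbinom(length(reads), nchar(reads), error_rate)
  for (i in which(nmut > 0L)) {
    pos <- sample.int(nchar(reads[i]), nmut[i])
    for (p in pos) {
      b <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(NNK_N_BASES, b), 1L)
    }
  }
  reads
}

#' Emit sequencing reads from a population
#'
#' Samples reads with probability proportional to clone weight, assembles
#' the full amplicon layout (upstream flank with barcode, insert, downstream
#' flank), then optionally injects aberrant-read defects and uniform
#' substitution errors. Defects are drawn uniformly from
#' `insert_indel` (one-nucleotide insertion or deletion inside the insert),
#' `wrong_barcode` (one substitution in the barcode), and `non_nnk` (a random
#' codon's third base set to A or C); `wrong_barcode` is skipped for
#' barcode-free designs. Uses the current RNG state.
#'
#' @param pop An `nnk_population` with positive total weight.
#' @param n_reads Number of reads (>= 0).
#' @param error_rate Per-base substitution probability.
#' @param aberrant_fraction Probability that a read carries a defect.
#' @return A data.frame with columns `id`, `seq`, `clone_insert` (the
#'   originating insert, pre-defect) and `defect`.
#' @export
emit_reads <- function(pop, n_reads, error_rate = 0, aberrant_fraction = 0) {
  stopifnot(inherits(pop, "nnk_population"), n_reads >= 0,
            error_rate >= 0, error_rate <= 1,
            aberrant_fraction >= 0, aberrant_fraction <= 1)
  n_reads <- as.integer(n_reads)
  design <- pop$design
  if (n_reads == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      clone_insert = character(0), defect = character(0)))
  }
  w <- pop$clones$weight
  if (sum(w) <= 0) stop("population has zero total weight")
  idx <- sample.int(nrow(pop$clones), n_reads, replace = TRUE, prob = w)
  ins <- pop$clones$insert[idx]
  reads <- paste0(design$upstream_flank, ins, design$downstream_flank)
  defect <- rep("none", n_reads)
  ab <- stats::runif(n_reads) < aberrant_fraction
  if (any(ab)) {
    types <- c("insert_indel", "wrong_barcode", "non_nnk")
    if (nchar(design$barcode) == 0L) types <- setdiff(types, "wrong_barcode")
    defect[ab] <- sample(types, sum(ab), replace = TRUE)
    for (i in which(ab)) {
      reads[i] <- .apply_defect(reads[i], defect[i], design)
    }
  }
  reads <- .substitute_errors(reads, error_rate)
  data.frame(id = sprintf("read_%07d", seq_len(n_reads)),
             seq = reads, clone_insert = ins, defect = defect)
}

#' Write reads as FASTQ
#'
#' Standard 4-line records with constant Phred+33 quality Q40 (`I`). Output
#' is byte-identical for identical input.
#'
#' @param reads Data.frame from [emit_reads()] (columns `id`, `seq`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  n <- nrow(reads)
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$id)
    lines[seq(2L, by = 4L, length.out = n)] <- reads$seq
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- strrep("I", nchar(reads$seq))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Simulate a sequenced NNK library end to end
#'
#' Convenience wrapper: seeds the RNG, builds a naive pool, optionally
#' passages it through a host, emits reads, and optionally writes FASTQ and
#' a ground-truth TSV (read id, originating insert, injected defect).
#' Identical arguments (including `seed`) give byte-identical outputs.
#'
#' @param design An `nnk_design`.
#' @param synthesis An `nnk_synthesis_model`.
#' @param host An `nnk_host_model`, or NULL to skip passage.
#' @param n_clones Clones in the naive pool.
#' @param n_reads Reads to emit.
#' @param error_rate Per-base substitution probability (default 0.001,
#'   Illumina-like).
#' @param aberrant_fraction Fraction of defective reads (default 0.05).
#' @param seed Integer seed controlling all randomness.
#' @param fastq Optional FASTQ output path.
#' @param truth Optional ground-truth TSV output path.
#' @return Invisibly, a list with `population` and `reads`.
#' @examples
#' d <- library_design("L7", 7)
#' sim <- simulate_library(d, n_clones = 100, n_reads = 200, seed = 1)
#' head(sim$reads$seq, 2)
#' @export
simulate_library <- function(design,
                             synthesis = synthesis_model(),
                             host = NULL,
                             n_clones = 10000,
                             n_reads = 10000,
                             error_rate = 0.001,
                             aberrant_fraction = 0.05,
                             seed = 1,
                             fastq = NULL,
                             truth = NULL) {
  set.seed(as.integer(seed))
  pop <- build_naive_pool(design, synthesis, n_clones)
  pop$seed <- as.integer(seed)
  if (!is.null(host)) pop <- passage(pop, host)
  reads <- emit_reads(pop, n_reads, error_rate = error_rate,
                      aberrant_fraction = aberrant_fraction)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth)) {
    utils::write.table(reads[, c("id", "clone_insert", "defect")], truth,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(population = pop, reads = reads))
}
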