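# Read-to-insert filtering. Filters run in a fixed order and each read is
# counted under exactly one (first-failing) reason:
#   barcode_mismatch -> flank_mismatch -> wrong_length -> non_nnk
#     -> missing_cys -> ambiguous_base
# Matching is exact (zero mismatches) at fixed offsets: the upstream flank is
# anchored at the read start and the downstream flank at the read end, as in
# fixed-layout amplicon sequencing. Base qualities are ignored; reads are
# assumed to be in forward orientation.

FILTER_REASONS <- c("barcode_mismatch", "flank_mismatch", "wrong_length",
                    "non_nnk", "missing_cys", "ambiguous_base")

#' Filter tally for one pre-processing run
#'
#' @param total Total reads seen.
#' @param rejected Named integer vector over (a subset of) the rejection
#'   reasons.
#' @return An object of class `nnk_filter_report` with fields `total`,
#'   `accepted`, and `rejected` (full named vector over all six reasons).
#' @export
filter_report <- function(total, rejected = integer(0)) {
  total <- as.integer(total)
  rej <- stats::setNames(integer(length(FILTER_REASONS)), FILTER_REASONS)
  if (length(rejected)) {
    bad <- setdiff(names(rejected), FILTER_REASONS)
    if (length(bad)) stop("unknown rejection reason(s): ", paste(bad, collapse = ", "))
    rej[names(rejected)] <- as.integer(rejected)
  }
  accepted <- total - sum(rej)
  if (total < 0L || any(rej < 0L) || accepted < 0L) {
    stop("inconsistent filter tally")
  }
  structure(list(total = total, accepted = accepted, rejected = rej),
            class = "nnk_filter_report")
}

#' @export
print.nnk_filter_report <- function(x, ...) {
  cat("Filter report: ", x$accepted, "/", x$total, " reads accepted\n", sep = "")
  for (r in FILTER_REASONS) {
    if (x$rejected[[r]] > 0L) cat(sprintf("  %-16s %d\n", r, x$rejected[[r]]))
  }
  invisible(x)
}

#' Exact barcode match
#'
#' The barcode must occur with 100% fidelity at its fixed 0-based offset;
#' an empty barcode matches vacuously, and reads too short to contain the
#' barcode fail.
#'
#' @param read Character vector of read sequences.
#' @param design An `nnk_design`.
#' @return Logical vector.
#' @export
match_barcode <- function(read, design) {
  stopifnot(inherits(design, "nnk_design"))
  bl <- nchar(design$barcode)
  if (bl == 0L) return(rep(TRUE, length(read)))
  off <- design$barcode_offset
  nchar(read) >= off + bl &
    substr(read, off + 1L, off + bl) == design$barcode
}

# Vectorized flank matching + insert extraction. Returns list(insert, reason):
# reason is "flank_mismatch" or NA; insert is NA where rejected.
.extract_inserts <- function(reads, design) {
  rl <- nchar(reads)
  ul <- nchar(design$upstream_flank)
  dl <- nchar(design$downstream_flank)
  ok <- rl >= ul + dl &
    substr(reads, 1L, ul) == design$upstream_flank &
    substr(reads, rl - dl + 1L, rl) == design$downstream_flank
  ins <- rep(NA_character_, length(reads))
  ins[ok] <- substr(reads[ok], ul + 1L, rl[ok] - dl)
  list(insert = ins,
       reason = ifelse(ok, NA_character_, "flank_mismatch"))
}

#' Extract the insert from one read
#'
#' Requires a zero-mismatch match of the upstream flank at the read start
#' and of the downstream flank at the read end; the spanned region (fixed
#' cysteine codons included for constrained designs) is returned. Length and
#' NNK validity are checked downstream, so a read with an intact flank pair
#' but a shifted insert is reported there as `wrong_length`, not here.
#'
#' @param read A single read sequence (barcode already checked).
#' @param design An `nnk_design`.
#' @return A list with `insert` (string or `NA`) and `reason`
#'   (`NA` or `"flank_mismatch"`).
#' @export
extract_insert <- function(read, design) {
  stopifnot(is.character(read), length(read) == 1L,
            inherits(design, "nnk_design"))
  r <- .extract_inserts(read, design)
  list(insert = r$insert, reason = r$reason)
}

# Cheap structural scan of the 4-line records, run before parsing so a
# broken record can be reported by index (Biostrings tolerates some
# malformations, e.g. quality/sequence length mismatches).
.check_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ record at record ", length(lines) %/% 4L + 1L,
         " in ", path, ": truncated record", call. = FALSE)
  }
  for (i in seq_len(length(lines) %/% 4L)) {
    chunk <- lines[(4L * i - 3L):(4L * i)]
    if (!startsWith(chunk[1L], "@") || !startsWith(chunk[3L], "+") ||
        nchar(chunk[2L]) != nchar(chunk[4L])) {
      stop("malformed FASTQ record at record ", i, " in ", path,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.read_fastq_seqs <- function(path) {
  .check_fastq_structure(path)
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Table of accepted NNK inserts
#'
#' Container pairing distinct validated inserts with read counts, the design
#' they were validated against, and the [filter_report()] of the run. Mostly
#' produced by [run_preprocess()]; the constructor is exported so analytic
#' tables (e.g. exact codon-uniform input) can be built directly.
#'
#' @param inserts Character vector of distinct insert sequences.
#' @param counts Positive integer (or weight) vector, same length.
#' @param design An `nnk_design`; every insert must validate against it.
#' @param report Optional `nnk_filter_report`; defaults to an all-accepted
#'   tally of `sum(counts)` reads.
#' @return An object of class `nnk_insert_table`: list with `data`
#'   (data.frame `insert`, `count`), `design`, `report`.
#' @export
insert_table <- function(inserts, counts, design, report = NULL) {
  stopifnot(length(inserts) == length(counts), !anyDuplicated(inserts),
            all(counts >= 1))
  bad <- .validate_inserts(inserts, design)
  if (any(!is.na(bad))) {
    stop("invalid insert(s) for design '", design$name, "': ",
         paste(utils::head(inserts[!is.na(bad)], 3), collapse = ", "))
  }
  if (is.null(report)) report <- filter_report(sum(counts))
  stopifnot(inherits(report, "nnk_filter_report"),
            sum(counts) == report$accepted)
  ord <- order(inserts)
  structure(
    list(data = data.frame(insert = inserts[ord], count = counts[ord]),
         design = design, report = report),
    class = "nnk_insert_table"
  )
}

#' @export
print.nnk_insert_table <- function(x, ...) {
  cat("NNK insert table (design '", x$design$name, "'): ",
      nrow(x$data), " unique inserts, ", sum(x$data$count), " reads\n",
      sep = "")
  print(x$report)
  invisible(x)
}

#' Filter reads and tabulate accepted inserts
#'
#' Applies, in order, the exact barcode match, exact flank match, and insert
#' validation (length, NNK third bases, fixed cysteines, ambiguity), counting
#' each read under its first failing filter; identical accepted inserts are
#' aggregated with counts. Re-running on the same input is deterministic.
#'
#' @param fastq Path to a FASTQ file, a `DNAStringSet`, or a plain character
#'   vector of read sequences.
#' @param design An `nnk_design`.
#' @return An [insert_table()].
#' @examples
#' d <- library_design("L3", 3)
#' reads <- paste0(d$upstream_flank, c("GGTTAGATG", "GGTTAGATG", "GGTTAAATG"),
#'                 d$downstream_flank)
#' run_preprocess(reads, d)
#' @export
run_preprocess <- function(fastq, design) {
  stopifnot(inherits(design, "nnk_design"))
  reads <-
    if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
      .read_fastq_seqs(fastq)
    } else if (methods::is(fastq, "DNAStringSet")) {
      as.character(fastq)
    } else if (is.character(fastq)) {
      fastq
    } else {
      stop("fastq must be a file path, DNAStringSet, or character vector")
    }
  total <- length(reads)
  reason <- rep(NA_character_, total)

  reason[!match_barcode(reads, design)] <- "barcode_mismatch"
  live <- is.na(reason)
  ext <- .extract_inserts(reads[live], design)
  reason[live][!is.na(ext$reason)] <- "flank_mismatch"
  inserts <- ext$insert[is.na(ext$reason)]
  v <- .validate_inserts(inserts, design)
  reason[is.na(reason)][!is.na(v)] <- v[!is.na(v)]
  accepted <- inserts[is.na(v)]

  rej <- table(factor(reason, levels = FILTER_REASONS))
  rep_ <- filter_report(total, stats::setNames(as.integer(rej), FILTER_REASONS))
  if (length(accepted)) {
    tab <- table(accepted)
    insert_table(names(tab), as.integer(tab), design, rep_)
  } else {
    structure(
      list(data = data.frame(insert = character(0), count = integer(0)),
           design = design, report = rep_),
      class = "nnk_insert_table"
    )
  }
}
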