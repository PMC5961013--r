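# Reporting layer: run the full QC pipeline on a FASTQ and serialize the
# results as TSV tables plus one JSON roll-up. Outputs carry no timestamps,
# so identical inputs give byte-identical files.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' JSON-ready summary of a bias report
#'
#' Flattens an `nnk_bias_report` into plain lists/vectors for
#' serialization. Every fraction in the summary can be re-derived from the
#' emitted tables.
#'
#' @param report An `nnk_bias_report`.
#' @return A named list.
#' @export
qc_summary <- function(report) {
  stopifnot(inherits(report, "nnk_bias_report"))
  list(
    tool = "nnkqc",
    version = as.character(utils::packageVersion("nnkqc")),
    design = report$design$name,
    n_random_codons = report$design$n_random_codons,
    constrained = report$design$constrained,
    theoretical_complexity = report$complexity,
    total_reads = report$report$total,
    accepted_reads = report$report$accepted,
    rejected_by_reason = as.list(report$report$rejected),
    total_peptides = report$total_peptides,
    unique_peptides = report$unique_peptides,
    stop_class_reads = as.list(report$stop_class$reads),
    stop_class_unique = as.list(report$stop_class$unique),
    uag_observed = report$uag_observed,
    uag_observed_unique = report$uag_observed_unique,
    uag_expected = report$uag_expected,
    uag_expected_adjusted = report$uag_expected_adjusted,
    max_position_chisq = max(report$deviation$chisq),
    aa_normalized = as.list(unclass(report$aa_normalized))
  )
}

#' Run the QC pipeline and write its reports
#'
#' Filters the reads ([run_preprocess()]), translates and classifies them
#' ([tabulate_peptides()]), assembles the bias diagnostics
#' ([build_bias_report()]), and writes `filter_report.tsv`,
#' `peptides.tsv`, `composition.tsv`, `deviation.tsv`,
#' `aa_distribution.tsv`, `overrepresented.tsv`, and `summary.json` into
#' `out_dir`. An input with zero accepted reads yields the filter report
#' and a minimal summary, with a warning.
#'
#' @param fastq FASTQ path (or reads; see [run_preprocess()]).
#' @param design An `nnk_design` or path to a design YAML.
#' @param out_dir Output directory (created if missing).
#' @param amber_as_q Logical; translate TAG as Gln.
#' @param top_k Rows in the over-representation report.
#' @return Invisibly, the `nnk_bias_report` (or the bare `nnk_insert_table`
#'   when nothing was accepted).
#' @export
run_qc <- function(fastq, design, out_dir, amber_as_q = TRUE, top_k = 25L) {
  if (is.character(design)) design <- read_design(design)
  stopifnot(inherits(design, "nnk_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  it <- run_preprocess(fastq, design)
  fr <- it$report
  .write_tsv(data.frame(reason = c("accepted", names(fr$rejected)),
                        count = c(fr$accepted, unname(fr$rejected))),
             file.path(out_dir, "filter_report.tsv"))
  if (fr$accepted == 0L) {
    warning("no reads accepted for design '", design$name, "'")
    jsonlite::write_json(
      list(tool = "nnkqc",
           version = as.character(utils::packageVersion("nnkqc")),
           design = design$name,
           total_reads = fr$total, accepted_reads = 0L,
           rejected_by_reason = as.list(fr$rejected)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(it))
  }
  report <- build_bias_report(it, amber_as_q = amber_as_q, top_k = top_k)
  peps <- tabulate_peptides(it, amber_as_q = amber_as_q)
  .write_tsv(peps$peptides, file.path(out_dir, "peptides.tsv"))
  .write_tsv(as.data.frame(report$composition),
             file.path(out_dir, "composition.tsv"))
  .write_tsv(report$deviation, file.path(out_dir, "deviation.tsv"))
  .write_tsv(data.frame(residue = names(report$aa_normalized),
                        normalized = as.numeric(report$aa_normalized),
                        raw = as.numeric(attr(report$aa_normalized, "raw"))),
             file.path(out_dir, "aa_distribution.tsv"))
  .write_tsv(report$top_overrepresented,
             file.path(out_dir, "overrepresented.tsv"))
  jsonlite::write_json(qc_summary(report),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Load a synthesis model from YAML
#'
#' Fields `stock_n`, `stock_k`, `efficiency`, each a base-named map; missing
#' fields use the [synthesis_model()] defaults.
#'
#' @param path YAML file path.
#' @return An `nnk_synthesis_model`.
#' @export
read_synthesis_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- lapply(cfg, function(x) unlist(x))
  do.call(synthesis_model, args)
}

#' Load a host model from YAML
#'
#' Fields as in [host_model()] (`supE44` required).
#'
#' @param path YAML file path.
#' @return An `nnk_host_model`.
#' @export
read_host_model <- function(path) {
  do.call(host_model, yaml::read_yaml(path))
}

#' Load a pool specification from YAML
#'
#' A `members` list, each with a `design` map (fields of [library_design()]),
#' `titer` and `transformants`.
#'
#' @param path YAML file path.
#' @return An `nnk_pool_spec`.
#' @export
read_pool_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$members)) stop("pool spec must have a 'members' list")
  designs <- lapply(cfg$members, function(m) do.call(library_design, m$design))
  pool_spec(designs,
            titer = vapply(cfg$members, `[[`, numeric(1), "titer"),
            transformants = vapply(cfg$members, `[[`, numeric(1),
                                   "transformants"))
}
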