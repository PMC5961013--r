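test_that("composition profiles are exact on degenerate input", {
  d <- linear_design(1)
  it <- insert_table("GGT", 1, d)
  prof <- nucleotide_composition(it)
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$G, c(1, 1, 0))
  expect_equal(prof$T, c(0, 0, 1))
  expect_equal(unname(rowSums(prof[, c("A", "C", "G", "T")])), rep(1, 3))
  expect_error(nucleotide_composition(run_preprocess(character(0), d)),
               "empty")
  # constrained designs profile only the random core
  dc <- library_design("C1C", 1, constrained = TRUE)
  itc <- insert_table("TGTGGTTGT", 1, dc)
  expect_equal(nrow(nucleotide_composition(itc)), 3L)
})

test_that("chi-square deviations match hand-computed values", {
  d <- linear_design(1)
  # all-G at N positions with n = 100: (100-25)^2/25 + 3*(0-25)^2/25 = 300
  it <- insert_table("GGG", 100, d)
  dev <- composition_deviation(nucleotide_composition(it))
  expect_equal(dev$chisq[1:2], c(300, 300))
  # K slot 100% G with n = 100: 2 * 50 = 100
  expect_equal(dev$chisq[3], 100)
  expect_equal(dev$fold_G[1], 4)  # 1.0 / 0.25

  # K slot with 60/40 G/T at n = 100: (10^2 + 10^2)/50 = 4
  it2 <- insert_table(c("GGG", "GGT"), c(60, 40), d)
  dev2 <- composition_deviation(nucleotide_composition(it2))
  expect_equal(dev2$chisq[3], 4)
  # exactly expected counts: statistic 0 everywhere
  it3 <- insert_table(c("AAG", "CCG", "GGT", "TTT"), c(1, 1, 1, 1), d)
  dev3 <- composition_deviation(nucleotide_composition(it3))
  expect_equal(dev3$chisq, rep(0, 3))
  # row-order invariance
  it3r <- insert_table(c("TTT", "GGT", "CCG", "AAG"), c(1, 1, 1, 1), d)
  expect_equal(composition_deviation(nucleotide_composition(it3r)), dev3)
})

test_that("codon-uniform input gives the flat 1/21 normalized distribution", {
  d <- linear_design(1)
  it <- insert_table(nnk_codons(), rep(1, 32), d)
  dist <- normalized_aa_distribution(tabulate_peptides(it))
  expect_length(dist, 21L)
  expect_true("q" %in% names(dist))
  expect_equal(as.numeric(dist), rep(1 / 21, 21), tolerance = 1e-14)
  expect_equal(sum(dist), 1)
  expect_equal(round(dist[["G"]], 3), 0.048)

  # all-Gly input concentrates on G
  itg <- insert_table(c("GGG", "GGT"), c(1, 1), d)
  dg <- normalized_aa_distribution(tabulate_peptides(itg))
  expect_equal(unname(dg[["G"]]), 1)
  expect_equal(sum(dg[names(dg) != "G"]), 0)
  # raw frequencies come along
  expect_equal(unname(attr(dg, "raw")[["G"]]), 1)
})

test_that("brute-force enumeration confirms amber and residue expectations (n <= 3)", {
  for (n in 2:3) {
    ins <- enumerate_nnk_inserts(n)
    expect_length(ins, 32^n)
    # amber fraction by direct counting over all inserts
    cm <- vapply(seq_len(n), function(j) substr(ins, 3 * j - 2, 3 * j),
                 character(length(ins)))
    frac <- mean(apply(matrix(cm == "TAG", ncol = n), 1, any))
    expect_equal(expected_uag_fraction(n), frac, tolerance = 1e-12)
    # per-residue normalized frequencies are flat at 1/21 on the full census
    d <- linear_design(n)
    it <- insert_table(ins, rep(1, length(ins)), d)
    dist <- normalized_aa_distribution(tabulate_peptides(it))
    expect_equal(as.numeric(dist), rep(1 / 21, 21), tolerance = 1e-12)
  }
})

test_that("expected amber fraction is monotone with the right endpoints", {
  expect_equal(expected_uag_fraction(0), 0)
  expect_equal(expected_uag_fraction(1), 1 / 32)
  expect_equal(round(100 * expected_uag_fraction(10)), 27)
  v <- expected_uag_fraction(0:100)
  expect_true(all(diff(v) > 0))
  expect_gt(expected_uag_fraction(500), 1 - 1e-6)
  expect_error(expected_uag_fraction(-1))
})

test_that("over-representation ranking computes fold over mean copy number", {
  d <- linear_design(2)
  # 101 rows with distinct peptides, counts (100, 1 x 100):
  # total 200, top fold = 100/(200/101). Built from codons with unique
  # translations so nucleotide- and peptide-level uniqueness coincide.
  uniq_codons <- c("TGG", "ATG", "TTT", "TAT", "CAT", "ATT", "AAG", "AAT",
                   "GAT", "GAG", "TGT")
  pairs <- as.vector(outer(uniq_codons, uniq_codons, paste0))[1:101]
  it <- insert_table(pairs, c(100, rep(1, 100)), d)
  top <- overrepresentation_report(tabulate_peptides(it), top_k = 5)
  expect_equal(nrow(top), 5L)
  expect_equal(top$count[1], 100)
  expect_equal(top$fold[1], 100 / (200 / 101))
  expect_equal(top$fold[1], 50.5)
  # equal counts: all folds 1, ties broken lexicographically
  it2 <- insert_table(c("GGTGGT", "AAGAAG", "TTGTTG"), c(2, 2, 2), d)
  allr <- overrepresentation_report(tabulate_peptides(it2), top_k = 10)
  expect_equal(nrow(allr), 3L)  # top_k larger than table
  expect_equal(allr$fold, rep(1, 3))
  expect_equal(allr$peptide, sort(allr$peptide))
})

test_that("bias reports tie the diagnostics together consistently", {
  d <- linear_design(10)
  set.seed(61)
  host <- host_model(supE44 = FALSE, display_burden = 0.1, generations = 19)
  sim <- simulate_library(d, host = host, n_clones = 5000, n_reads = 2e4,
                          error_rate = 0, aberrant_fraction = 0, seed = 61)
  tab <- run_preprocess(sim$reads$seq, d)
  rep <- build_bias_report(tab)
  # passage in a non-suppressing host enriches amber clones
  expect_gt(rep$uag_observed, rep$uag_expected)
  expect_equal(sum(rep$aa_normalized), 1)
  expect_equal(rep$complexity, 20^10)
  expect_equal(rep$total_peptides, tab$report$accepted)

  # without passage, the equimolar and composition-adjusted amber
  # expectations agree (amber enrichment is what skews composition above)
  sim0 <- simulate_library(d, n_clones = 5000, n_reads = 2e4, error_rate = 0,
                           aberrant_fraction = 0, seed = 62)
  rep0 <- build_bias_report(run_preprocess(sim0$reads$seq, d))
  expect_lt(abs(rep0$uag_expected_adjusted - rep0$uag_expected), 0.02)
})
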