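test_that("insert sampling follows the effective incorporation distribution", {
  d <- linear_design(3)
  set.seed(11)
  ins <- sample_nnk_inserts(d, n = 5)
  expect_true(all(nchar(ins) == 9L))
  expect_true(all(substr(ins, 3, 3) %in% c("G", "T")))

  # only-G efficiency forces G everywhere (K position included)
  g_only <- synthesis_model(efficiency = c(A = 1e-12, C = 1e-12, G = 1, T = 1e-12))
  set.seed(12)
  expect_equal(sample_nnk_inserts(d, g_only, 1), "GGGGGGGGG")

  # constrained designs get fixed cysteine codons
  dc <- constrained_design(2)
  set.seed(13)
  i2 <- sample_nnk_inserts(dc, n = 3)
  expect_true(all(substr(i2, 1, 3) == "TGT" & substr(i2, 10, 12) == "TGT"))

  # equal model: N-position base fractions converge to 0.25 within 3 sigma
  set.seed(14)
  n <- 1e5
  one <- sample_nnk_inserts(linear_design(1), n = n)
  for (p in 1:2) {
    frac <- table(factor(substr(one, p, p), levels = c("A", "C", "G", "T"))) / n
    expect_true(all(abs(frac - 0.25) < 3 * sqrt(0.25 * 0.75 / n)))
  }
  fk <- mean(substr(one, 3, 3) == "G")
  expect_lt(abs(fk - 0.5), 3 * sqrt(0.25 / n))
})

test_that("naive pools carry the analytic amber-codon fraction", {
  d <- linear_design(10)
  set.seed(21)
  pop <- build_naive_pool(d, n_clones = 1e4)
  expect_equal(nrow(pop$clones), 1e4)
  expect_true(all(pop$clones$weight == 1))
  p_exp <- 1 - (31 / 32)^10
  expect_lt(abs(uag_fraction(pop) - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / 1e4))

  # biased chemistry: the amber fraction follows the exact per-codon
  # product P(T) * P(A) * P(G) under the biased incorporation distribution
  for (eff in list(c(A = 2, C = 0.5, G = 1, T = 2),        # raises P(TAG)
                   c(A = 2/3, C = 0.625, G = 1, T = 2/3))) { # G-surplus
    biased <- synthesis_model(efficiency = eff)
    p <- incorporation_probs(biased)
    p_tag <- p$N[["T"]] * p$N[["A"]] * p$K[["G"]]
    set.seed(22)
    popb <- build_naive_pool(d, biased, n_clones = 1e4)
    p_exp_b <- 1 - (1 - p_tag)^10
    expect_lt(abs(uag_fraction(popb) - p_exp_b),
              3 * sqrt(p_exp_b * (1 - p_exp_b) / 1e4))
  }
  # a T/A-favouring chemistry pushes the amber fraction above the
  # equimolar expectation (per-codon TAG probability is monotone in
  # P(T at 1), P(A at 2), P(G at 3))
  pta <- incorporation_probs(synthesis_model(
    efficiency = c(A = 2, C = 0.5, G = 1, T = 2)))
  expect_gt(pta$N[["T"]] * pta$N[["A"]] * pta$K[["G"]], 1 / 32)
})

test_that("passage follows the closed-form amber enrichment", {
  # 12 amber clones and 88 stop-free clones, unit weights: f = 0.12
  d <- linear_design(2)
  clones <- c(rep("TAGAAG", 12), rep("GGTAAG", 88))
  pop <- structure(list(clones = data.frame(insert = clones, weight = 1),
                        design = d, synthesis = synthesis_model(),
                        host = NULL, seed = NA_integer_),
                   class = "nnk_population")
  expect_equal(uag_fraction(pop), 0.12)

  # supE44-: w_uag = 1, w_rec = 0.9, g = 19
  grown <- passage(pop, host_model(supE44 = FALSE, display_burden = 0.1,
                                   generations = 19))
  f_exp <- 0.12 / (0.12 + 0.88 * 0.9^19)
  expect_equal(uag_fraction(grown), f_exp, tolerance = 1e-12)
  expect_equal(round(f_exp, 3), 0.502)

  # neutral growth: burden 0 leaves weights and fraction unchanged
  neutral <- passage(pop, host_model(supE44 = FALSE, display_burden = 0,
                                     generations = 19))
  expect_equal(neutral$clones$weight, pop$clones$weight)
  expect_equal(uag_fraction(neutral), 0.12)

  # full suppression: amber clones share the burden, fraction unchanged
  full <- passage(pop, host_model(supE44 = TRUE, suppression_efficiency = 1,
                                  display_burden = 0.1, generations = 19))
  expect_equal(uag_fraction(full), 0.12, tolerance = 1e-12)

  # clone identity conserved; order-independent over clones
  expect_equal(grown$clones$insert, pop$clones$insert)
  perm <- sample(nrow(pop$clones))
  pop2 <- pop
  pop2$clones <- pop$clones[perm, ]
  grown2 <- passage(pop2, host_model(supE44 = FALSE, display_burden = 0.1,
                                     generations = 19))
  expect_equal(uag_fraction(grown2), uag_fraction(grown))

  # monotone in generations when supE44- and burden > 0
  fr <- vapply(c(0, 1, 5, 10, 19), function(g) {
    uag_fraction(passage(pop, host_model(FALSE, display_burden = 0.1,
                                         generations = g)))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))

  expect_error(passage(pop, host_model(FALSE, generations = -1)))
})

test_that("opal/ochre clones always take the unburdened wild-type phenotype", {
  d <- linear_design(2)
  pop <- structure(list(clones = data.frame(insert = c("TGAAAG", "GGTAAG"),
                                            weight = 1),
                        design = d, synthesis = synthesis_model(),
                        host = NULL, seed = NA_integer_),
                   class = "nnk_population")
  # even in a suppressing host, the TGA clone escapes the burden entirely
  grown <- passage(pop, host_model(TRUE, suppression_efficiency = 1,
                                   display_burden = 0.2, generations = 5))
  expect_equal(grown$clones$weight[1], 1)
  expect_equal(grown$clones$weight[2], 0.8^5)
})

test_that("emitted reads round-trip through preprocessing when clean", {
  d <- linear_design(4)
  set.seed(31)
  pop <- build_naive_pool(d, n_clones = 50)
  reads <- emit_reads(pop, 500, error_rate = 0, aberrant_fraction = 0)
  tab <- run_preprocess(reads$seq, d)
  expect_equal(tab$report$accepted, 500L)
  expect_equal(sum(tab$report$rejected), 0L)
  # extraction recovers each clone insert exactly
  expect_setequal(tab$data$insert, unique(reads$clone_insert))
  got <- tab$data$count[match(names(table(reads$clone_insert)), tab$data$insert)]
  expect_equal(got, as.integer(table(reads$clone_insert)))

  # aberrant_fraction = 1: nothing passes
  set.seed(32)
  bad <- emit_reads(pop, 200, error_rate = 0, aberrant_fraction = 1)
  expect_equal(run_preprocess(bad$seq, d)$report$accepted, 0L)

  # accepted fraction tracks 1 - aberrant_fraction binomially
  set.seed(33)
  mix <- emit_reads(pop, 1e4, error_rate = 0, aberrant_fraction = 0.3)
  acc <- run_preprocess(mix$seq, d)$report$accepted / 1e4
  expect_lt(abs(acc - 0.7), 3 * sqrt(0.3 * 0.7 / 1e4))
})

test_that("injected defects map onto the matching rejection reasons", {
  d <- linear_design(4)
  set.seed(34)
  pop <- build_naive_pool(d, n_clones = 30)
  reads <- emit_reads(pop, 2000, error_rate = 0, aberrant_fraction = 0.5)
  tab <- run_preprocess(reads$seq, d)
  rej <- tab$report$rejected
  expect_equal(unname(rej[["barcode_mismatch"]]),
               sum(reads$defect == "wrong_barcode"))
  expect_equal(unname(rej[["wrong_length"]]),
               sum(reads$defect == "insert_indel"))
  expect_equal(unname(rej[["non_nnk"]]), sum(reads$defect == "non_nnk"))
  expect_equal(tab$report$accepted, sum(reads$defect == "none"))
})

test_that("simulation is byte-deterministic under a fixed seed", {
  d <- constrained_design(6)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  host <- host_model(supE44 = FALSE)
  simulate_library(d, host = host, n_clones = 300, n_reads = 400,
                   error_rate = 0.01, aberrant_fraction = 0.1, seed = 99,
                   fastq = f1)
  simulate_library(d, host = host, n_clones = 300, n_reads = 400,
                   error_rate = 0.01, aberrant_fraction = 0.1, seed = 99,
                   fastq = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed gives different bytes
  f3 <- withr::local_tempfile(fileext = ".fastq")
  simulate_library(d, host = host, n_clones = 300, n_reads = 400,
                   error_rate = 0.01, aberrant_fraction = 0.1, seed = 100,
                   fastq = f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})
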