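# nnkqc — randomness QC for NNK phage-display peptide libraries

Phage-display experiments — epitope mapping, serum antibody profiling,
computational epitope prediction — all rest on one assumption: that the
naive peptide library is random. Deep sequencing of real NNK-encoded
libraries shows it usually is not, for two reasons:

* **Amber-codon enrichment.** In type-88 display vectors, a UAG codon in
  the random insert aborts only the recombinant copy of the pVIII coat
  protein; the phage assembles with a wild-type coat and escapes the
  fitness cost of displaying a peptide. In hosts without the *supE44*
  amber suppressor, this advantage compounds every generation and
  UAG-bearing clones take over the library.
* **Phosphoramidite incorporation bias.** During oligonucleotide
  synthesis, G couples more efficiently than A, C or T, so an equimolar
  stock yields a G-rich library and a skewed amino-acid distribution.

`nnkqc` is for library builders and screeners who want to measure those
deviations from sequencing reads and correct them. It provides:

* strict read filtering (barcode / flanks / length / NNK / cysteine /
  ambiguity, in a fixed order, one reason per read);
* amber-aware translation and stop-class accounting;
* per-position nucleotide composition with chi-square deviations from the
  NNK expectation (25% per base at N slots, 50/50 G/T at K slots);
* the degeneracy-normalized amino-acid distribution, flat at
  **1/21 ≈ 0.048** per residue class for a perfectly random library
  (20 amino acids plus amber-derived Gln);
* analytic amber expectations — an insert of *n* equimolar NNK codons
  contains ≥1 UAG with probability **1 − (31/32)ⁿ** (27% at *n* = 10);
* a calibration solver: from observed composition, fit per-base
  incorporation efficiencies (`eff ∝ observed/stock`, G ≡ 1) and solve the
  compensating stock mix (`stock ∝ target/eff`);
* adjusted-complexity pooling for multi-length library mixes
  (copies per unique clone equalized via the coupon-collector expectation
  `C(1 − (1 − 1/C)ᵀ)`);
* a deterministic simulator implementing both bias mechanisms, used
  throughout the tests.

## Worked example

Simulate a constrained C10C library synthesized with a G incorporation
advantage, filter it, diagnose it, and compute the corrective mix:

```r
library(nnkqc)

design <- library_design("C10C", 10, constrained = TRUE)
biased <- synthesis_model(efficiency = c(A = 2/3, C = 0.625, G = 1, T = 2/3))
simulate_library(design, synthesis = biased,
                 n_clones = 20000, n_reads = 50000,
                 error_rate = 0.001, aberrant_fraction = 0.05,
                 seed = 42, fastq = "library.fastq")

inserts <- run_preprocess("library.fastq", design)
#> NNK insert table (design 'C10C'): 18900 unique inserts, 45587 reads
#> Filter report: 45587/50000 reads accepted
#>   barcode_mismatch 1081
#>   flank_mismatch   1066
#>   wrong_length     863
#>   non_nnk          1124
#>   missing_cys      279

report <- build_bias_report(inserts)
#> NNK library bias report -- design 'C10C'
#>   reads accepted: 45587/50000; unique inserts: 18900; theoretical complexity: 1.02e+13
#>   amber content: observed 0.259 (read-weighted) vs expected 0.272 (equimolar), 0.263 (bias-adjusted)
#>   stop classes (reads): no_stop 0.741, uag_only 0.259, other_stop 0.000
#>   max position chi-square: 2235.9; max |normalized AA - 1/21|: 0.0409

calibrate_from_library(report)
#> NNK synthesis calibration
#>   fitted efficiencies  N = A:0.67 C:0.63 G:1.00 T:0.67
#>   fitted efficiencies  K = G:1.00 T:0.67
#>   compensating stock   N = A:1.50 C:1.60 G:1.00 T:1.50
#>   compensating stock   K = G:1.00 T:1.50
#>   residual vs equimolar target: 0.00e+00
```

Reading the output: the filter rejected 8.8% of reads, one reason each,
matching the 5% injected defect rate plus substitution-error losses. The
amber fraction (25.9%) sits at the equimolar expectation (27.2%) because
this library was never passaged through a non-suppressing host — growth
bias and chemistry bias are separable. The position chi-squares, however,
are enormous (up to ~2,200 on ~45,000 reads: G near 34% at N slots where
25% is expected), and the calibration recovers the simulated efficiencies
(1, 2/3, 2/3, 0.625) and prescribes the compensating stock
**N = G:1.0, A:1.5, T:1.5, C:1.6 and K = G:1.0, T:1.5** — re-synthesizing
with that mix flattens the composition.

Pooling a 6-mer with the C10C library so every unique clone gets the same
expected copy number:

```r
mix <- adjusted_mix(pool_spec(list(library_design("L6", 6), design),
                    titer = c(1e10, 1e10), transformants = c(1e7, 1e7)),
                    target = 1e9)
#>   name complexity transformants unique_effective     phage  volume copies_per_unique
#> 1   L6  6.400e+07         1e+07          9257899 480732681 0.04807             51.93
#> 2 C10C  1.024e+13         1e+07          9999995 519267319 0.05193             51.93
```

The 6-mer's 10⁷ transformants partially saturate its 6.4×10⁷ peptides
(only ~9.26×10⁶ expected unique clones), so it receives proportionally
fewer phages; copies per unique clone are exactly equal.

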