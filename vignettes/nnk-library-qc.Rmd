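---
title: "Randomness QC for NNK phage-display peptide libraries"
author: "nnkqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomness QC for NNK phage-display peptide libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnkqc)
```

## The problem

Phage-display peptide libraries are screened on the assumption that the
naive library presents peptides at random: every residue equally likely at
every position, every clone at comparable copy number. Deep sequencing of
real NNK-encoded libraries shows that this assumption fails in two
systematic ways.

1. **Amber-codon enrichment.** In a "type 88" display vector, both a
   wild-type and a recombinant copy of the major coat protein (pVIII) sit
   on the same genome. An amber codon (UAG) in the random insert aborts
   translation of the recombinant copy only; the phage is still assembled,
   now with a pure wild-type coat, and escapes whatever fitness cost the
   peptide fusion imposes. In a host without the *supE44* suppressor this
   cost asymmetry compounds every generation, so UAG-bearing clones
   over-grow the rest of the library. With *supE44* (UAG read through as
   glutamine) the asymmetry largely disappears.
2. **Phosphoramidite incorporation bias.** During chemical synthesis of
   the degenerate oligonucleotide, the four phosphoramidites do not couple
   with equal efficiency: G incorporates noticeably better than A, C or T.
   An equimolar stock therefore yields a G-rich library, which propagates
   into excess of the amino acids encoded with G and a distorted overall
   composition.

`nnkqc` quantifies both effects from sequencing reads, computes the
analytic expectations they should be compared against, and computes the
two correctives: compensating phosphoramidite stock ratios, and mixing
proportions for multi-length library pools. A deterministic simulator
generates reads under configurable versions of both mechanisms, so every
stage of the pipeline is exercised by tests without any external data.

## NNK coding machinery

An NNK codon has any base at positions 1–2 and G or T at position 3:
32 codons covering all 20 amino acids. A point worth stating explicitly,
because it drives all the arithmetic below: **TAG (amber) is the only stop
codon reachable by NNK** — TAA and TGA both end in A. Consequently:

* the probability that an insert of $n$ equimolar NNK codons contains at
  least one amber codon is $1 - (31/32)^n$ (`expected_uag_fraction()`),
  which is 27% for $n = 10$;
* under amber suppression every one of the 32 codons codes, and the
  natural residue classes are the 20 amino acids plus the amber-derived
  glutamine as its own 21st class (labelled `q`), with codon degeneracies
  summing to 32.

The `normalized_aa_distribution()` statistic divides the read-weighted
residue frequency by that degeneracy and renormalizes, so a perfectly
codon-uniform library is flat at $1/21 \approx 0.048$ for all 21 classes.
Normalizing this way — rather than over 20 classes with glutamine's
degeneracy set to 2 — is what makes the flat reference value $1/21$; the
merged convention would give $1/20$ and hide amber-derived glutamine, the
single most diagnostic residue class. The merged degeneracy table is still
available from `nnk_degeneracy_table("amber_as_q")`.

Stop-class accounting (`classify_stops()`) still recognises TGA/TAA as a
distinct `other_stop` class with precedence over `uag_only`. On
NNK-validated inserts this class is structurally zero; it becomes non-zero
only when validation is bypassed or relaxed, and is kept for robustness on
such inputs.

## The simulator and its defaults

The generator composes three stages, all driven by one integer seed
(identical seed, identical bytes):

* **Synthesis** (`synthesis_model()`): each random-position base is drawn
  with probability proportional to `stock ratio × incorporation
  efficiency`. The model is single-step and multiplicative with no
  neighbour effects — there is no established chemical mechanism for the G
  surplus, and this is the simplest model whose exact corrective is a
  per-base stock ratio, which is precisely the corrective used in
  practice. Defaults are equimolar stocks and equal efficiencies (the
  intended ideal); the documented G-biased setting uses efficiencies
  (G 1, A 2/3, T 2/3, C 0.625), chosen because their exact compensating
  mix is the published-style ratio N = G:1.0, A:1.5, T:1.5, C:1.6 and
  K = G:1.0, T:1.5.
* **Passage** (`host_model()`, `passage()`): deterministic expectation
  dynamics; each clone's weight is multiplied by
  $\mathrm{fitness}^{\mathrm{generations}}$. Fitness is 1 for clones whose
  recombinant coat protein is never made (any non-suppressed stop),
  $1 - s\,b$ for amber-only clones under suppression efficiency $s$ and
  display burden $b$, and $1 - b$ for stop-free clones. Defaults:
  $b = 0.1$ per generation, $s = 0.9$ for *supE44*⁺ hosts (suppression is
  known to be incomplete), 0 otherwise, and 19 generations (roughly one
  per hour of overnight growth). With these values a naive 10-mer library
  (27% amber) grows to ~70–75% amber in a non-suppressing host while
  remaining essentially unchanged under full suppression — the qualitative
  host-strain contrast the model is meant to reproduce. A stochastic
  birth–death mode is deliberately out of scope: the claims being tested
  are about expected fractions, and expectation dynamics make every test
  deterministic.
* **Sequencing** (`emit_reads()`): reads sampled proportionally to clone
  weight, fixed amplicon layout, uniform substitution errors (default
  0.001 per base), and a configurable fraction of aberrant reads (default
  0.05) carrying one defect each — a ±1 nt indel in the insert, a barcode
  substitution, or a non-NNK third base — so that every rejection path of
  the filter is exercised by realistic inputs. Quality scores are constant
  Q40; indels outside the aberrant channel, PCR bias and chimeras are not
  modelled.

What the simulator does *not* emulate: the observed ~12% amber fraction at
1 h of growth (well below the naive 27% expectation, and unexplained);
length-dependent display burden (exposed as a user-settable scalar, not
fitted); quality-score structure; reverse-strand reads. Passing tests
therefore demonstrate correctness of the statistics and the two bias
mechanisms as modelled, not fidelity to every artefact of real runs.

## Filtering

`run_preprocess()` applies, in a fixed order, with exact matching:

1. barcode at its fixed offset, 100% fidelity;
2. upstream flank anchored at the read start and downstream flank at the
   read end, zero mismatches;
3. insert length; NNK third bases; fixed cysteines (constrained designs);
   ambiguous base calls.

Each read is counted under exactly one (first-failing) reason, making
tallies conservative and reproducible; `accepted + rejected = total` holds
on every input. Anchoring both flanks at the read ends means an indel
inside the insert leaves the flanks intact and is reported as
`wrong_length` — the defect class it actually belongs to — rather than as
a flank artefact. Base qualities are ignored: the criteria are purely
sequence-based. Reads containing N in the insert are rejected, not
imputed.

## Calibration

`calibrate_from_library()` is the computational analogue of calibrating
stock mixes against a known-equimolar reference measurement, with the
sequenced base composition playing the role of the readout:

* `fit_efficiencies()`: from observed composition and the stock that
  produced it, $e_b \propto p_b / s_b$, normalized to $e_G = 1$
  (efficiencies are identifiable only up to scale);
* `solve_stock_ratios()`: $s_b \propto t_b / e_b$, normalized to
  $s_G = 1$, so the corrected mix hits the target composition exactly in
  the model.

N-slot composition is pooled across positions (a single efficiency vector
is assumed shared across cycles; per-position spread is visible in the
composition table as residual heterogeneity and is not fitted). Calibrate
from a **naive, non-passaged** library: amber enrichment during growth
skews T/A/G composition upwards and would be misattributed to chemistry.
Parameter recovery on simulated reads converges as $1/\sqrt{n}$; at
$10^5$ reads the solved ratios are within a few percent of truth.

## Pooling

For a mixed multi-length pool, `adjusted_mix()` equalizes expected copies
per unique clone: member $i$ receives $N_i \propto U_i$ phages. How many
*unique* clones a member has is not observable directly, and the field's
phrase "same number of copies per unique peptide" does not fix an
operationalization, so the package makes one explicit: $U_i$ is the
coupon-collector expectation
$C_i\,(1 - (1 - 1/C_i)^{T_i})$ of distinct clones among $T_i$
transformants drawn from $C_i = 20^{n_i}$ peptides, capped by $T_i$. This
matters only for short libraries, whose sequence space saturates; for
$T_i \ll C_i$ it reduces to $U_i = T_i$, and a `plain` mode using
transformant counts directly is provided for users who prefer the
assumption-free version. The expectation is computed in log space
(`expm1`/`log1p`) so it is exact to machine precision at complexities of
$10^{13}$ and beyond.

## Numerical and design choices

* Theoretical complexity is the amino-acid-level $20^n$ (the convention in
  library datasheets); nucleotide-level $32^n$ is exposed separately.
* Uniqueness in peptide tables is nucleotide-level (synonymous NNK codons
  exist); peptide-level aggregation is used only in the
  over-representation ranking, where ties break lexicographically.
* The constrained-design cysteine codon defaults to TGT (itself
  NNK-compatible) and is configurable; which codon real constructs use is
  generally not stated by suppliers.
* Chi-square composition deviations are reported as descriptive statistics
  only — no p-values, no multiplicity correction — since the questions
  asked of them are about effect size, not significance.
* Empty tables yield `NaN` fractions (never silently 0); degenerate
  compositions (a base absent) abort calibration with a diagnostic rather
  than returning an infinite efficiency.
* All coordinates are 0-based half-open at the API surface (barcode
  offset); codon indices in reports are 1-based, matching how positions
  are discussed at the bench.

## Problem sizes used by the test-suite

Monte-Carlo checks run at $10^5$ reads/clones for composition convergence
and calibration recovery (binomial $3\sigma \approx 0.004$ per position;
a simultaneous $4\sigma$ bound is used where ~56 position×base marginals
are checked at once), $10^4$ for amber-fraction checks, and exhaustive
enumeration of all $32^n$ inserts for $n \le 3$ as the brute-force oracle
for the amber and residue expectations. These sizes make the statistical
assertions sharp while keeping the default suite fast.

## Known limitations

* The growth model is deterministic; drift in small populations and
  jackpot effects are not represented.
* The incorporation model has no positional or neighbour dependence; real
  synthesis may have cycle-dependent efficiency drift, which would appear
  here as residual per-position heterogeneity after correction.
* The filter is strict fixed-offset matching; it will discard reads from
  layouts with length-variable upstream regions (none of the supported
  designs have them).
* `other_stop` fractions are zero by construction on validated NNK data;
  observing UGA/UAA stops requires analysing unvalidated reads or
  translated flanking regions, which the package does not do.
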