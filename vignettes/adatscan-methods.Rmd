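---
title: "Methods: detecting and scoring I34-tRNA-dependent low-complexity regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and scoring I34-tRNA-dependent low-complexity regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adatscan)
```

## The biological model

Eukaryotic tRNAs for Thr, Ala, Pro, Ser, Leu, Ile, Val and Arg
(TAPSLIVR) carry inosine at the anticodon wobble position (I34),
produced by the ADAT2/ADAT3 deaminase from genomically encoded A34
precursors. By wobble pairing, an I34 anticodon reads the U-, C- and
A-ended codons of its box; `adatscan` calls these 24 codons
*ADAT-sensitive*. The 37 sense codons encoding TAPSLIVR amino acids
are the universe within which ADAT sensitivity is scored. The four
codon classes (`ADAT`, `TAPSLIVR_NON_ADAT`, `OTHER`, `STOP`) partition
the 64 codons as 24/13/24/3.

The package quantifies the hypothesis that proteins with
low-complexity regions composed largely of TAPSLIVR residues — mucin
type domains and other adhesion/ECM proteins — are preferentially
dependent on the I34 decoding route, and that their phylogenetic
distribution tracks A34-tRNA gene content.

The 24-codon set is reconstructed from the eight I34 anticodons and
the wobble rule, not from a printed enumeration; it is exposed as
`adat_codons()` and treated as configuration, so an alternative set
can be scored without code changes.

## Region detection

A *low-complexity TAPSLIVR-rich region* is a protein segment of at
least `window` residues in which at least `min_fraction` of residues
(in any combination) are TAPSLIVR. The detector slides a window of
exactly `window` residues (default 30) with step 1; a window qualifies
when its TAPSLIVR count is at least `ceiling(min_fraction * window)`
(24 of 30 at the 0.80 default — the threshold is inclusive, "at least
80%"). Overlapping or adjacent qualifying windows are merged by
coordinate union into maximal regions.

Design choices that were genuinely open, and how they were resolved:

* **Window semantics.** Fixed-length windows that are union-merged is
  the simplest formalization that yields regions "of 30 or more amino
  acids"; the brute-force oracle used in the tests implements the same
  definition independently (explicit per-window counting), so the fast
  cumulative-sum implementation is checked against it exactly on
  thousands of random sequences. An alternative formalization
  (maximal substrings of length ≥ 30 with overall fraction ≥ 0.80)
  gives different boundaries; anyone comparing counts against an
  external reference should be aware of the choice.
* **Merged-region fraction.** After union the overall fraction can
  fall below `min_fraction` (a merged region bridging a short
  TAPSLIVR-poor gap); it is reported but not used for re-filtering,
  because regions are defined by their qualifying windows.
* **Monotonicity.** Lowering `min_fraction` can only extend coverage,
  and the tests assert this. Shrinking the *window* is not monotone:
  a qualifying 30-window need not contain any qualifying 20-window,
  and each qualifying window covers fewer residues, so coverage can
  both grow and shrink. This is a property of the union
  formalization itself, not of the implementation.
* **Coordinates.** 0-based half-open everywhere in tables; only
  human-readable report columns would use 1-based inclusive, clearly
  labelled.
* **Ambiguity codes.** `X` (and anything coerced to it on input) is
  never counted as TAPSLIVR — detection is conservative.

With fully saturated planted regions (fraction 1.0) between
non-TAPSLIVR spacers, the union extends each planted segment by
exactly `window - ceiling(min_fraction * window)` = 6 residues on each
side, because windows overhanging the boundary by up to 6 residues
still contain 24 TAPSLIVR positions. The synthetic-data recovery tests
assert this margin exactly rather than treating coordinates as fuzzy.

## Enrichment scoring and the threshold

For a coding region, `adat_enrichment()` reports the percentage of
*TAPSLIVR codons* that are ADAT-sensitive. The denominator choice
matters: under uniform usage of the 61 sense codons the expectation is
100 × 24/37 = 64.865%, and the human codon-usage table shipped with
the package gives `derive_threshold(human_codon_usage())` ≈ 65.76%,
mutually consistent with the 65.743% default threshold
(`ADAT_THRESHOLD_DEFAULT`) only under this reading. The default
constant is retained as shipped even though the bundled usage table
reproduces it only to about 0.02 percentage points — codon-usage
tables differ slightly between compilations, and the threshold is
configuration, not a derived quantity. The comparison is strict
(`> threshold`), and regions without TAPSLIVR codons are flagged
undefined rather than scored.

## CAI, GC and reporter recoding

`cai()` is the classic geometric mean of relative adaptiveness
`w(c) = usage(c) / max(usage over c's synonyms)`, excluding stops and
the single-codon families (Met, Trp), with a configurable floor
(default 0.01) for zero-usage codons to avoid `log(0)`. It is
invariant to rescaling usage within each synonymous family, which the
tests assert.

`recode_tapslivr()` rewrites every TAPSLIVR codon to one canonical
synonym per amino acid: C-ended `ACC, GCC, CCC, TCC, CTC, ATC, GTC,
CGC` or G-ended `ACG, GCG, CCG, TCG, CTG, GTG, CGG`. Isoleucine has no
G-ended codon (ATG is Met); the default fallback keeps ATC — which is
C-ended in both variants, preserving the GC parity of the pair — and
counts the positions in `n_fallback` (`ATT` and `keep` are available).
Because the C/G synonym pairs differ only by a third-position C↔G
swap, the two recoded variants of any CDS have identical GC content by
construction, mirroring the matched-GC design used for expression
reporters. Translation invariance is asserted inside the function and
property-tested on random CDS.

`build_reporter_pair()` backtranslates a protein (by default the
standard 239-residue EGFP) with each amino acid's most-used human
codon, then produces the C-/G-ended pair. The published reporter pair
for EGFP is described as 239 codons of which 88 encode TAPSLIVR
(36.8%), with GC 61.8% and CAI 0.761/0.759; the canonical EGFP protein
contains 101 TAPSLIVR residues, and the exact plasmid sequences are
distributed only in supplementary listings, so the bundled scaffold
reproduces the structural guarantees (same protein, GC parity, 100%
ADAT sensitivity of the C variant, 239 codons) but not those printed
values. Supplying the actual reporter CDS through `read_fasta()`
feeds the same metric functions.

## Homolog-distribution statistics

Hits arrive as BLAST outfmt-6 tables. Filtering collapses duplicate
(query, subject) HSP pairs to the best e-value, caps each query at
10000 accepted hits *before* the score filters (mirroring search-tool
behaviour; the order is configurable by calling the steps directly),
then requires e-value ≤ 0.01 and aligned-query-coverage ≥ 0.20
(subject coverage is ignored).

The "average ratio" between species groups is computed as the ratio of
the two across-query means of per-genome hit rates, not the mean of
per-query ratios: per-query ratios are undefined whenever a query has
no hits in the denominator group, and a pooled ratio matches how a
single headline number is normally reported. Per-genome normalization
makes the statistic invariant to duplicating a group's genomes
together with their hit columns (property-tested).

`permutation_ratio_test()` draws B random query sets of the same size
without replacement, computes the null mean and SD of the ratio, and
reports a z-score p-value. The tail direction is an explicit
`alternative` argument with default `"less"` (is the query set's ratio
*depleted* relative to random sets?), rather than folding to the
observed direction: a fixed one-sided test has uniform p-values under
the null (asserted by the calibration tests), whereas
observed-direction folding would double the small-p rate. The
empirical tail proportion is reported alongside the normal
approximation, which is what allows extreme bounds (p far below 1/B)
to be quoted. A degenerate null (SD 0, e.g. when the query set is the
whole universe) reports z = 0 when the observed value equals the null
mean, and flags the p-value rather than inventing one.

Presence screening re-uses the region detector on homolog sequences: a
(query, species) pair counts only when some homolog itself contains a
detectable TAPSLIVR-rich region. Phylum normalization divides the
number of positive species by the phylum's species count.
`multicellular_compare()` reports the fold-change of medians
(multicellular/unicellular), a two-sided Mann-Whitney U test (with R's
tie correction; completely tied samples are reported as p = 1 since
the tie-corrected statistic is 0/0), and the permutation arm on the
unicellular/multicellular average ratio. `trna_spearman()` excludes
species with more than 400 A34-tRNA genes (strictly greater; 400 is
retained) and reports them.

## Translation-efficiency enrichment

`classify_te()` follows the printed thresholds literally: impaired
means interaction fold-change < 1.5 with p < 0.05 on the fold-change
scale of the consumed table, and a relaxed mode classifies by
fold-change sign only (above/below 1), because both conventions are
used in such analyses. "Highly translated in control" takes the
control fold-change > 1.5, adding a significance filter only when a
`p_ctrl` column is present — both readings occur, and the
threshold-only form is the default for the 31-gene style selection.

`fisher_enrichment()` is the exact hypergeometric two-sided test
(`stats::fisher.test`), cross-checked in the tests against a
brute-force enumeration of all 2×2 tables with fixed margins; the
odds ratio is the raw sample odds ratio, Haldane-corrected only when a
zero cell makes it undefined. `permutation_proportion_test()` draws B
random n-gene sets and reports the proportion with an annotated
fraction at least the observed one (inclusive ≥ by default — the
conservative convention; strict > and add-one smoothing are options).
Its B→∞ limit is the hypergeometric upper tail, asserted at B = 10000
within Monte-Carlo error. Being a discrete, inclusive empirical
p-value it is *super-uniform* (P(p < a) ≤ a), so its null calibration
is checked as a one-sided bound; the continuous z-based ratio test is
checked against the two-sided binomial band.

## What the synthetic data does and does not emulate

The generators reproduce the statistical structure the analyses
assume: planted regions with known coordinates and composition,
usage-weighted codon sampling with controllable ADAT bias, Poisson hit
counts with group-specific rates (a negative-binomial option would be
the natural extension for overdispersed real search output), decoy
hits that fail the filters, monotone A34-tRNA links on realized
homolog counts, and normal log fold-changes with matching two-sided
p-values. They do not emulate phylogenetic correlation between
species, indels or alignment artefacts, compositional biases of real
proteomes, or the mean-variance structure of real RNA-Seq fits — so
passing recovery tests demonstrates the statistics and their
implementation, not robustness to those real-data features. Spacers
between planted regions contain no TAPSLIVR residues at all, which
buys exact coordinate recovery at the cost of realism; background-only
proteins use a 20% TAPSLIVR rate, far enough below the 80% window
threshold that false positives are vanishingly rare (asserted across
seeds).

## Problem sizes and numerical choices

The test and acceptance workloads use 1000 random proteins (≤ 200
residues) for the oracle-equivalence check, 1000 random CDS for the
recoding invariants, 500 repetitions at B = 200 for null calibration,
B = 10000 for the hypergeometric comparison and B = 1000 for
planted-effect recovery — sizes chosen so the whole suite runs in
well under a minute while keeping Monte-Carlo bounds (3σ binomial)
meaningful. All randomness flows through explicit seeds via
`withr::with_seed`, so package functions never disturb the caller's
RNG state and every generator is byte-reproducible. Floating-point
tie handling in the permutation proportion uses a 1e-12 tolerance when
counting `>=` ties.

## Known limitations

* The genome-scale replications (the 2218-protein human TAPSLIVR set
  from CCDS release 22, and the orthology-database ratios derived
  from thousands of genomes) require external downloads and
  cluster-scale searches; the package exposes the exact statistics so
  they can be reproduced when those inputs are available.
* The canonical recoding synonym tables and the 24-codon ADAT set are
  reconstructions from the decoding rules, overridable by
  configuration.
* `read_blast_hits()` computes query coverage from aligned query span;
  gapped alignments with large internal gaps slightly overestimate
  coverage relative to summing aligned columns.
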