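---
title: "Methods: barcoded supF amplicon mutagenesis analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded supF amplicon mutagenesis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supfmut)
```

## The assay and its computational model

The supF forward-mutagenesis assay reads out mutations in a compact
*E. coli* amber-suppressor tRNA gene carried on a shuttle vector. In the
barcoded NGS variant of the assay, every vector molecule carries a random
12-nt barcode (N12-BC) between two fixed hexamer anchors (`GGCGAT` and
`ATCGAA`). After mutagen exposure and in vivo amplification, a ~355 bp
amplicon spanning the barcode and the supF region is PCR-amplified with
primers that carry a 6-nt sample index and a 0/1/2-nt random stagger, and
sequenced in 200 bp paired-end mode.

Because all reads sharing one (corrected) barcode descend from a single
plasmid lineage, a true mutation must appear in essentially all reads of
its barcode group, while stochastic base-calling errors appear in a
minority. The per-barcode supporting-read fraction — the variant
frequency, VF — therefore separates true mutations from sequencing error
without any quality-model machinery:

* observations with VF ≥ 0.1 are emitted as calls (and retained for
  diagnostics),
* calls with VF ≥ 0.4 are classified `true_mutation`, calls below it
  `sub_threshold` (the signature of position-specific base-calling
  errors),
* barcode groups with ≤ 9 reads are excluded from calling entirely.

Both thresholds are applied inclusively; the assay literature states the
call threshold as "equal to or greater than 0.1" and the discrimination
threshold as "around 0.4", and inclusive comparisons make the boundary
deterministic.

## Coordinates

supF coordinates are 1-based with negative positions upstream of supF
position 1 and **no position 0** — the window −19..214 contains exactly
233 positions. The analysis window −67..214 (281 positions) splits at the
−20/−19 boundary into the barcode cloning region (−67..−20, where
construction-derived variants concentrate) and the supF region (−19..214,
where the mutation frequency is measured). `map_coordinate()` and
`window_length()` implement the convention; all public outputs use supF
coordinates.

The full supF amplicon sequence is not machine-readable from the assay
literature, so the default reference (`supf_reference()`) is a
**synthetic** 355-nt amplicon: the published barcoding-oligo flanks
around an N12 slot, a handful of documented local sequence motifs
(`TTACC` at 53–57, `GTTCC` at 67–71, `GAG` at 73–75, `TTCGAA` at 115–120
and 123–128), and seeded-random fill elsewhere, constrained so each
anchor occurs exactly once. Real-data users load their own reference with
`read_reference()`. Phenotype-site annotation is an optional user-supplied
mask, never hard-coded.

## Pipeline stages and their parameters

1. **Demultiplexing** — exact 6-nt index match at stagger offsets 0/1/2
   on the index read, first hit wins; no mismatch tolerance. Exactness is
   auditable and the pre-designed indexes (pairwise Hamming ≥ 3,
   `default_indexes()`) make one miscall unambiguous anyway.
2. **Pair merging** — R2 is reverse-complemented and all overlaps
   ≥ 30 nt are scanned; the overlap with the most matching bases wins
   (ties → longest). Default mismatch-rate ceiling 0.1. Disagreements
   resolve by higher base quality, ties keep R1; `N` never counts as a
   match and always loses the consensus.
3. **Sense orientation** — a shared k-mer vote (k = 11) against the
   reference; reads are flipped when the reverse complement scores
   higher and discarded below a 30% shared-k-mer floor.
4. **Barcode extraction and correction** — the 12 nt strictly between
   the first exact `GGCGAT`/`ATCGAA` pair exactly 12 nt apart (a relaxed
   1-mismatch anchor mode exists behind a flag). The whitelist is built
   by directional collapse (a barcode within Hamming 1 of a ≥ 2×-more-
   abundant barcode is absorbed) with a count floor of 10, aligned with
   the > 9-reads filter; observed barcodes correct to a whitelist entry
   at Hamming distance ≤ 1, with ambiguity (two entries at distance 1)
   left unassigned rather than inventing a tie-break.
5. **Alignment and variant extraction** — global affine-gap alignment
   (match +2, mismatch −3, gap open −5, gap extend −2; a length-k gap
   costs 5 + 2k), compiled, with `N` in the reference (the barcode slot)
   as a wildcard. Ties prefer substitution over gap, reference gap over
   read gap, and gap extension over opening; indels are then
   left-aligned, so co-optimal gap placements collapse to one record.
   Reads under 60% alignment identity are flagged unalignable. The
   scoring is an amplicon-alignment default, configurable, not an assay
   constant.
6. **Classification** — six mutually exclusive types: SNS, DNS, 1-nt
   deletion, longer deletion, insertion, and deletion-with-insertion
   (all length-changing replacements plus same-length replacements of
   ≥ 3 nt, covering the UV "triplet" `GAG→AAA`).
7. **Spectrum and statistics** — strand-resolved 192-class trinucleotide
   spectra, type/substitution breakdowns, per-barcode multi-mutation
   profiles, the NGS mutation frequency, and the inter-SNS distance
   statistic.

### Why adjacent differences merge across one matching base

`GAG→AAA` aligns as mismatch–match–mismatch: the middle base is
unchanged. Treating only strictly contiguous difference columns as one
observation would split this documented single event into two SNSs, so
`extract_read_variants()` bridges difference runs separated by at most
one matching column (`merge_gap = 1`, configurable). Tandem `CC→TT`
remains a single DNS under either rule; substitutions three or more
positions apart remain separate observations.

## The synthetic-data generator

The simulator is first-class, tested code. It emulates the statistical
structure the pipeline assumes, not lesion photochemistry:

* `generate_library()` — unique random 12-mers in the anchor slot
  (barcodes containing an anchor hexamer are rejected so extraction
  stays well-posed on truth data).
* `apply_mutagenesis()` — per-molecule Bernoulli events at eligible
  sites: C→T at dipyrimidine (TC/CC) sites, tandem CC→TT, triplet
  GAG→AAA, 1-nt deletions, and a spontaneous background; `strand_bias`
  places lesions on the non-transcribed versus transcribed strand
  (appearing as G→A / GG→AA / CTC→TTT on the sense sequence), and `dose`
  scales the lesion classes. Defaults (3×10⁻⁴ per dipyrimidine site,
  2×10⁻⁵ per CC tandem and GAG triplet, 10⁻⁵ per-molecule 1-nt deletion,
  strand bias 0.5) give a supF mutation frequency of roughly 2×10⁻² per
  dose unit, the order observed on titer plates by the NGS readout.
  Events in one molecule are kept ≥ 3 positions apart and deletions are
  recorded left-aligned, so each injected lesion corresponds to exactly
  one normalized observation — distinct lesions colliding within 2 nt of
  each other in the same molecule are not a feature of the modelled
  regime.
* `synthesize_reads()` — per-barcode coverage (default uniform 200–250
  read pairs, matching the assay's design target), a per-barcode mutant
  fraction (1 = fixed mutation; 0.5 = heteroduplex-derived colony, the
  source of the bipolar VF distributions seen in real libraries), a
  uniform per-base miscall rate, and per-position per-read miscall
  overrides that reproduce position-specific base-calling errors such as
  the well-known supF positions 55 and 69. Errors are injected into the
  sequenced fragment before it is split into the pair, since the merged
  consensus is the analysis unit; the underlying per-read error rates at
  positions 55/69 are not published, so overrides are free parameters.
  The 0/1/2-nt random stagger is modelled on the index primer, whose
  offset demultiplexing must resolve; a reverse-primer stagger would
  only add ≤ 2 soft bases beyond the amplicon 3' end, outside the
  analysis window.

What the generator does **not** emulate: CPD/6-4PP kinetics, replication
and repair, colony growth, quality-score structure, chimeric PCR
artefacts, or large deletions/insertions that PCR cannot amplify. A green
suite therefore demonstrates correctness of the bookkeeping and
thresholds under the modelled read structure, not robustness to every
failure mode of real libraries.

## Spectrum bookkeeping

The 192 classes are all 12 substitution types × 16 flank combinations.
Each SNS is counted once in the non-transcribed view (context and
alleles read from the sense strand) and once in the transcribed view
(the reverse-complement transform: C→T in `TCA` appears as G→A in
`TGA`). The two views are exactly mutually derivable by
`strand_transform()`; strand-asymmetry statements are comparisons of the
same class label across views, and both totals equal the SNS record
count.

## Distance null

The "theoretically expected" inter-SNS distance is computed exactly: all
pairs of eligible sites enumerated, distance measured on sequence
indices (so the missing position 0 costs nothing). The eligible set
defaults to all C/G positions in the window because multi-mutation
substitutions come almost exclusively from C or G; it is configurable to
all positions or to a user-supplied site list. The observed-versus-null
comparison is a one-sided Wilcoxon rank-sum test.

## Numerical and design choices

* Wilson score intervals accompany mutation frequencies (point estimates
  alone are not actionable at n of a few hundred barcodes).
* The VF denominator is the number of reads covering the variant's
  span; reads with leading/trailing alignment gaps count as partial
  coverage and are excluded from numerator and denominator.
* Replicate merging (`merge_replicates()`) keeps a (barcode, variant)
  only when called in both duplicate PCR samples, reporting the mean VF.
* Two analysis-window presets exist (−67..214 default; −80..−20 upstream
  variants can be included by constructing the reference with a wider
  window) because the upstream boundary is reported differently between
  titer-plate and dose-series analyses.
* Position-specific error masking is deliberately **not** hard-coded: no
  blacklist of positions 55/69. Discrimination is purely VF-based.
* All simulation entry points take explicit seeds; the pipeline itself
  is deterministic, and rerunning a configuration reproduces
  byte-identical summaries.

## Problem sizes used in the shipped checks

The package's own verification runs use 10³ barcodes at coverage 200
(clean-path recovery), 300 barcodes at coverage 200 (positional-error
discrimination), 500 barcodes at coverage 30 (UV-signature spectrum
statistics), and 10³ seeded toy string pairs (alignment oracle) — sizes
chosen so each property is measured with comfortable statistical margin
on a single CPU.

## Limitations

* Variant calls are co-optimal-alignment representatives; a different
  scoring scheme can shift complex-event boundaries (the six-type
  classification is stable under left-alignment but not under arbitrary
  rescoring).
* The mutation frequency counts barcodes, not molecules; heteroduplex
  colonies (mutant fraction 0.5) still count once, as in the assay.
* Barcodes at Hamming distance ≤ 2 of each other can in principle
  cross-absorb during whitelist construction; with 12-nt random barcodes
  at the assay's 10⁴ complexity this is rare, and a known whitelist
  bypasses the issue.
* Large structural changes are invisible to an amplicon assay; the
  pipeline cannot and does not try to recover them.
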