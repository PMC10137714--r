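---
title: "Methods: tsRNA identification, classification and regulatory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tsRNA identification, classification and regulatory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrnaflow)
```

## Scope

`tsrnaflow` analyzes tRNA-derived small RNAs (tsRNAs) in bulk small-RNA
sequencing of a two-group design — the archetype being subcutaneous versus
visceral white adipose tissue with three replicates each. The pipeline runs
from reads to biology in nine stages: reference modeling, alignment,
classification, quantification, differential expression, seed-sequence
features, duplex-energy target prediction, anti-correlation network and
enrichment analysis, and parental amino-acid versus codon-usage correlation.
Every stage has a paired simulator with full ground truth, so each method is
testable against planted effects.

## Reference model

A `trna_gene_model` carries the gene sequence, the mature sequence (intron
spliced out, 3' CCA appended when not genomically encoded), the precursor
3' trailer left by transcription and removed by RNase Z, and cloverleaf
landmarks: D loop, anticodon loop, anticodon triplet, T loop, and the mature
3' end. All classification logic runs on these landmarks, not on hard-coded
offsets, so non-canonical geometries (e.g. mitochondrial tRNAs with unusual
loop positions) are handled by supplying the right landmark table. Precursor
coordinates extend the mature axis: trailer position one is `mature_end + 1`.
The fixed 76-nt archetype used throughout the documentation and tests is
`canonical_template()` (D loop 14–21, anticodon loop 32–38, anticodon 34–36,
T loop 54–60).

## Alignment

Reads are collapsed to distinct sequences with per-sample counts, optionally
adapter-trimmed, filtered to 15–45 nt, and placed gap-free on the sense
strand of every mature and precursor reference with at most one substitution.
All placements at the optimal mismatch level are kept; a read's count is
shared across its placements through equal fractional weights summing to one.
Precursor placements that lie entirely inside the mature region are
suppressed, because the mature-space placement represents them — only
trailer-overlapping placements carry information beyond the mature sequence.
The implementation is an exact substring hash index, so results are
byte-identical to a brute-force scan (a property the test suite checks
against an independent oracle).

## Classification

The nine-type decision table (tRF-5a/b/c, tRF-3a/b, tRF-1, i-tRF, tiRNA-5,
tiRNA-3) is deterministic given a placement:

* Precursor placements starting within two nucleotides after the mature end
  are tRF-1 (RNase Z trailer products); other trailer-overlapping placements
  are junction i-tRFs.
* 5'-anchored fragments (start ≤ 2) are divided by where they end: D loop →
  tRF-5a, before the anticodon loop → tRF-5b, inside the anticodon loop →
  tRF-5c or tiRNA-5, past it → tiRNA-5.
* 3'-anchored fragments (ending within one nucleotide of the CCA end) are
  tiRNA-3 when they start at or before the anticodon loop end, else tRF-3a
  (≤ 20 nt) or tRF-3b (longer).
* Everything else is i-tRF.

tRNA halves are defined by two constraints at once: anticodon-region cleavage
and half-molecule length (30–36 nt for the 5' half). On a canonically
numbered tRNA these interact — a 30-nt 5' half ends two positions *before*
the anticodon loop. The classifier therefore uses an anticodon *cleavage
window* spanning the loop plus the two adjacent 3'-stem positions
(`[loop_start - 2, loop_end]`): a 5'-anchored fragment is tiRNA-5 when its
end falls in this window and its length is 30–36 nt. In-loop fragments
outside the length band remain tRF-5c. `tirna5_length_bounds()` enumerates
this definition; on the canonical template the bounds are 30 and 36 nt.

Identical sequences merge into one record; the record's type is the
majority-weight label over its placements, with ties broken by the
lexicographically first label and flagged (`ambiguous_type`) rather than
hidden. Names follow `tRF-<AA>-<anticodon>-<serial>` with serials assigned by
descending abundance within each family. A record is mitochondrial only when
all parents are; mixed parentage is reported as cytosolic and flagged.

## Differential expression

Counts are library-size equalized by scaling each sample to the geometric
mean library size. For small feature panels where library size is known
externally (for instance a handful of features from a depth-matched
experiment), explicit `lib_sizes` should be supplied: column sums of a panel
in which most features are differential absorb the group effect into the
normalization. Per feature, the equalized group sums are compared by a
two-sided conditional exact test under a common-dispersion negative binomial
model: conditional on the total, the probability of each split is
proportional to the product of the two group-sum NB densities, and the
p-value sums all splits at least as unlikely as the observed one
(minimum-likelihood rule). At zero dispersion this is the exact binomial
test, which the implementation reproduces to machine precision. Two
numerical choices matter:

* Equalized group sums are real-valued; the exact test needs integers, so
  the sums are rounded. For the library sizes in scope the rounding
  perturbation is far below the discreteness of the test itself.
* Fold changes use a 0.5 pseudo-count on the group means; the pseudo-count
  never enters the test.

The common dispersion is a method-of-moments estimate: the pooled
within-group excess of variance over mean, divided by the pooled squared
mean. Significance follows the published rule — raw p ≤ 0.05 and
|log2 fold change| ≥ 1 — with Benjamini-Hochberg FDR reported alongside.
Calibration is checked on 10,000 simulated null features (lognormal means,
`meanlog = log(200)`, `sdlog = 1`, dispersion 0.1, three replicates per
group), where the type-I error at α = 0.05 must stay within [0.03, 0.07];
that generator was chosen to span the realistic abundance range rather than
to flatter the test.

## Target prediction and network

Candidate sites are exact Watson-Crick complements of regulator positions
2–7 (the seed; no G:U in the seed). Each site is extended 30 nt upstream on
the UTR and scored by a nearest-neighbor duplex dynamic program over gapped
antiparallel base-pair chains: Watson-Crick stacks carry standard
nearest-neighbor free energies, wobble-containing stacks a simplified flat
value, bulges and internal loops are penalized per unpaired nucleotide (3.0
and 1.5 kcal/mol, at most 4 per side), and a duplex initiation penalty of
4.09 kcal/mol is added. The DP is exact for this move set — the test suite
verifies equality with exhaustive enumeration on a thousand random pairs.
Hits are retained at ≤ −20 kcal/mol, the study's threshold; one best hit is
kept per regulator/gene pair.

Network edges require the regulator and the target to be differentially
expressed in opposite directions and negatively correlated across samples
(Pearson). A correlation p-value cut is available but off by default: with
three replicates per group, correlation p-values carry almost no
information, so the sign rule is the honest default. Enrichment uses the
upper-tail hypergeometric test (ORA) and a preranked GSEA with the classic
weighted running-sum enrichment score and a fixed-seed gene-label
permutation null.

## Amino-acid usage correlation

The parental amino-acid spectrum of a record set (per distinct tsRNA or
read-weighted; multi-parent records split fractionally; iMet folded into
Met, Sec excluded and renormalized) is correlated against the amino-acid
usage translated from coding sequences. Translation counts codons literally
— alternative initiator codons such as a leading CTG are not remapped to
Met — and excludes stops.

## Simulators

Every stage's simulator emits data *and* truth:

* `simulate_reference()` builds genes on canonical landmarks with random
  sequence, the assigned anticodon at 34–36, and roughly one gene in ten
  mitochondrial.
* `simulate_fragmentome()` draws fragments from per-type candidate pools
  without replacement. This design guarantees termination: some types have
  small admissible spaces (tRF-5c admits only a few cuts per gene, because
  in-loop 5' fragments of half length are tiRNA-5 by definition), and when a
  pool is exhausted the draw falls back to the remaining types, re-weighted
  by the mixture. Abundances are lognormal (`meanlog = log(50)`,
  `sdlog = 1.5`, concentrating reads in few fragments, as observed in real
  landscapes), counts negative binomial (dispersion 0.1), planted log2 fold
  changes lower the group-B mean, and sequencing errors substitute single
  bases.
* `simulate_regulatory_system()` plants perfect or seed-only sites on true
  target UTRs, expresses regulators higher in group B and anti-couples each
  target's mean to its regulator. Its libraries are depth-matched by
  construction and the known `lib_sizes` are returned — the correct input
  for testing a six-feature panel.
* `simulate_cds_with_aa_corr()` constructs the codon-usage vector to have
  *exactly* the target Pearson correlation with the parental spectrum: a
  second lognormal draw is orthogonalized against the standardized parental
  vector, the two are mixed with weights `r` and `sqrt(1 - r^2)`, and an
  affine positivity shift (which cannot change a Pearson correlation) plus
  integer rounding are the only deviations. Planting at the latent Gaussian
  level instead would make the realized correlation leverage-sensitive with
  only 20 amino-acid points (deviations up to ±0.13 per draw).

Generator defaults mirror the study design (3 vs 3, 44 genes, tRF-5c
dominant mixture, planted r = 0.7) and are fixed independently of any test
threshold.

## Problem sizes and determinism

The package targets desk scale: tens of references, thousands of distinct
reads, hundreds of tsRNA features. The end-to-end pipeline
(`run_pipeline()`) on the default configuration runs in well under a minute;
the heaviest internals are the exact test (10,000 features in seconds) and
the duplex DP (hundreds of site evaluations per run). All stochastic steps
consume a single configured seed, and identical configurations produce
byte-identical artifacts and manifests.
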