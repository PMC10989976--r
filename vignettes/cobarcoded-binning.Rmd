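---
title: "Binning-first assembly of cobarcoded metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning-first assembly of cobarcoded metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Cobarcoded libraries tag every short read derived from one long DNA
fragment with a shared barcode, so a barcode is (to a good approximation)
a sample of ~100 bp paired-end reads from one ~30 kb locus of one genome.
`cobin` exploits this to bin metagenomic reads by species *before*
assembly.

Three read regimes matter. Reads from species-specific sequence are
classified to the species by a k-mer classifier. Reads from inter-species
repeats carry k-mers present in several genomes and are classified to the
lowest common ancestor (LCA) of those genomes, above species rank. Reads
from sample sequence absent from every reference (unique genome-specific
regions) are unclassified. Only the first regime is directly usable for
binning; the other two are recovered through the barcode:

1. Reads classified exactly at species rank are the species' *taxonomy
   reads* (TRs). Assignments below species rank are first lifted to their
   species ancestor.
2. Every barcode attached to at least one TR is a candidate. For each
   candidate we record `Num_T`, the number of TRs of the target species in
   the barcode, and `Ratio_T = Num_T / (all reads of the barcode in the
   whole dataset)`. `Ratio_T`'s denominator is dataset-wide because it
   measures barcode purity: a colliding barcode that also carries another
   species' fragment has depressed `Ratio_T` even when `Num_T` is high.
3. Candidates are ranked by `Num_T` descending, then `Ratio_T` descending
   (ties broken by barcode id for determinism), and *whole barcodes* are
   collected down the ranking. Barcodes are atomic — splitting one would
   discard exactly the linkage information the library exists to provide —
   and collection stops after the first barcode whose inclusion brings the
   collected bases to at least `cap_coverage` (default 300×) times the
   reference length; that barcode is included. The cap exists purely to
   bound assembly cost for very abundant species.
4. A species is refined at all only if its estimated abundance — total TR
   bases divided by reference length — strictly exceeds
   `min_abundance` (default 10×), below which short-read assembly is
   hopeless anyway.

No minimum `Num_T` or `Ratio_T` is imposed by default: the ranking plus
the cap is the whole constraint. Optional `min_num_t` / `min_ratio_t`
knobs exist (off by default) for datasets where collision rates warrant a
hard floor. Reads with the null barcode `0_0_0` carry no linkage signal
and are excluded from candidacy; a flag can admit their TRs directly.

Each refined read set is assembled independently (any external assembler
via a `{fwd} {rev} {out}` command template, or the built-in toy de Bruijn
assembler). Collisions admit some foreign reads, so assemblies are
decontaminated against the species reference: per alignment, ANI =
100 × matches / alignment columns (match + mismatch + inserted + deleted —
the gap-inclusive identity reference evaluators report); per contig, AF =
merged length of query intervals of alignments with ANI strictly above
90%, divided by contig length; contigs with AF strictly above 50% are
retained. Both inequalities are strict, including at AF = 0.5.

## Evaluation procedures

*Genome fraction* is the merged reference coverage by alignments with
identity strictly above 95%, as a percentage of reference length. *N50*
is the largest contig length whose descending cumulative sum reaches half
the assembly; *NG50* the same against half the reference (0 when the
assembly is shorter than half the reference). NGA50 would require
misassembly-aware alignment breaking and is deliberately not reported.

*Valid fragments* proxy usable long-range information: per barcode and
reference, read-pair positions are clustered with a 50 kb gap cutoff (the
gap value is not dictated by the library chemistry; it is exposed as a
flag), and a cluster is valid iff it has strictly more than 5 read pairs
and spans strictly more than 10 kb.

On simulated data, *completeness* and *contamination* come from truth
labels: completeness is the fraction of the target sample genome covered
by contigs originating from it (origin by exact substring match, with a
k-mer majority vote and toy alignment as fallback for error-carrying
contigs); contamination is the fraction of contig bases originating
elsewhere. Marker-gene estimators used on real data are out of scope; the
tier thresholds are applied to whatever (completeness, contamination)
pair is supplied: high iff completeness > 90 and contamination < 5,
else medium iff completeness > 50 and contamination < 10, else low.

*Variants* are called from whole-genome alignments carrying extended
CIGARs (`=`/`X`/`I`/`D`), after discarding alignments whose reference
span is under 10 kb. Mismatch columns are SNVs. Single-base indels are
ignored entirely — neither SNV nor indel — so small indels are 2–49 bp
and large indels ≥ 50 bp. Variants sharing (species, reference, position,
ref, alt) across samples are shared variants. SNV density is reported per
100 kb of aligned reference; the unit is this package's convention, chosen
so densities are O(10) at percent-scale divergence.

## The simulator

The generator emulates what the method depends on, at desk scale:

- **Genomes**: i.i.d. uniform DNA references (default 50 kb — miniature,
  so the full pipeline runs in minutes) with shared repeat blocks copied
  verbatim between named species pairs; sample genomes add point
  substitutions at a per-species divergence and novel random insertions
  totalling `unique_insertion_fraction` of the genome (novel random
  sequence guarantees zero classifier hits, the unique-region regime).
  The taxonomy is a star of genera in which block-sharing species share a
  genus, so shared-block k-mers collapse to a genus LCA.
- **Library**: log-normal fragment lengths (median 30 kb, sdlog 0.35 —
  the canonical model for long-fragment libraries, and long enough to
  exercise the >10 kb valid-fragment rule), uniform fragment placement,
  read pairs of 2 × 100 bp at insert ~350 bp sampled at 0.3× per-fragment
  coverage (a read pair roughly every 670 bp of fragment), substitution
  sequencing errors (5e-4 default; no indel errors, keeping the toy
  assembler and the variant oracle exact), and barcodes assigned fresh
  per fragment except with probability `collision_rate` (0.005), when a
  fragment joins a uniformly chosen used barcode — the simplest mechanism
  that produces the false-positive reads decontamination exists to catch.
- **Truth**: every read carries its genome, fragment and region regime
  (species-specific / inter-species repeat / unique genome-specific; a
  pair is labelled repeat or unique only when both mates lie wholly
  inside such a region, since boundary-straddling reads carry
  species-specific k-mers).
- **Mock default**: ten species — eight at relative abundance 12% and two
  at 2% — scaled to a configurable total coverage (250× default, putting
  the majority members at 30× and the minority at 5×, below the 10×
  gate).

What it does not emulate: GC and amplification bias, realistic error
profiles, strains within a species, plasmids, rearrangements, or
reference databases that are wrong rather than merely incomplete. Passing
tests demonstrate the algorithmic contracts (ranking, capping, recall
through barcode recruitment, threshold semantics), not performance on
real gut microbiomes.

## Numerical and design choices

- **Classifier**: canonical k-mers (lexicographic min of the strand
  pair), k = 31; both mates pooled; each species leaf scored by summed
  hits along its root-to-leaf path; unique maximal leaf wins, and tied
  leaves resolve to their LCA — which is what places pure repeat reads at
  the genus. Zero hits → unclassified. Deterministic and
  permutation-invariant.
- **Toy assembler**: canonical k-mer counts (k = 31), count floor 2
  (drops singleton error k-mers at error rates ≤ 0.1%), maximal
  non-branching paths ≥ 2k bp, lexicographically smaller strand reported,
  contigs ordered by length then sequence for determinism.
- **Toy aligner**: exact 19-mer anchors (reference k-mers occurring > 10
  times are skipped), longest strictly-collinear chain per strand via
  patience LIS, same-diagonal anchors merged into exact runs, inter-run
  gaps closed by global pairwise alignment (match 1, mismatch −2, gap
  open 5, extend 2), gaps over 5 kb split the record, and contig-end
  flanks are attached only when their alignment identity reaches 60% so
  novel contig ends stay unaligned. Secondary chains are emitted for
  query regions the primary chain left uncovered.
- **Coordinates**: 0-based half-open everywhere internally; conversion
  only at format boundaries (PAF is already 0-based; VCF output is
  1-based and anchored).
- **Cap boundary**: "not more than 300×" is enforced pre-inclusion — the
  crossing barcode is included, then collection stops — so the refined
  set can exceed the cap by at most one barcode, and raising the cap
  never removes a previously collected barcode.
- **Degenerate inputs**: empty read sets assemble to empty contig sets;
  contigs without qualifying alignments get AF 0; an empty assembly has
  N50 = NG50 = 0; a species absent from the references is an error, and
  any per-species stage failure is recorded in the manifest without
  stopping other species.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
five- to ten-species communities of 50 kb genomes at 12–50× (about
30,000–63,000 read pairs), sizes chosen so an end-to-end run takes a few
minutes on one core while still exercising every regime: the abundance
gate (one species at 5×), the repeat LCA regime (a 1.5 kb shared block),
the unique-insertion regime (1–20% novel sequence) and collision-driven
contamination (0.5% collision rate). Production data is 3–6 orders of
magnitude larger; every stage is either linear in reads or per-species.

## Known limitations

The toy assembler has no scaffolding and no barcode awareness, so
contiguity on errored data understates what a production cobarcoding
assembler achieves; the toy aligner's identity estimates drift below the
planted identity when divergence exceeds ~15% (anchors become sparse);
the fixture classifier holds every reference k-mer in memory and is not
meant for genomes beyond a few Mb. Abundance estimation inherits the
classifier's blind spots: heavy inter-species repeat content depresses TR
counts and hence estimated abundance, which is why the gate compares
against a deliberately conservative 10×.
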