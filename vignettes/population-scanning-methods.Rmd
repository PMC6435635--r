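---
title: "Population scanning and consensus genome comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population scanning and consensus genome comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacpopscan)
```

## The problem

A bacterial strain kept in culture for years and passaged dozens of
times is not a single genotype but a population.  When such a culture
is sequenced as a pool and the reads are mapped to a close reference
genome, two distinct classes of information sit in the same pileup:

1. **Fixed consensus differences** between the strain and the
   reference — SNPs, small deletion–insertion polymorphisms (DIPs),
   and entire missing regions such as excised prophage-like elements.
2. **Sub-consensus variation within the culture** — minor alleles
   segregating in the cell population, whose per-site read frequencies
   reveal where the genome is mutating fastest ("hypermutation
   hotspots").

`bacpopscan` implements both analyses, plus the codon-level
consequence annotation that connects them to phenotype (most notably
frameshift-*restoring* indels, which can reactivate a pseudogene such
as *sfp*, the phosphopantetheinyl transferase required for surfactin
and fengycin synthesis in *Bacillus subtilis*), and the biocontrol
index used to summarise antagonism assays.

## The sensitivity scan

For every pileup site with depth $d \ge$ `min_depth` and allele count
$k$, the scan at sensitivity tier $t$ reports every allele with
$k/d \ge t$ that is neither the reference allele nor the site's
consensus allele (the count argmax, ties resolved in favour of the
reference).  Three conventions matter and are pinned:

* **The threshold is inclusive** ("at least 5 %"): a variant at
  exactly the tier frequency is reported.  Tier nesting follows
  structurally: results at 35 % ⊆ 20 % ⊆ 5 %.
* **The consensus allele is never a population variant**, even when
  its frequency is below 1 — it *is* the deposited genome.
* Frequencies are compared at full precision; no rounding happens
  before thresholding.

Multiallelic sites yield one record per alternate allele; deletion and
insertion read evidence is scanned under the same rule.  `min_depth`
defaults to 10: there is no principled depth floor for this kind of
scan, and 10 merely prevents frequency estimates from one or two
reads.  Genotype likelihoods, strand-bias and base-quality filters are
deliberately out of scope — pileup counts are taken at face value.

## The genome diff

Consensus comparison is a collinear whole-genome diff built for the
>99.9 % identity regime:

1. **Anchors** — maximal exact matches seeded at k-mers (default
   `k = 21`) unique in *both* genomes, merged along diagonals and
   extended to the first mismatch.
2. **Chain** — the maximum-coverage strictly increasing chain
   (weighted longest-increasing-subsequence over anchor lengths).
3. **Gaps** — inter-anchor gaps with both sides at most `band`
   (5,000 bp) are closed by global alignment (match +1, mismatch −1,
   gap open −2, gap extend −1 via `Biostrings::pairwiseAlignment`);
   any sensible scoring gives identical variant calls at this
   identity, the values are pinned purely for reproducibility.
   Reference-only gaps of at least `min_segment_len` become *deleted
   segments*, query-only gaps *inserted segments*.
4. **Normalisation** — a run of $n$ adjacent mismatches is $n$ SNPs
   (per-position counting); indels are left-normalised against the
   reference; any indel of `min_segment_len` or more is reclassified
   as a segment, so DIP and segment counts are disjoint by
   construction.

`min_segment_len` defaults to 1,000 bp, which cleanly separates the
multi-kilobase deleted blocks (1.4–11.4 kb in the motivating data)
from ordinary DIPs (1–10 bp).  Every variant carries both reference
and query coordinates, because deletions upstream shift the two
systems apart.  The invariant backing the whole module is exact
reconstruction: applying the emitted edit set to the reference must
reproduce the query byte for byte, and the test suite enforces this on
random edit sets.

Rotation search, inversions and repeat-aware alignment are non-goals:
the intended inputs are same-origin deposited genome pairs.  When both
sides of a gap exceed the band, base-level detail is not recoverable
and the replacement is reported as one deleted plus one inserted
segment.

## Consequence annotation

SNPs are mapped to codon and residue index respecting strand, using
the standard genetic code with `ATG/GTG/TTG` accepted as initiators
(translated as Met at residue 1).  Categories partition every SNP:
intergenic, synonymous, missense, stop_gain, stop_loss.  For DIPs, the
mutated CDS is rebuilt and both versions translated to their first
stop: length changes divisible by 3 are in-frame, all others
frameshifts, and a frameshift is *frame-restoring* exactly when the
reference frame carried an internal stop and the shifted frame reads
through to the full expected length — the signature of the *sfp*
reactivation (675 bp gene, 224-residue product).  A non-restoring
frameshift whose product ends earlier than the reference product is
reported `truncated`; one that does not shorten the product is
`frame_disrupting`.

Amino-acid property transitions use pinned tables that are the
load-bearing interpretive choice of the module: acidic {D, E},
basic {K, R, H}, everything else neutral; small
{G, A, S, C, T, P, N, D, V}, the remaining eleven residues large.
Charge transitions take precedence over size transitions when both
change; a change to a stop codon is `truncation`.  The label set also
includes `acidic_to_basic`/`basic_to_acidic`: such changes are
single-nucleotide reachable (e.g. Asp→His) and mislabelling them as
anything else would be wrong even though they are rare.

## Hotspot aggregation

Variants are assigned to the feature containing them — once per
feature where genes overlap — or to the intergenic interval between
feature-covered runs (per-interval binning preserves information and
can be pooled afterwards).  A feature is a **hotspot** when it holds
at least two SNPs at the lowest-tier scan.  Counts per feature are
non-increasing in the tier, and their sum over features and intergenic
bins conserves the per-tier variant totals.

The within-gene positional profile adds a chi-square goodness-of-fit
test against the uniform-position null.  This statistic is an addition
of this package (positional non-randomness is otherwise a qualitative
claim): to keep expected counts ≥ 5 the test runs on at most
`floor(n/5)` equal bins and is declined below 3 such bins, while the
descriptive profile is always emitted.

## The synthetic-data generator

The generator exists so that every stage is testable end to end with
a known truth, offline.  It emulates:

* a clonal population whose pileups carry site-specific minor-allele
  frequencies concentrated in designated hotspot genes, planted in
  tier bands (0.50 / 0.25 / 0.10) that straddle the 35/20/5 %
  thresholds;
* binomial read sampling at Poisson-distributed depth (default mean
  78×, matching the coverage regime the pipeline targets) with a
  uniform per-base error model (default 0.005, a typical effective
  post-mapping short-read error rate; the motivating platform's
  colour-space error structure is deliberately not modelled);
* an `exact` mode (constant depth, counts = `round(freq × depth)`)
  that makes threshold arithmetic integer-deterministic, so recovery
  tests admit exact expectations;
* a derived strain genome: 106 consensus SNPs split 18 intergenic /
  46 synonymous / 42 amino-acid-changing, 23 DIPs of which 9 lie in
  structural genes — among them a single-base deletion at 407,533
  that restores the reading frame of a 676 bp *sfp*-like pseudogene
  to a 675 bp gene encoding a full 224-residue product — and three
  deletions at 529,444–536,858 / 536,946–548,309 / 548,412–549,854
  (7,415 / 11,364 / 1,443 bp, separated by 87 bp and 102 bp retained
  islands);
* a 531-residue *yqcG*-like toxin gene whose codons are chosen so
  that a fixed 17-substitution panel is reachable by single
  nucleotide changes, plus 20 high-frequency silent SNPs — so a 35 %
  scan sees 25 SNPs in the gene of which exactly 5 change the
  protein, a 20 % scan 10, and a 5 % scan 17.

The default genome is 1 Mb — large enough to keep every planted
coordinate at its literal value (the deletion block ends below
550 kb) while keeping simulation and diff runtimes in seconds; the
genome-scale layout (gene count, intergenic spacing) is otherwise
synthetic and not a miniature of any particular chromosome.  Per-site
frequencies for the panel are not observable quantities; the tier-band
placement is the supported reconstruction, and nothing downstream
depends on the exact values beyond their band.

Two generator details exist purely to make recovery *exact* rather
than approximate, and are worth knowing about:

* the bases flanking each planted multi-kilobase deletion are
  disambiguated (`ref[start] != ref[end+1]`, `ref[end] != ref[start-1]`)
  so anchor extension cannot slide a segment boundary — with real
  genomes a boundary can be genuinely ambiguous, which is why the
  validation report itemises boundary-adjacent calls separately;
* planted DIPs are stored already left-normalised, the same canonical
  form the diff emits.

What passing these tests does **not** show: robustness to mapping
bias, repeat-induced mis-anchoring, strand-specific error structure,
or contamination — none of which the generator emulates.  Real-data
runs should treat the boundary-adjacent call list and the undetermined
(`N`) spans of the consensus caller as the places to look first.

## Summary statistics

The biocontrol index is computed per replicate pair,
$\mathrm{BCI}_i = (C_i - T_i)/C_i \times 100$, then summarised as mean
± sample standard deviation (n − 1); the pairing and the SD choice are
this package's convention, since a mean ± dispersion without stated
estimator admits either reading.  BCI is invariant under rescaling all
radii and strictly decreasing in each treatment radius.

Average coverage is `reads × read_length / genome_length` *truncated*
to two decimals: for the canonical inputs (6,531,607 × 50 nt /
4,195,195 bp = 77.8463…) truncation, not rounding, reproduces the
conventionally displayed 77.84 — an inference about how such figures
are displayed, pinned here as the package's rule.  GC content excludes
`N` from numerator and denominator and is rounded half-up to one
decimal.

## Interfaces and reproducibility

The package is function-first: `simulate_scenario()`,
`scan_all_tiers()`, `diff_genomes()`, `annotate_variants()`,
`aggregate_hotspots()`, `reference_validation_report()`,
`compute_bci()` and `average_coverage()` are the pipeline; file
interchange goes through FASTA (`Biostrings`), GFF3 (`ape`), the
package's explicit pileup TSV dialect, VCF v4.2 emission with `AF` and
`TIERS` INFO keys, and YAML run configurations whose resolved values
(seed included) can be written next to any output for reproducibility.
A shell CLI would add nothing over `Rscript -e` for these entry
points, so none is shipped.  The pileup dialect is package-defined
(per-site base/indel counts with depth always derived); a converter
from `samtools mpileup` text is a documented non-goal.  All coordinates
everywhere are 1-based inclusive; origin-spanning features on circular
chromosomes are rejected rather than silently split, since none of the
loci this package targets span the origin.

`reference_validation_report()` runs the whole comparison on any
FASTA + GFF3 pair with a shared origin convention — including
downloaded GenBank-derived records — and itemises counts, segment
coordinates, the SNP category split, the strain-side length of a gene
of interest, and every boundary-adjacent call.  Exact agreement with
numbers produced by other pipelines is contingent on matching the
normalisation conventions above and on the annotation release used;
the report is designed so that disagreements can be itemised per
variant rather than argued about in aggregate.
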