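# bacpopscan

Population-genomic characterisation of clonal bacterial cultures from
read pileups, for microbiologists studying strain evolution and
biocontrol genetics.

A long-passaged bacterial culture sequenced as a pool carries two
layers of signal at once: the **fixed consensus differences** between
the strain and a reference genome (SNPs, small deletion–insertion
polymorphisms, whole missing prophage-like regions), and the
**sub-consensus variation segregating inside the culture**, whose
per-site minor-allele frequencies expose hypermutation hotspots —
e.g. the *yqcG* contact-dependent-inhibition toxin gene of *Bacillus
subtilis*, whose N-terminal delivery region diversifies rapidly while
its RNase domain stays untouched. `bacpopscan` separates and
quantifies both layers and connects them to consequence, including
frameshift-*restoring* deletions of the kind that reactivates the
*sfp* phosphopantetheinyl-transferase gene and with it surfactin and
fengycin production.

## What it computes

* **Sensitivity scans** — at tier *t*, every allele with read
  frequency `count/depth >= t` (inclusive) that is neither the
  reference nor the consensus allele; default tiers 5 / 20 / 35 %.
  Results nest across tiers by construction.
* **Collinear genome diff** — unique *k*-mer anchors, a
  maximum-coverage collinear chain, base-level alignment of small
  gaps, per-position SNPs, left-normalised DIPs
  (|Δ| < `min_segment_len` = 1,000 bp) and larger deleted/inserted
  segments, with byte-exact reconstruction guaranteed.
* **Consequence annotation** — strand-aware codon mapping (standard
  genetic code, `ATG/GTG/TTG` starts), categories
  intergenic/synonymous/missense/stop_gain/stop_loss, amino-acid
  property transitions (charge over size), and ORF comparison for
  indels with `frame_restoring` detection.
* **Hotspot reports** — per-gene counts per tier; a hotspot holds
  ≥ 2 SNPs at the lowest tier; within-gene positional profiles with a
  chi-square uniformity test.
* **Summaries** — biocontrol index `BCI = (C − T)/C × 100` per
  replicate pair with mean ± SD, average coverage
  (`reads × read_len / genome_len`, truncated to 2 decimals), GC
  content.
* **Synthetic data** — `simulate_scenario()` builds a 1 Mb
  reference/strain pair plus population pileups with fully known
  planted truth (106 SNPs, 23 DIPs, three multi-kb deletions, five
  hotspot genes, a frame-restoring *sfp*-like deletion), so the whole
  pipeline is testable offline.

## Worked example

```r
library(bacpopscan)

# a fully known strain/reference pair with planted differences
scn <- simulate_scenario(seed = 1)
rep <- reference_validation_report(scn$reference, scn$strain,
                                   scn$ref_annotation,
                                   region = c(529444, 549854))
print(rep)
#> <validation_report>
#>   query genome: 979,761 bp, GC 43.8%
#>   SNPs: 106 (intergenic 18, synonymous 46, aa-changing 42)
#>   DIPs: 23 (in genes 9, intergenic 14)
#>   deleted segments: 529444-536858, 536946-548309, 548412-549854
#>   sfp length in query: 675 bp
#>   boundary-adjacent calls: 0
```

Every planted difference is recovered: the 106 fixed SNPs split into
18 intergenic, 46 silent and 42 protein-changing; the 23 DIPs include
the single-base deletion that shortens the 676 bp *sfp*-like
pseudogene to a 675 bp gene encoding a full-length 224-residue
product; and the three deleted segments (7,415 / 11,364 / 1,443 bp)
are reported at their exact boundaries.

Scanning the hypermutating toxin gene at the strictest tier:

```r
fx <- build_yqcg_fixture(seed = 1)          # exact-mode pileups, depth 100
v35 <- scan_sites(fx$pileups, 0.35, tiers_config = c(0.05, 0.2, 0.35))
eff <- most_severe_effect(annotate_variants(v35, fx$annotation, fx$genome))
nrow(v35)                                   # 25 SNPs seen at 35 %
length(unique(na.omit(eff$aa_change)))      # 5 change the protein
sort(unique(na.omit(eff$aa_change)))
#> [1] "Ala260Val" "Asn89Ser"  "Phe84Ile"  "Thr98Ser"  "Val28Ala"
```

Of the 25 sub-consensus SNPs the 35 % scan reports in the gene, only
5 alter the toxin sequence; the 20 % and 5 % scans widen the set to 10
and 17 amino-acid changes respectively, reflecting the planted
frequency bands.

```r
average_coverage(6531607, 50, 4195195)
#> [1] 77.84
compute_bci(c(30, 30, 30), c(10, 10, 10))[c("mean", "sd")]
#> $mean 66.67   $sd 0
```

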