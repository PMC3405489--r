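# mirnome

Cataloging isomiRs and surveying miRNome complexity from plant small
RNA-seq.

Mature miRNAs are not single sequences: variable Dicer (DCL1) cleavage
produces populations of 5'/3' length variants — isomiRs — from the same
hairpin precursor, and the passenger strand (miRNA\*) can itself accumulate
to functional levels in a tissue-dependent way. `mirnome` is for researchers
who want to quantify that heterogeneity in a small RNA-seq experiment: it
takes raw reads (real or simulated), a reference genome and hairpin locus
annotation, and produces a normalized, arm-annotated isomiR catalog together
with the statistics needed to interpret it.

## What it computes

**Read processing.** The standard small-RNA filtering cascade: 3' adapter
trimming, 18–24 nt length selection, low-complexity removal (< 3 distinct
nucleotides), rRNA/tRNA substring matching on both strands, and exact
full-length genome mapping (both strands, zero mismatches). Reads are then
assigned to every annotated hairpin locus that fully contains a hit, and
per-stage redundant/non-redundant tallies are recorded.

**IsomiR catalog.** Counts are normalized to reads per million of
genome-matched reads, `rpm = count / genome_matched_total x 1e6`. Each
variant is placed exactly within its precursor and annotated with its arm
(mature or miRNA\*) and end offsets `(offset5, offset3)` relative to the
reference arm sequence, in precursor 5'→3' orientation.

**Statistics.**

- *Replicate concordance*: Pearson correlation over all library pairs of the
  de-duplicated sequence view (multi-locus reads counted once), with
  configurable outlier exclusion, checked against the ENCODE replicate band
  (0.92–0.98).
- *Differential isomiRs*: two-sided pooled-variance Student t-tests for all
  tissue pairs, significant at p < 0.05 (no multiplicity correction).
- *Sample clustering*: agglomerative clustering (complete linkage) on
  Canberra distances, `d(u,v) = Σ |uᵢ−vᵢ|/(uᵢ+vᵢ)`, on all reads or on the
  sample-invariant dominant reads only.
- *Arm ratios*: per-replicate miRNA/miRNA\* RPM ratios, averaged per tissue
  and classified into duplex-asymmetry bins: high (≥ 100), intermediate
  (10–100), low (1–10), inverted (< 1).

**Synthetic data.** A generator that plants hairpin loci (with proper 2-nt
3'-overhang miRNA/miRNA\* duplex geometry) into a random genome and emits
FASTQ libraries with a configurable cut-site heterogeneity model,
negative-binomial replicate noise, contaminant and low-complexity spike-ins
— plus ground-truth tables, so the whole pipeline can be validated by
parameter recovery.

A reference dataset of 15 peach (*Prunus persica*) libraries — five
tissues (BF, F, GF, GL, O) × three replicates, 26 hairpin loci, 392
isomiR rows — is packaged as plain-text fixtures with checksums.

## Worked example

```r
library(mirnome)

em <- load_table2_fixture()        # packaged reference isomiR catalog
concordance(em, exclusions = "HE860285")
```

```
<concordance_report>
  within-tissue Pearson averages:
    BF  0.98  [ENCODE band ok]
    F   0.95  [ENCODE band ok]
    GF  0.98  [ENCODE band ok]
    GL  0.95  [ENCODE band ok]
    O   0.97  [ENCODE band ok]
  cross-tissue average: 0.66 over 90 pairs
  excluded sequence(s): TCGGACCAGGCTTCATTCCCC
```

Every tissue's replicate concordance sits inside the ENCODE band, while
unrelated tissues correlate at only 0.66 — the catalog separates biology
from noise. The excluded read is one abnormally abundant sequence whose
presence would pin every correlation near 1.

```r
arm_ratio(em, "3_16", mature_acc = "HE860348", star_acc = "HE860347",
          pools = list(`GF+GL` = c("GF", "GL")))
```

```
<arm_ratio_report> locus 3_16
  BF  mean miRNA/miRNA* = 1.1 (low)
  F   mean miRNA/miRNA* = 0.9 (inverted)
  GF  mean miRNA/miRNA* = 6.7 (low)
  GL  mean miRNA/miRNA* = 4.7 (low)
  O   mean miRNA/miRNA* = 0.4 (inverted)
  pooled GF+GL: 5.7
```

Locus 3_16 shows tissue-dependent arm selection: in tissue O the miRNA\* is
the dominant accumulating strand (ratio 0.4, "inverted"), while in the bud
tissues the mature arm dominates ~6-fold.

```r
print(reproduce_study())   # recompute all reference statistics, with pass flags
```

An end-to-end synthetic run is one call:

```r
reports <- run_pipeline(simulation_config(depth = 2e4, seed = 1),
                        n_loci = 10, out_dir = "run1")
```

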