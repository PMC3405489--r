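---
title: "Methods: isomiR cataloging and miRNome-complexity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR cataloging and miRNome-complexity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnome)
```

## The problem

Plant miRNAs are excised from hairpin precursors by DCL1, whose cleavage
positions vary by a few nucleotides. A single locus therefore yields a
*population* of templated sequence variants — isomiRs — differing at the 5'
and/or 3' end, from both the mature arm and the passenger (miRNA\*) arm.
End identity matters biologically (the 5' nucleotide steers AGO loading),
so cataloging this heterogeneity, and testing whether it is reproducible
across replicates and tissues, is the package's job.

The package's data model is deliberately small:

- a **locus model**: precursor sequence plus the positions of its reference
  mature and (optional) star sequences within it;
- a **small RNA library**: distinct read sequences with raw counts and
  per-stage filtering tallies;
- an **expression matrix**: one row per (locus, sequence) pair with
  normalized abundance per library. A sequence that maps to several loci
  appears once per locus here and exactly once in the de-duplicated view
  used for whole-miRNome statistics.

## Read processing

The filtering cascade applies, in order: adapter trimming, length
selection, low-complexity removal, rRNA/tRNA removal, and exact genome
matching. Reads leaving stage *i* are exactly the reads entering stage
*i + 1*; redundant (read) and non-redundant (distinct-sequence) tallies are
recorded at every stage.

Choices where the field's conventions leave room:

- **Adapter rule.** The insert is the prefix before the leftmost occurrence
  of an adapter prefix of ≥ 6 nt (the occurrence must run to the read end
  or span the whole adapter). Reads with *no* detectable adapter are
  discarded rather than passed through: on a 36-nt machine read with an
  18–24 nt analysis window, a missing adapter implies the insert is longer
  than the window, so its boundary is unknown.
- **Low complexity** means fewer than 3 distinct nucleotides. This drops
  homopolymers and dinucleotide repeats while retaining every sequence of
  the packaged reference catalog; the exact rule used by common
  preprocessing toolkits is not published, so the package states its own.
- **Contaminant matching is substring matching**, both strands: small-RNA
  reads are fragments of full-length rRNA/tRNA, so read-in-reference
  containment (not equality) is the correct test.
- **`N`-containing reads are discarded before genome search** — a
  zero-mismatch match is undefined for `N`.
- **Genome matching** finds every full-length, zero-mismatch occurrence on
  both strands (Biostrings preprocessed dictionaries with a trusted band;
  a brute-force scan oracle verifies agreement in the tests). A read is
  assigned to *every* locus whose precursor interval fully contains one of
  its hits on the same strand.

Coordinates are 1-based inclusive throughout, the native convention of R,
IRanges and GFF3. Keeping the host ecosystem's convention makes the GFF
round trip an identity and avoids exactly the off-by-one drift that mixed
conventions invite.

## Normalization and annotation

Abundance is reads per million genome-matched reads:
`rpm = count / genome_matched_total × 1e6`. The denominator is the
library's post-filter total, so normalization is linear and depth-invariant.

`annotate_isomir()` places a variant exactly within its precursor and
assigns the arm whose reference interval it overlaps most, reporting end
offsets in precursor 5'→3' orientation for *both* arms (references are
stored in precursor orientation, so no genomic-strand sign juggling).
Bounds and tie-breaks:

- offsets beyond ±8 nt mark the variant `unaligned` — reference-catalog
  variants never deviate more, and the cap guards against spurious
  placements;
- a sequence placeable at several positions takes the placement nearest a
  reference and is flagged ambiguous;
- equal overlap of both arms resolves to the mature arm (deterministic,
  and the mature reference is the better-curated anchor).

## Dominance and the invariant-dominant read set

Per (locus, library) the variants are ranked by RPM; per (locus, tissue)
by the arithmetic mean of the three replicates. Ties are broken by total
abundance across all libraries, then lexicographically, and flagged. The
abundance tie-break matters on the packaged catalog, which is printed at
one decimal: two exact ties there are printing artifacts, and the globally
dominant read is the sensible winner.

A locus is *sample-invariant* when the same read dominates every library —
all samples and all replicates (`level = "library"`, the default). On the
packaged catalog this yields 21 loci and, because several locus families
share their dominant read, 16 distinct reads. The relaxed convention
(replicate-averaged dominant identical across tissues, `level = "tissue"`)
is available and yields 23 loci / 18 reads; the stricter one is the default
because it is the one consistent with the reference analysis's own
invariant-read count.

## Statistics

**Concordance.** Pearson correlations between all 105 library pairs of the
de-duplicated view, after removing configured outliers. The packaged
catalog contains one sequence (accession HE860285, ~2–3 × 10^5 RPM, two
orders of magnitude above everything else) whose presence pins every
correlation near 1; it is excluded by default. Within-tissue averages are
reported at 2 decimals and compared against the ENCODE replicate band
0.92–0.98. Correlations use untransformed RPM.

**Differential tests.** Two-sided two-sample Student t-tests with pooled
variance (df = 4 for 3 + 3 replicates) per isomiR and tissue pair,
significant at p < 0.05 with *no* multiplicity correction — the package
mirrors the screening convention of the reference analysis rather than
imposing an FDR layer on it. Welch's variant was rejected because the
pooled test is the one whose significant-comparison counts the reference
catalog reproduces. Degenerate cases are defined, not dodged: both groups
constant and equal → p = 1; constant and different → p = 0, flagged.

**Clustering.** Canberra distance, implemented from its definition with
0/0 terms contributing 0 and *no* rescaling — note this differs from
`stats::dist(method = "canberra")`, which rescales the sum when terms are
dropped; the two agree on strictly positive vectors, which is how `dist()`
serves as the test oracle. Linkage is complete, the default of the
statistical environment in which such analyses are conventionally run;
only the metric, not the linkage, is a substantive choice here. Two modes:
all reads (replicate-averaged, multi-locus reads counted once) and
dominant-only (restricted to the sample-invariant dominant reads), at
tissue or replicate level.

**Arm ratios.** Per replicate, the ratio of the mature read's RPM to the
star read's RPM; the tissue value is the arithmetic mean of per-replicate
ratios (replicates with zero star RPM are excluded and counted). Averaging
ratios rather than forming a ratio of averages is what reproduces both
reference values at locus 3_16 (0.4 in tissue O; 5.7 pooled over GF+GL).
Classes use the standard duplex-asymmetry bins [100, ∞), [10, 100),
[1, 10), [0, 1).

## The synthetic-data generator

The generator emulates the structure of the reference experiment: five
tissues × three replicates, 18–24 nt inserts sequenced as 36-nt machine
reads with the 3' adapter filling the remainder (so adapter trimming is
always exercised), hairpin loci with correct DCL1 duplex geometry (star =
reverse complement of the mature-pairing region with 2-nt 3' overhangs,
4-nt precursor pads so end variants stay templated), and spike-ins:
contaminant reads copied from generated rRNA/tRNA-like references (both
strands) and homopolymer reads.

Variant abundance follows a **cut-site model**: independent probability
tables for the 5' and 3' offsets (defaults concentrated on the reference
cut with modest ±1–2 nt spread, the 3' end more variable than the 5' end,
matching the qualitative asymmetry of observed catalogs) and a mature-arm
fraction (default 0.8). These defaults are free parameters of the
generator, not estimates — published catalogs constrain them only loosely.

Counts are negative-binomial per (library, isomiR) with mean
`depth × locus share × cut-model probability` and common dispersion
(default 0.05, a typical replicate CV² for count data); `dispersion = 0`
produces deterministic rounded expected counts, which is what makes the
"replicate Pearson = 1 exactly" property testable. Locus shares default to
a log-normal draw (sdlog 1) fixed by the master seed; tissue effects are
fold-change matrices (identity = null). Every library derives its own RNG
stream from (seed, tissue, replicate), so libraries are reproducible
independently of generation order.

What the generator does **not** emulate — and hence what passing
recovery tests do not establish about real data: sequencing errors and
quality-score structure, non-templated 3' additions (tailing), expression
heterogeneity beyond log-normal locus shares, and real rRNA/tRNA sequence
composition. The analysis itself considers only templated perfect-match
variants, so these omissions match its scope.

## Numerical and testing choices

- Rounding is frozen where values are reported: correlations 2 dp, ratios
  1 dp; p-values are never rounded internally.
- Parameter-recovery testing runs 20 independently seeded replicate
  libraries of a shared expectation through the *full* cascade and
  catalog. Mean observed RPM is compared to the analytic expectation per
  variant. Because ~100 variants are tested simultaneously, "within
  sampling error" is implemented as: > 90% of variants within 3 standard
  errors, and the maximum standardized deviation within the two-sided
  Bonferroni t bound at familywise 1% — a strict per-variant 3-SE rule
  would reject a correct implementation in roughly half of runs.
- Type-I error of the differential tests is measured on a null simulation
  (no tissue effects, dispersion 0.05, equal locus shares, depth 4 × 10^4,
  20 loci → 4,800 tests) and required to lie in 0.05 ± 0.02.
- Problem sizes in the test suite (depths 2–40 × 10^3, genomes 10–100 kb,
  3–25 loci) are chosen so that every distributional property is measured
  on comfortably more than enough events while a full run stays
  interactive; they are the package's own testing conditions, not
  estimates of any real experiment.

## Known limitations

- Arm annotation is reference-based (orientation and position against the
  supplied mature/star sequences), not thermodynamic; loci without a star
  reference cannot have star-arm variants annotated.
- Exact-match mapping means a single sequencing error drops a read; the
  package deliberately has no mismatch tolerance.
- The t-test layer is a screening tool; count-model inference (e.g.
  negative-binomial GLMs) is out of scope.
- The packaged reference catalog is printed at 1-dp RPM precision, so
  statistics recomputed from it can differ in the last digit from values
  computed on unrounded data; two exact dominance ties on the rounded
  table are resolved by the abundance tie-break described above.
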