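Package: mirnome
Title: IsomiR Cataloging and miRNome Complexity Analysis for Plant Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to survey the complexity of a plant miRNome from small RNA
    sequencing: a read-filtering cascade (adapter trimming, 18-24 nt length
    selection, low-complexity and rRNA/tRNA removal, perfect-match genome
    mapping), reads-per-million normalization, cataloging of isomiRs (5'/3'
    processing variants of mature miRNAs and miRNA* passenger strands) at
    annotated hairpin loci, and the downstream statistics used to interpret
    such catalogs: replicate concordance against the ENCODE Pearson band,
    pairwise differential tests, Canberra-distance hierarchical clustering of
    samples, dominant-isomiR and 5'-uridine analyses, and miRNA/miRNA*
    arm-ratio classification. Includes a synthetic small RNA-seq generator
    that emulates Dicer cut-site heterogeneity with ground-truth tables for
    end-to-end parameter-recovery testing, plus a packaged reference dataset
    of 15 peach libraries across five tissues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
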