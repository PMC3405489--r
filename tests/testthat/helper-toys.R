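# Small constructors shared across test files.

# A hand-built hairpin locus with known mature/star placement.
toy_locus <- function(mature = "TGACAGAAGAGAGTGAGCAC", loop = "GTCAAGTTCAAGTCA",
                      pad = "ACGT") {
  stem5 <- paste0("CA", mature)
  stem3 <- mirnome:::revcomp(stem5)
  pre <- paste0(pad, stem5, loop, stem3, pad)
  L <- nchar(mature)
  plen <- nchar(pre)
  list(locus_id = "toy", chrom = "chr1", start = 1, end = plen, strand = "+",
       precursor_seq = pre,
       mature_seq = mature, mature_start = nchar(pad) + 3,
       mature_end = nchar(pad) + 2 + L,
       star_seq = substr(pre, plen - nchar(pad) - L + 1, plen - nchar(pad)),
       star_start = plen - nchar(pad) - L + 1,
       star_end = plen - nchar(pad))
}

# An expression matrix with a fixed small layout: `vals` is a list mapping
# sequence -> numeric vector over `libs`.
toy_em <- function(vals, libs, locus = "L1") {
  m <- do.call(rbind, vals)
  colnames(m) <- libs
  expression_matrix(
    data.frame(locus_id = rep(locus, length(vals)),
               sequence = names(vals), stringsAsFactors = FALSE), m)
}

# Library ids of the five-tissue, three-replicate design.
design_libs <- function() {
  as.vector(t(outer(c("BF", "F", "GF", "GL", "O"), 1:3, paste0)))
}

# Write a temporary FASTA and return its path.
tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}
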