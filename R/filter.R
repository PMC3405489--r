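#' Filtering-cascade configuration
#'
#' @param adapter3 3' adapter sequence (non-empty).
#' @param min_len,max_len Inclusive insert length bounds retained after
#'   trimming (18 and 24 nt: the small-RNA window).
#' @param min_distinct_bases Minimum number of distinct nucleotides a read
#'   must contain; reads below this are low-complexity and dropped.
#' @param min_adapter_overlap Minimum adapter prefix length that must be seen
#'   in the read for trimming.
#' @param contaminant_set Character vector of rRNA/tRNA reference sequences.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                          min_len = 18, max_len = 24,
                          min_distinct_bases = 3,
                          min_adapter_overlap = 6,
                          contaminant_set = character()) {
  stopifnot(nchar(adapter3) > 0, min_len > 0, min_len <= max_len,
            min_adapter_overlap >= 1)
  structure(list(adapter3 = adapter3, min_len = min_len, max_len = max_len,
                 min_distinct_bases = min_distinct_bases,
                 min_adapter_overlap = min_adapter_overlap,
                 contaminant_set = contaminant_set),
            class = "filter_config")
}

#' Trim the 3' adapter from reads
#'
#' Returns the insert before the leftmost occurrence of an adapter prefix of
#' length at least `min_adapter_overlap` (the occurrence must run to the end
#' of the read or span the full adapter). Reads without a detectable adapter
#' are rejected (`NA`): with a machine read longer than the insert window,
#' absence of adapter means the insert boundary is unknown.
#'
#' @param reads Character vector of machine reads over `{A,C,G,T,N}`.
#' @param config A [filter_config()].
#' @return Character vector of inserts, `NA` where rejected.
#' @export
trim_adapter <- function(reads, config = filter_config()) {
  adapter <- config$adapter3
  alen <- nchar(adapter)
  seed <- substr(adapter, 1, config$min_adapter_overlap)
  vapply(reads, function(read) {
    rlen <- nchar(read)
    hits <- gregexpr(seed, read, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NA_character_)
    for (i in hits) {
      want <- min(alen, rlen - i + 1)
      if (substr(read, i, i + want - 1) == substr(adapter, 1, want))
        return(substr(read, 1, i - 1))
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Length filter: keep inserts within the small-RNA window
#'
#' @param sequences Character vector of trimmed inserts.
#' @param config A [filter_config()].
#' @return Logical keep vector (inclusive bounds).
#' @export
filter_length <- function(sequences, config = filter_config()) {
  n <- nchar(sequences)
  n >= config$min_len & n <= config$max_len
}

#' Low-complexity filter
#'
#' Drops reads made of fewer than `min_distinct_bases` distinct nucleotides
#' (homopolymers, dinucleotide repeats).
#'
#' @param sequences Character vector.
#' @param config A [filter_config()].
#' @return Logical keep vector.
#' @export
filter_complexity <- function(sequences, config = filter_config()) {
  distinct <- grepl("A", sequences, fixed = TRUE) +
    grepl("C", sequences, fixed = TRUE) +
    grepl("G", sequences, fixed = TRUE) +
    grepl("T", sequences, fixed = TRUE)
  distinct >= config$min_distinct_bases
}

#' rRNA/tRNA contaminant filter
#'
#' Drops a read if it is an exact substring of any contaminant reference on
#' either strand (reads are fragments of full-length rRNA/tRNA, so substring
#' matching, not equality, is the rule).
#'
#' @param sequences Character vector.
#' @param config A [filter_config()] with a non-empty `contaminant_set`
#'   (empty set: warning, everything kept).
#' @return Logical keep vector.
#' @export
filter_contaminants <- function(sequences, config = filter_config()) {
  refs <- config$contaminant_set
  if (length(refs) == 0) {
    warning("empty contaminant set: all reads kept")
    return(rep(TRUE, length(sequences)))
  }
  subject <- paste(c(refs, revcomp(refs)), collapse = "NN")
  !vapply(sequences, grepl, logical(1), x = subject, fixed = TRUE,
          USE.NAMES = FALSE)
}

#' Exact full-length genome matching
#'
#' Finds every zero-mismatch, full-length occurrence of each read on both
#' strands of the genome. Reads containing `N` are discarded before the
#' search (a perfect match is undefined for `N`). Matching uses Biostrings
#' preprocessed dictionaries, grouped by read length.
#'
#' @param sequences Character vector of distinct reads.
#' @param genome Named character vector of chromosome sequences, or a single
#'   string, or a `sim_genome`.
#' @return Data frame with columns `sequence`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`. Reads without a hit are absent.
#' @export
match_genome <- function(sequences, genome) {
  if (inherits(genome, "sim_genome"))
    genome <- stats::setNames(genome$seq, genome$chrom)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  sequences <- unique(sequences[!grepl("N", sequences, fixed = TRUE)])
  if (length(sequences) == 0)
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  subjects <- lapply(genome, Biostrings::DNAString)
  out <- list()
  scan <- function(seqs, strand) {
    # seqs: forward-strand query sequences (revcomp'ed reads for "-").
    # One variable-width dictionary per strand, trusted band = shortest read.
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs),
                            tb.start = 1, tb.end = min(nchar(seqs)))
    for (chrom in names(subjects)) {
      m <- Biostrings::matchPDict(pd, subjects[[chrom]])
      starts <- Biostrings::startIndex(m)
      for (k in seq_along(seqs)) {
        st <- starts[[k]]
        if (length(st) == 0) next
        read <- if (strand == "+") seqs[k] else revcomp(seqs[k])
        out[[length(out) + 1]] <<- data.frame(
          sequence = read, chrom = chrom, start = st,
          end = st + nchar(seqs[k]) - 1,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  scan(sequences, "+")
  scan(revcomp(sequences), "-")
  if (length(out) == 0)
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  hits[order(match(hits$sequence, sequences), hits$chrom, hits$start), ,
       drop = FALSE]
}

#' Assign genome hits to hairpin loci
#'
#' A read is assigned to every locus whose precursor interval fully contains
#' at least one of its hits on the same strand; hits outside all loci leave
#' the read unassigned.
#'
#' @param hits Data frame from [match_genome()].
#' @param loci A `locus_set` (or `sim_genome$loci`).
#' @return Named list mapping each hit sequence to a character vector of
#'   locus ids (possibly empty).
#' @export
assign_loci <- function(hits, loci) {
  if (inherits(loci, "sim_genome")) loci <- loci$loci
  seqs <- unique(hits$sequence)
  res <- stats::setNames(rep(list(character(0)), length(seqs)), seqs)
  if (nrow(hits) == 0 || length(loci) == 0) return(res)
  gr_hits <- GenomicRanges::GRanges(hits$chrom,
                                    IRanges::IRanges(hits$start, hits$end),
                                    strand = hits$strand)
  gr_loci <- loci_granges(loci)
  ov <- GenomicRanges::findOverlaps(gr_hits, gr_loci, type = "within")
  for (k in seq_along(ov)) {
    s <- hits$sequence[S4Vectors::queryHits(ov)[k]]
    lid <- gr_loci$locus_id[S4Vectors::subjectHits(ov)[k]]
    res[[s]] <- union(res[[s]], lid)
  }
  res
}

#' Run the full filtering cascade on one library
#'
#' Applies, in order: adapter trimming, 18-24 nt length selection,
#' low-complexity removal, rRNA/tRNA removal, perfect-match genome mapping.
#' Both redundant (read) and non-redundant (distinct sequence) tallies are
#' recorded after every stage, mirroring the reference accounting layout.
#'
#' @param fastq Data frame from [read_fastq()] (or a character vector of
#'   reads).
#' @param genome Genome as accepted by [match_genome()].
#' @param loci A `locus_set` used to assign retained reads to loci.
#' @param config A [filter_config()].
#' @param library_id Library identifier recorded in the outputs.
#' @return A list of class `small_rna_library`: `library_id`, `reads` (named
#'   integer vector: retained sequence -> raw count), `locus_assignment`
#'   (from [assign_loci()]), `genome_matched_total`, `stage_tallies`, and a
#'   one-row `stats` data frame in the packaged-fixture column layout.
#' @export
run_cascade <- function(fastq, genome, loci, config = filter_config(),
                        library_id = "lib") {
  reads <- if (is.character(fastq)) fastq else fastq$sequence
  if (length(reads) == 0)
    warning("empty input: producing an empty library")
  # collapse to unique sequences up front; all stages work on weighted
  # unique reads
  tab <- table(reads)
  seqs <- names(tab)
  counts <- as.integer(tab)

  tally <- function(keep) c(sum(counts[keep]), sum(keep))
  stages <- list(raw = c(sum(counts), length(seqs)))

  trimmed <- trim_adapter(seqs, config)
  ok <- !is.na(trimmed)
  if (any(ok)) {
    # trimming changes the sequence: re-aggregate identical inserts
    agg <- tapply(counts[ok], trimmed[ok], sum)
    seqs <- names(agg); counts <- as.integer(agg)
  } else {
    seqs <- character(0); counts <- integer(0)
  }
  stages$adapter_matched <- c(sum(counts), length(seqs))

  keep <- filter_length(seqs, config)
  seqs <- seqs[keep]; counts <- counts[keep]
  stages$length_filtered <- c(sum(counts), length(seqs))

  keep <- filter_complexity(seqs, config)
  seqs <- seqs[keep]; counts <- counts[keep]
  stages$low_complexity <- c(sum(counts), length(seqs))

  if (length(config$contaminant_set) > 0) {
    keep <- filter_contaminants(seqs, config)
    seqs <- seqs[keep]; counts <- counts[keep]
  }
  stages$contaminant <- c(sum(counts), length(seqs))

  hits <- match_genome(seqs, genome)
  keep <- seqs %in% hits$sequence
  seqs <- seqs[keep]; counts <- counts[keep]
  stages$genome_matched <- c(sum(counts), length(seqs))

  assignment <- assign_loci(hits, loci)

  stats_row <- data.frame(
    library_id = library_id,
    raw = stages$raw[1],
    adapter_matched = stages$adapter_matched[1],
    length_filtered = stages$length_filtered[1],
    low_complexity_r = stages$low_complexity[1],
    low_complexity_nr = stages$low_complexity[2],
    contaminant_r = stages$contaminant[1],
    contaminant_nr = stages$contaminant[2],
    genome_matched_r = stages$genome_matched[1],
    genome_matched_nr = stages$genome_matched[2],
    stringsAsFactors = FALSE)
  class(stats_row) <- c("filter_stats", "data.frame")

  structure(list(library_id = library_id,
                 reads = stats::setNames(counts, seqs),
                 locus_assignment = assignment,
                 genome_matched_total = stages$genome_matched[1],
                 stage_tallies = stages,
                 stats = stats_row),
            class = "small_rna_library")
}

#' @export
print.small_rna_library <- function(x, ...) {
  cat("<small_rna_library>", x$library_id, "-",
      x$genome_matched_total, "genome-matched reads over",
      length(x$reads), "distinct sequences\n")
  invisible(x)
}
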