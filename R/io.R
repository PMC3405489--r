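#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are upper-cased and RNA `U` is converted to `T` so that RNA and
#' DNA inputs unify on the DNA alphabet. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param allow_n Logical; permit `N` in sequences (default `TRUE`, needed for
#'   genome assemblies). Characters outside `A,C,G,T(,N)` are a format error.
#' @return A named character vector of sequences, named by record identifier
#'   (the header up to the first whitespace).
#' @export
read_fasta <- function(path, allow_n = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(x))
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr(sprintf("[^%s]", alphabet), seqs[i]))
    stop("invalid character '", ch, "' in FASTA record ", i,
         " ('", ids[i], "') of ", path)
  }
  if (any(nchar(seqs) == 0)) {
    i <- which(nchar(seqs) == 0)[1]
    stop("empty sequence in FASTA record ", i, " ('", ids[i], "') of ", path)
  }
  stats::setNames(seqs, ids)
}

#' Read a FASTQ file
#'
#' @param path Path to a 4-line-per-record FASTQ file (Sanger qualities).
#' @return A data frame with columns `id`, `sequence`, `quality`; zero rows
#'   for an empty file. Truncated records or sequence/quality length
#'   disagreement raise a format error.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record at end of ", path,
         " (", length(lines), " lines, not a multiple of 4)")
  ix <- seq(1, length(lines), by = 4)
  if (!all(startsWith(lines[ix], "@")) || !all(startsWith(lines[ix + 2], "+")))
    stop("malformed FASTQ in ", path, ": record markers out of register")
  seqs <- toupper(lines[ix + 1])
  quals <- lines[ix + 3]
  if (any(nchar(seqs) != nchar(quals))) {
    i <- which(nchar(seqs) != nchar(quals))[1]
    stop("FASTQ record ", i, " in ", path,
         ": sequence and quality lengths differ")
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[ix])),
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

#' Write FASTQ records
#'
#' @param records Data frame with columns `id`, `sequence`, `quality` (as
#'   returned by [read_fastq()] or [simulate_library()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records) > 0)
    writeLines(paste0("@", records$id, "\n", records$sequence, "\n+\n",
                      records$quality), con)
  invisible(path)
}

#' Load hairpin locus annotation
#'
#' Reads a GFF3 file of `miRNA_primary_transcript` features with child
#' `miRNA` features (1-based inclusive coordinates, the GFF native
#' convention, which is also the package's internal convention), together
#' with precursor sequences and reference mature/star sequences. Child
#' features are assigned to an arm by the suffix of their `Name` attribute:
#' `<locus>.mature` or `<locus>.star`.
#'
#' @param gff_path GFF3 annotation path.
#' @param precursor_fasta FASTA of precursor sequences named by locus id.
#' @param refs_fasta FASTA of reference arm sequences named
#'   `<locus>.mature` / `<locus>.star`. Star records may be absent.
#' @return A list of locus models (class `locus_set`); each element has
#'   `locus_id`, `chrom`, `start`, `end`, `strand`, `precursor_seq`,
#'   `mature_seq`, `mature_start`, `mature_end` and (optionally) `star_seq`,
#'   `star_start`, `star_end`, positions being 1-based within the precursor.
#' @export
load_locus_annotation <- function(gff_path, precursor_fasta, refs_fasta) {
  gff <- rtracklayer::import(gff_path)
  prim <- gff[gff$type == "miRNA_primary_transcript"]
  kids <- gff[gff$type == "miRNA"]
  if (length(prim) == 0) stop("no miRNA_primary_transcript features in ", gff_path)
  precursors <- read_fasta(precursor_fasta)
  refs <- read_fasta(refs_fasta)
  loci <- lapply(seq_along(prim), function(i) {
    p <- prim[i]
    id <- p$ID
    if (is.null(id) || is.na(id)) id <- p$Name
    if (!id %in% names(precursors))
      stop("precursor sequence missing for locus ", id)
    pre <- unname(precursors[id])
    if (nchar(pre) != GenomicRanges::width(p))
      stop("precursor length for locus ", id, " disagrees with annotation")
    if (nchar(pre) < 41 || nchar(pre) > 227)
      warning("precursor of locus ", id, " is ", nchar(pre),
              " nt, outside the usual 41-227 nt range")
    mine <- kids[unlist(lapply(kids$Parent, function(pp) id %in% pp))]
    loc <- list(locus_id = id,
                chrom = as.character(GenomicRanges::seqnames(p)),
                start = GenomicRanges::start(p), end = GenomicRanges::end(p),
                strand = as.character(GenomicRanges::strand(p)),
                precursor_seq = pre)
    for (j in seq_along(mine)) {
      k <- mine[j]
      arm <- sub("^.*\\.", "", k$Name)
      if (!arm %in% c("mature", "star"))
        stop("miRNA child of locus ", id, " has Name '", k$Name,
             "'; expected suffix .mature or .star")
      # offset of the arm within the precursor, strand-aware
      off <- if (loc$strand == "-") loc$end - GenomicRanges::end(k) + 1
             else GenomicRanges::start(k) - loc$start + 1
      len <- GenomicRanges::width(k)
      seq_in_pre <- substr(pre, off, off + len - 1)
      ref_name <- paste0(id, ".", arm)
      if (ref_name %in% names(refs) && refs[[ref_name]] != seq_in_pre)
        stop("locus ", id, ": ", arm, " reference sequence is not the ",
             "precursor substring at its stated position")
      loc[[paste0(arm, "_seq")]] <- seq_in_pre
      loc[[paste0(arm, "_start")]] <- off
      loc[[paste0(arm, "_end")]] <- off + len - 1
    }
    if (is.null(loc$mature_seq)) stop("locus ", id, " has no mature arm record")
    if (!is.null(loc$star_seq) &&
        loc$mature_start <= loc$star_end && loc$star_start <= loc$mature_end)
      stop("locus ", id, ": mature and star intervals overlap")
    loc
  })
  names(loci) <- vapply(loci, `[[`, character(1), "locus_id")
  structure(loci, class = "locus_set")
}

#' Write locus models as GFF3 + FASTA
#'
#' Inverse of [load_locus_annotation()]; used by the simulator to emit its
#' planted loci in standard formats.
#'
#' @param loci A `locus_set`.
#' @param gff_path,precursor_fasta,refs_fasta Output paths.
#' @return Invisibly, the three paths.
#' @export
write_locus_annotation <- function(loci, gff_path, precursor_fasta, refs_fasta) {
  rows <- list()
  for (loc in loci) {
    rows[[length(rows) + 1]] <- data.frame(
      chrom = loc$chrom, start = loc$start, end = loc$end,
      strand = loc$strand, type = "miRNA_primary_transcript",
      id = loc$locus_id, parent = NA_character_, stringsAsFactors = FALSE)
    for (arm in c("mature", "star")) {
      off <- loc[[paste0(arm, "_start")]]
      if (is.null(off)) next
      len <- loc[[paste0(arm, "_end")]] - off + 1
      gstart <- if (loc$strand == "-") loc$end - (off + len - 1) + 1
                else loc$start + off - 1
      rows[[length(rows) + 1]] <- data.frame(
        chrom = loc$chrom, start = gstart, end = gstart + len - 1,
        strand = loc$strand, type = "miRNA",
        id = paste0(loc$locus_id, ".", arm), parent = loc$locus_id,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                               strand = d$strand, type = d$type,
                               ID = d$id, Name = d$id)
  gr$Parent <- IRanges::CharacterList(
    lapply(d$parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, gff_path, format = "gff3")
  pre <- Biostrings::DNAStringSet(vapply(loci, `[[`, character(1), "precursor_seq"))
  names(pre) <- names(loci)
  Biostrings::writeXStringSet(pre, precursor_fasta)
  ref_list <- list()
  for (loc in loci) {
    ref_list[[paste0(loc$locus_id, ".mature")]] <- loc$mature_seq
    if (!is.null(loc$star_seq))
      ref_list[[paste0(loc$locus_id, ".star")]] <- loc$star_seq
  }
  refs <- Biostrings::DNAStringSet(unlist(ref_list))
  Biostrings::writeXStringSet(refs, refs_fasta)
  invisible(c(gff_path, precursor_fasta, refs_fasta))
}

#' @export
print.locus_set <- function(x, ...) {
  cat("<locus_set> of", length(x), "hairpin loci\n")
  for (loc in head(x, 5))
    cat(sprintf("  %s %s:%d-%d(%s) precursor %d nt, mature %d nt%s\n",
                loc$locus_id, loc$chrom, loc$start, loc$end, loc$strand,
                nchar(loc$precursor_seq), nchar(loc$mature_seq),
                if (is.null(loc$star_seq)) "" else
                  sprintf(", star %d nt", nchar(loc$star_seq))))
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}

# GRanges of the precursor intervals of a locus_set.
loci_granges <- function(loci) {
  GenomicRanges::GRanges(
    vapply(loci, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(loci, `[[`, numeric(1), "start"),
                     vapply(loci, `[[`, numeric(1), "end")),
    strand = vapply(loci, `[[`, character(1), "strand"),
    locus_id = names(loci))
}
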