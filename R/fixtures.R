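#' Construct an isomiR expression matrix
#'
#' The central container: one row per (locus, sequence) pair with its
#' normalized abundance (reads per million of genome-matched reads, RPM) in
#' every library. A sequence assigned to several loci appears once per locus
#' in this per-locus layout; [dedup_view()] collapses it to one row per
#' sequence for whole-miRNome statistics.
#'
#' @param info Data frame with columns `locus_id`, `sequence` and optionally
#'   `accession` (plus any further annotation columns).
#' @param values Numeric matrix of non-negative RPM values, one row per row
#'   of `info`, columns named by library id.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(info, values) {
  stopifnot(is.data.frame(info), all(c("locus_id", "sequence") %in% names(info)),
            is.matrix(values), nrow(values) == nrow(info),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("expression values must be non-negative")
  if (any(!grepl("^[ACGT]+$", info$sequence)))
    stop("sequences must be over the alphabet {A,C,G,T}")
  structure(list(info = info, values = values, libraries = colnames(values)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$info), "(locus, sequence) rows,",
      length(unique(x$info$sequence)), "distinct sequences,",
      length(unique(x$info$locus_id)), "loci,",
      length(x$libraries), "libraries\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' De-duplicated sequence view of an expression matrix
#'
#' Collapses rows sharing a sequence (reads assigned to several loci) to a
#' single row, so each read is counted once in whole-miRNome statistics such
#' as replicate concordance and sample clustering. Duplicate rows of the same
#' sequence carry identical values by construction; the first is kept.
#'
#' @param em An `expression_matrix`.
#' @return A numeric matrix with one row per distinct sequence (rownames are
#'   the sequences) and one column per library.
#' @export
dedup_view <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- !duplicated(em$info$sequence)
  m <- em$values[keep, , drop = FALSE]
  rownames(m) <- em$info$sequence[keep]
  m
}

# Map accessions to the sequences they label (possibly within one locus).
accession_sequences <- function(em, accessions, locus_id = NULL) {
  info <- em$info
  if (!is.null(locus_id)) info <- info[info$locus_id == locus_id, ]
  unique(info$sequence[info$accession %in% accessions])
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "mirnome", mustWork = TRUE)
}

check_fixture <- function(file) {
  path <- fixture_path(file)
  manifest <- read.delim(fixture_path("manifest.tsv"), stringsAsFactors = FALSE)
  expect <- manifest$md5[manifest$file == file]
  if (length(expect) != 1) stop("no manifest entry for fixture ", file)
  got <- unname(tools::md5sum(path))
  if (got != expect)
    stop("fixture integrity error: ", file, " has md5 ", got,
         " but the manifest records ", expect)
  path
}

#' Load the packaged per-library filtering statistics
#'
#' Returns the filtering cascade accounting for the 15 reference peach
#' small-RNA libraries (five tissues, BF/F/GF/GL/O, three replicates each):
#' raw reads, adapter-matched, 18-24 nt, and the redundant/non-redundant
#' tallies after low-complexity removal, rRNA/tRNA removal and perfect-match
#' genome mapping. The packaged file is checksum-verified and the cascade
#' monotonicity is validated on load.
#'
#' @return A data frame of class `filter_stats` with one row per library.
#' @export
load_table1_fixture <- function() {
  path <- check_fixture("table1.tsv")
  d <- read.delim(path, stringsAsFactors = FALSE)
  num_cols <- setdiff(names(d), "library_id")
  for (cc in num_cols) d[[cc]] <- as.integer(d[[cc]])
  casc <- c("raw", "adapter_matched", "length_filtered",
            "low_complexity_r", "contaminant_r", "genome_matched_r")
  mono <- apply(as.matrix(d[casc]), 1, function(v) all(diff(v) <= 0))
  if (!all(mono))
    stop("fixture integrity error: non-monotone filtering cascade for ",
         paste(d$library_id[!mono], collapse = ", "))
  class(d) <- c("filter_stats", "data.frame")
  d
}

#' Load the packaged isomiR expression table
#'
#' Returns the normalized (RPM) isomiR expression catalog of the reference
#' dataset: 392 (locus, sequence) rows over 26 hairpin loci and 15 libraries,
#' keyed by EMBL accession. Sequences assigned to several loci are listed
#' once per locus here; use [dedup_view()] for the one-row-per-sequence view.
#' The packaged file is checksum-verified on load.
#'
#' @return An [expression_matrix()].
#' @export
load_table2_fixture <- function() {
  path <- check_fixture("table2.tsv")
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  libs <- setdiff(names(d), c("locus_id", "sequence", "accession"))
  if (length(libs) != 15)
    stop("fixture integrity error: expected 15 library columns, found ",
         length(libs))
  expression_matrix(d[c("locus_id", "sequence", "accession")],
                    as.matrix(d[libs]))
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with columns `locus_id`, `sequence`, optional `accession`,
#'   then one numeric column per library. Lines starting `#` are ignored.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  comment.char = "#")
  key <- intersect(c("locus_id", "sequence", "accession"), names(d))
  expression_matrix(d[key], as.matrix(d[setdiff(names(d), key)]))
}

#' Write an expression matrix to TSV
#'
#' Values are written at full precision (15 significant digits) so a
#' write/read round trip reproduces them to well below 1e-9.
#'
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @param header Optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, header = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  vals <- format(em$values, digits = 15, trim = TRUE, scientific = FALSE)
  d <- cbind(em$info, as.data.frame(vals, stringsAsFactors = FALSE))
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
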