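#' Reads-per-million normalization
#'
#' `rpm = raw_count / genome_matched_total * 1e6`: each library's counts are
#' divided by its total number of genome-matched reads and scaled to one
#' million, so abundances are comparable across libraries of different depth.
#'
#' @param raw_count Numeric vector of raw counts.
#' @param genome_matched_total The library's genome-matched read total (> 0).
#' @param library_id Used in the error message for a zero total.
#' @return Numeric vector of RPM values.
#' @export
normalize_counts <- function(raw_count, genome_matched_total,
                             library_id = "library") {
  if (is.na(genome_matched_total) || genome_matched_total <= 0)
    stop("cannot normalize ", library_id,
         ": genome-matched total is not positive")
  raw_count / genome_matched_total * 1e6
}

#' Annotate an isomiR against its locus
#'
#' Places the sequence exactly within the precursor, assigns it to the arm
#' (mature or star) whose reference interval it overlaps most, and reports
#' the 5'/3' end offsets relative to that reference, in precursor 5'->3'
#' orientation (negative `offset5` = 5' extension, positive `offset3` = 3'
#' extension). A sequence that cannot be placed, does not overlap an arm, or
#' exceeds `max_offset` at either end is `unaligned`. When several
#' placements are possible the one nearest a reference is used and the
#' ambiguity flagged.
#'
#' @param sequence IsomiR sequence.
#' @param locus A locus model with `precursor_seq`, `mature_*` and
#'   optionally `star_*` fields.
#' @param max_offset Largest absolute end offset before declaring
#'   `unaligned`.
#' @return A list: `arm` (`"mature"`, `"star"` or `"unaligned"`), `offset5`,
#'   `offset3` (NA when unaligned), `ambiguous`.
#' @export
annotate_isomir <- function(sequence, locus, max_offset = 8) {
  starts <- gregexpr(sequence, locus$precursor_seq, fixed = TRUE)[[1]]
  if (starts[1] == -1)
    return(list(arm = "unaligned", offset5 = NA_integer_,
                offset3 = NA_integer_, ambiguous = FALSE))
  L <- nchar(sequence)
  arms <- c("mature", if (!is.null(locus$star_seq)) "star")
  cand <- list()
  for (s in starts) {
    e <- s + L - 1
    for (arm in arms) {
      rs <- locus[[paste0(arm, "_start")]]
      re <- locus[[paste0(arm, "_end")]]
      ov <- min(e, re) - max(s, rs) + 1
      if (ov <= 0) next
      o5 <- s - rs; o3 <- e - re
      if (max(abs(o5), abs(o3)) > max_offset) next
      cand[[length(cand) + 1]] <- list(arm = arm, offset5 = o5, offset3 = o3,
                                       overlap = ov, dist = abs(o5) + abs(o3))
    }
  }
  if (length(cand) == 0)
    return(list(arm = "unaligned", offset5 = NA_integer_,
                offset3 = NA_integer_, ambiguous = FALSE))
  ov <- vapply(cand, `[[`, numeric(1), "overlap")
  dist <- vapply(cand, `[[`, numeric(1), "dist")
  # prefer the arm overlapped most; among those, the placement nearest its
  # reference
  best <- which(ov == max(ov))
  pick <- best[which.min(dist[best])]
  list(arm = cand[[pick]]$arm,
       offset5 = as.integer(cand[[pick]]$offset5),
       offset3 = as.integer(cand[[pick]]$offset3),
       ambiguous = length(starts) > 1)
}

#' Build an annotated isomiR catalog
#'
#' Turns locus-assigned, filtered libraries into the central expression
#' matrix: one row per (locus, sequence) pair with RPM in every library,
#' annotated with arm and end offsets where precursor models are available.
#' Alternatively accepts an existing [expression_matrix()] (e.g. the
#' packaged reference table) and annotates it against `loci`.
#'
#' @param libraries List of `small_rna_library` objects (from
#'   [run_cascade()]), or an `expression_matrix`.
#' @param loci A `locus_set`, or `NULL` to skip arm annotation.
#' @param max_offset Passed to [annotate_isomir()].
#' @return A list of class `isomir_catalog` with elements `matrix` (an
#'   `expression_matrix` whose `info` carries `arm`, `offset5`, `offset3`)
#'   and `libraries` (library ids).
#' @export
build_catalog <- function(libraries, loci = NULL, max_offset = 8) {
  if (inherits(loci, "sim_genome")) loci <- loci$loci
  if (inherits(libraries, "expression_matrix")) {
    em <- libraries
  } else {
    lib_ids <- vapply(libraries, `[[`, character(1), "library_id")
    pairs <- list()
    for (lib in libraries) {
      for (s in names(lib$locus_assignment)) {
        lids <- lib$locus_assignment[[s]]
        if (length(lids) == 0) next
        for (lid in lids) pairs[[paste(lid, s)]] <- c(lid, s)
      }
    }
    if (length(pairs) == 0) stop("no locus-assigned reads in any library")
    info <- data.frame(locus_id = vapply(pairs, `[`, character(1), 1),
                       sequence = vapply(pairs, `[`, character(1), 2),
                       stringsAsFactors = FALSE)
    info <- info[order(info$locus_id, info$sequence), ]
    rownames(info) <- NULL
    vals <- matrix(0, nrow(info), length(libraries),
                   dimnames = list(NULL, lib_ids))
    for (j in seq_along(libraries)) {
      lib <- libraries[[j]]
      raw <- lib$reads[info$sequence]
      raw[is.na(raw)] <- 0
      vals[, j] <- normalize_counts(raw, lib$genome_matched_total,
                                    lib$library_id)
    }
    em <- expression_matrix(info, vals)
  }
  if (!is.null(loci)) {
    ann <- vector("list", nrow(em$info))
    for (i in seq_len(nrow(em$info))) {
      lid <- em$info$locus_id[i]
      if (lid %in% names(loci)) {
        ann[[i]] <- annotate_isomir(em$info$sequence[i], loci[[lid]],
                                    max_offset)
      } else {
        ann[[i]] <- list(arm = "unaligned", offset5 = NA_integer_,
                         offset3 = NA_integer_, ambiguous = FALSE)
      }
    }
    em$info$arm <- vapply(ann, `[[`, character(1), "arm")
    em$info$offset5 <- vapply(ann, `[[`, integer(1), "offset5")
    em$info$offset3 <- vapply(ann, `[[`, integer(1), "offset3")
    if (any(em$info$arm == "unaligned" & !is.null(loci)))
      for (i in which(em$info$arm == "unaligned"))
        if (em$info$locus_id[i] %in% names(loci))
          warning("sequence ", em$info$sequence[i],
                  " cannot be placed in locus ", em$info$locus_id[i],
                  "; kept as unaligned")
  }
  structure(list(matrix = em, libraries = em$libraries),
            class = "isomir_catalog")
}

#' @export
print.isomir_catalog <- function(x, ...) {
  cat("<isomir_catalog>\n  ")
  print(x$matrix)
  invisible(x)
}

# Rank rows of a value matrix slice for one locus: highest value first, ties
# broken by total abundance across all libraries, then lexicographically.
rank_rows <- function(values, totals, seqs) {
  order(-values, -totals, seqs)
}

#' Dominance table: most frequent isomiR per locus
#'
#' Ranks each locus' variants by RPM within every library (and within every
#' tissue, using the arithmetic mean of its replicates) and reports the
#' dominant and second-most-frequent read. Ties are broken by total
#' abundance over all libraries, then lexicographically, and flagged.
#'
#' @param em An `expression_matrix` (per-locus layout) or `isomir_catalog`.
#' @return A list of class `dominance_report` with data frames `by_library`
#'   (locus_id, library_id, dominant, dominant_rpm, second, second_rpm, tie)
#'   and `by_tissue` (same per tissue on replicate-averaged RPM).
#' @export
dominance_table <- function(em) {
  if (inherits(em, "isomir_catalog")) em <- em$matrix
  stopifnot(inherits(em, "expression_matrix"))
  totals <- rowSums(em$values)
  tissues <- unique(tissue_of(em$libraries))
  tissue_means <- vapply(tissues, function(tt)
    rowMeans(em$values[, tissue_of(em$libraries) == tt, drop = FALSE]),
    numeric(nrow(em$values)))
  if (is.null(dim(tissue_means)))
    tissue_means <- matrix(tissue_means, ncol = length(tissues),
                           dimnames = list(NULL, tissues))
  one_level <- function(vals, cols) {
    rows <- list()
    for (lid in unique(em$info$locus_id)) {
      ix <- which(em$info$locus_id == lid)
      for (cc in cols) {
        v <- vals[ix, cc]
        if (all(v == 0)) {
          rows[[length(rows) + 1]] <- data.frame(
            locus_id = lid, column = cc, dominant = NA_character_,
            dominant_rpm = 0, second = NA_character_, second_rpm = NA_real_,
            tie = FALSE, stringsAsFactors = FALSE)
          next
        }
        o <- rank_rows(v, totals[ix], em$info$sequence[ix])
        rows[[length(rows) + 1]] <- data.frame(
          locus_id = lid, column = cc,
          dominant = em$info$sequence[ix][o[1]], dominant_rpm = v[o[1]],
          second = if (length(o) > 1) em$info$sequence[ix][o[2]] else NA_character_,
          second_rpm = if (length(o) > 1) v[o[2]] else NA_real_,
          tie = length(o) > 1 && v[o[1]] == v[o[2]],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  by_library <- one_level(em$values, em$libraries)
  names(by_library)[2] <- "library_id"
  by_tissue <- one_level(tissue_means, tissues)
  names(by_tissue)[2] <- "tissue"
  structure(list(by_library = by_library, by_tissue = by_tissue,
                 tissues = tissues),
            class = "dominance_report")
}

#' @export
print.dominance_report <- function(x, ...) {
  nloc <- length(unique(x$by_library$locus_id))
  cat("<dominance_report>", nloc, "loci x",
      length(unique(x$by_library$library_id)), "libraries;",
      length(sample_invariant_dominants(x)), "distinct sample-invariant",
      "dominant reads\n")
  invisible(x)
}

#' Sample-invariant dominant reads
#'
#' The distinct dominant reads of loci whose most frequent read is identical
#' across samples. At `level = "library"` (default) a locus qualifies when
#' the same read dominates every library, i.e. in all samples and all
#' replicates; `level = "tissue"` relaxes this to the replicate-averaged
#' dominant being identical across tissues.
#'
#' @param report A [dominance_table()] result.
#' @param level `"library"` or `"tissue"`.
#' @return Character vector of distinct dominant sequences.
#' @export
sample_invariant_dominants <- function(report, level = c("library", "tissue")) {
  level <- match.arg(level)
  d <- if (level == "library") report$by_library else report$by_tissue
  doms <- split(d$dominant, d$locus_id)
  inv <- vapply(doms, function(v) !anyNA(v) && length(unique(v)) == 1,
                logical(1))
  unique(vapply(doms[inv], `[`, character(1), 1))
}

#' 5' composition of locus expression
#'
#' Fraction of each locus' RPM carried by variants whose first nucleotide is
#' `T` (uridine in the RNA), per library, plus whether the locus' dominant
#' variant starts with `T` — quantifying the tendency of processing variants
#' to preserve the 5' uridine that drives AGO1 association.
#'
#' @param em An `expression_matrix` or `isomir_catalog`.
#' @return Data frame: `locus_id`, `library_id`, `fraction_5p_T` (`NA` when
#'   the locus has no expression in the library), `dominant_starts_T`.
#' @export
five_prime_composition <- function(em) {
  if (inherits(em, "isomir_catalog")) em <- em$matrix
  stopifnot(inherits(em, "expression_matrix"))
  startsT <- startsWith(em$info$sequence, "T")
  totals <- rowSums(em$values)
  rows <- list()
  for (lid in unique(em$info$locus_id)) {
    ix <- which(em$info$locus_id == lid)
    for (lib in em$libraries) {
      v <- em$values[ix, lib]
      tot <- sum(v)
      frac <- if (tot == 0) NA_real_ else sum(v[startsT[ix]]) / tot
      dom <- if (tot == 0) NA else
        startsT[ix][rank_rows(v, totals[ix], em$info$sequence[ix])[1]]
      rows[[length(rows) + 1]] <- data.frame(
        locus_id = lid, library_id = lib, fraction_5p_T = frac,
        dominant_starts_T = dom, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
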