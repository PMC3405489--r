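#' Dicer cut-site heterogeneity model
#'
#' Probability tables for the 5' and 3' cleavage-offset of isomiRs relative
#' to the reference arm sequence, plus the fraction of a locus' reads that
#' originate from the mature arm (the rest come from the star arm). Offsets
#' are in precursor 5'->3' orientation; negative 5' offsets extend the 5'
#' end, positive 3' offsets extend the 3' end.
#'
#' @param offset5_probs,offset3_probs Named numeric vectors mapping integer
#'   offsets in `[-3, 3]` to probabilities; each must sum to 1.
#' @param arm_mature_fraction Fraction of locus reads from the mature arm,
#'   in (0, 1].
#' @return An object of class `cut_site_model`.
#' @export
cut_site_model <- function(offset5_probs = c("-1" = 0.10, "0" = 0.75, "1" = 0.15),
                           offset3_probs = c("-1" = 0.15, "0" = 0.55, "1" = 0.20,
                                             "2" = 0.10),
                           arm_mature_fraction = 0.8) {
  for (p in list(offset5_probs, offset3_probs)) {
    if (is.null(names(p)) || any(is.na(as.integer(names(p)))))
      stop("offset probabilities must be named by integer offsets")
    if (any(abs(as.integer(names(p))) > 3))
      stop("offsets must lie within [-3, 3]")
    if (abs(sum(p) - 1) > 1e-9)
      stop("offset probabilities must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop("probabilities must be non-negative")
  }
  if (arm_mature_fraction <= 0 || arm_mature_fraction > 1)
    stop("arm_mature_fraction must be in (0, 1]")
  structure(list(offset5_probs = offset5_probs, offset3_probs = offset3_probs,
                 arm_mature_fraction = arm_mature_fraction),
            class = "cut_site_model")
}

#' Simulation configuration
#'
#' Defaults emulate the reference study's design: five tissues (BF, F, GF,
#' GL, O) with three replicates each, 18-24 nt inserts read on a 36 nt
#' machine read with a 3' adapter, moderate negative-binomial replicate
#' noise, and small contaminant / low-complexity spike-in fractions.
#'
#' @param tissues Tissue codes.
#' @param replicates_per_tissue Replicates per tissue.
#' @param depth Expected reads per library.
#' @param dispersion Negative-binomial dispersion of per-(library, isomiR)
#'   counts; `0` means deterministic expected counts.
#' @param tissue_effects Optional loci-by-tissues matrix of fold changes
#'   (default: none, i.e. the null).
#' @param contaminant_fraction,low_complexity_fraction Fractions of reads
#'   drawn from rRNA/tRNA-like references and homopolymers, in `[0, 1)`.
#' @param adapter3 3' adapter sequence appended to every insert.
#' @param read_length Machine read length.
#' @param cut_model A [cut_site_model()] shared by all loci, or a list of one
#'   per locus.
#' @param locus_abundance Optional relative expression of each locus; by
#'   default drawn once (log-normal, sdlog 1) from `seed`.
#' @param seed Master seed; every library derives its own stream from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(tissues = c("BF", "F", "GF", "GL", "O"),
                              replicates_per_tissue = 3,
                              depth = 1e5,
                              dispersion = 0.05,
                              tissue_effects = NULL,
                              contaminant_fraction = 0.05,
                              low_complexity_fraction = 0.02,
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 36,
                              cut_model = cut_site_model(),
                              locus_abundance = NULL,
                              seed = 1) {
  stopifnot(depth > 0, dispersion >= 0, nchar(adapter3) > 0,
            replicates_per_tissue >= 1)
  for (f in c(contaminant_fraction, low_complexity_fraction))
    if (f < 0 || f >= 1) stop("spike-in fractions must be in [0, 1)")
  if (contaminant_fraction + low_complexity_fraction >= 1)
    stop("spike-in fractions must leave room for locus reads")
  structure(list(tissues = tissues,
                 replicates_per_tissue = replicates_per_tissue,
                 depth = depth, dispersion = dispersion,
                 tissue_effects = tissue_effects,
                 contaminant_fraction = contaminant_fraction,
                 low_complexity_fraction = low_complexity_fraction,
                 adapter3 = adapter3, read_length = read_length,
                 cut_model = cut_model, locus_abundance = locus_abundance,
                 seed = seed),
            class = "simulation_config")
}

#' Generate a random genome
#'
#' @param length Genome length in nt (> 0).
#' @param seed Seed for the i.i.d. uniform A/C/G/T draw.
#' @param chrom Chromosome name.
#' @return An object of class `sim_genome`: a list with the `seq` (character)
#'   and an initially empty `loci` registry ([plant_precursor()] fills it).
#' @export
make_genome <- function(length, seed = 1, chrom = "chr1") {
  if (length <= 0) stop("genome length must be positive")
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  structure(list(seq = seq, chrom = chrom,
                 loci = structure(list(), class = "locus_set")),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>", x$chrom, "of", nchar(x$seq), "nt with",
      length(x$loci), "planted loci\n")
  invisible(x)
}

#' Plant a miRNA hairpin precursor into a genome
#'
#' Overwrites the genome at `position` with a synthetic fold-back: a 2 nt 5'
#' flank, the mature sequence, a random loop, and the reverse complement of
#' the 5' stem. The star sequence is the reverse complement of the
#' mature-pairing region shifted so that the miRNA/miRNA* duplex carries the
#' standard 2 nt 3' overhang on each strand.
#'
#' @param genome A `sim_genome`.
#' @param position 1-based genome start of the precursor.
#' @param mature_seq Mature miRNA sequence, 18-24 nt.
#' @param locus_id Locus name (default `locus_<n>`).
#' @param loop_len Loop length between the two stems.
#' @param seed Seed for the random loop.
#' @return The modified `sim_genome`, with the new locus appended to
#'   `$loci`. Planting over a previously planted locus is an error.
#' @export
plant_precursor <- function(genome, position, mature_seq,
                            locus_id = NULL, loop_len = 15, seed = 1) {
  stopifnot(inherits(genome, "sim_genome"))
  L <- nchar(mature_seq)
  if (L < 18 || L > 24) stop("mature sequence must be 18-24 nt, got ", L)
  if (!grepl("^[ACGT]+$", mature_seq)) stop("mature sequence must be A/C/G/T")
  if (is.null(locus_id)) locus_id <- paste0("locus_", length(genome$loci) + 1)
  stem5 <- paste0(with_seed(seed + 7L, paste(
    sample(c("A", "C", "G", "T"), 2, replace = TRUE), collapse = "")), mature_seq)
  loop <- with_seed(seed + 11L, paste(
    sample(c("A", "C", "G", "T"), loop_len, replace = TRUE), collapse = ""))
  stem3 <- revcomp(stem5)
  # 4 nt pads on both sides so end-offset variants up to +/-3 nt stay within
  # the precursor (real pri-miRNAs extend beyond the duplex)
  pads <- with_seed(seed + 13L, replicate(2, paste(
    sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = "")))
  precursor <- paste0(pads[1], stem5, loop, stem3, pads[2])
  plen <- nchar(precursor)
  if (position < 1 || position + plen - 1 > nchar(genome$seq))
    stop("precursor does not fit in the genome at position ", position)
  new_iv <- c(position, position + plen - 1)
  for (loc in genome$loci)
    if (new_iv[1] <= loc$end && loc$start <= new_iv[2])
      stop("placement error: locus at ", position, " overlaps ", loc$locus_id)
  # star = revcomp of stem5[1..L]: the last L nt of the 3' stem.
  # Duplex geometry: mature pairs stem5[3..L+2], star pairs stem5[1..L],
  # leaving 2 nt 3' overhangs on both strands.
  star_seq <- substr(stem3, nchar(stem3) - L + 1, nchar(stem3))
  loc <- list(locus_id = locus_id, chrom = genome$chrom,
              start = position, end = position + plen - 1, strand = "+",
              precursor_seq = precursor,
              mature_seq = mature_seq, mature_start = 7, mature_end = L + 6,
              star_seq = star_seq,
              star_start = plen - L - 3, star_end = plen - 4)
  substr(genome$seq, position, position + plen - 1) <- precursor
  genome$loci[[locus_id]] <- loc
  genome
}

# Enumerate the isomiR universe of a locus under a cut model: one row per
# (arm, offset5, offset3) with its probability and realized sequence.
# Offsets running beyond the precursor are clipped with a warning.
enumerate_isomirs <- function(locus, cut_model) {
  arms <- data.frame(arm = "mature", p_arm = cut_model$arm_mature_fraction)
  if (!is.null(locus$star_seq) && cut_model$arm_mature_fraction < 1)
    arms <- rbind(arms, data.frame(arm = "star",
                                   p_arm = 1 - cut_model$arm_mature_fraction))
  plen <- nchar(locus$precursor_seq)
  out <- list()
  for (ai in seq_len(nrow(arms))) {
    arm <- arms$arm[ai]
    rs <- locus[[paste0(arm, "_start")]]
    re <- locus[[paste0(arm, "_end")]]
    for (o5 in as.integer(names(cut_model$offset5_probs))) {
      for (o3 in as.integer(names(cut_model$offset3_probs))) {
        s <- rs + o5; e <- re + o3
        if (s < 1 || e > plen) {
          warning("offset (", o5, ",", o3, ") extends beyond the precursor of ",
                  locus$locus_id, "; clipped")
          s <- max(1, s); e <- min(plen, e)
        }
        out[[length(out) + 1]] <- data.frame(
          arm = arm, offset5 = o5, offset3 = o3,
          sequence = substr(locus$precursor_seq, s, e),
          prob = arms$p_arm[ai] *
            cut_model$offset5_probs[[as.character(o5)]] *
            cut_model$offset3_probs[[as.character(o3)]])
      }
    }
  }
  d <- do.call(rbind, out)
  d[d$prob > 0, , drop = FALSE]
}

#' Sample isomiR counts for one locus
#'
#' Draws the per-variant composition of a locus' reads: the total count is
#' the expected total scaled by a negative-binomial library factor (gamma
#' mixing, mean 1, variance `dispersion`; deterministic when
#' `dispersion = 0`), then split multinomially over (arm, offset5, offset3)
#' according to the cut model.
#'
#' @param locus A locus model (element of a `locus_set` or `sim_genome$loci`).
#' @param cut_model A [cut_site_model()].
#' @param expected_total Expected total read count for the locus (> 0).
#' @param dispersion Negative-binomial dispersion of the library factor.
#' @return A data frame with columns `sequence`, `arm`, `offset5`, `offset3`,
#'   `count`.
#' @export
sample_isomir_counts <- function(locus, cut_model, expected_total,
                                 dispersion = 0) {
  if (expected_total <= 0) stop("expected_total must be positive")
  u <- enumerate_isomirs(locus, cut_model)
  n <- if (dispersion == 0) round(expected_total)
       else stats::rnbinom(1, mu = expected_total, size = 1 / dispersion)
  u$count <- as.integer(stats::rmultinom(1, n, u$prob))
  u$prob <- NULL
  u
}

#' Simulate one small RNA-seq library
#'
#' Emits machine reads for one (tissue, replicate) library: every planted
#' isomiR's insert with its 3' adapter appended and truncated to the machine
#' read length, plus contaminant reads copied from the configured rRNA/tRNA
#' references and low-complexity homopolymers at the configured fractions.
#' Counts per isomiR are negative-binomial with mean
#' `depth x locus share x cut-model probability` and common dispersion
#' (exactly the rounded mean when `dispersion = 0`). A ground-truth table
#' records every isomiR's arm, offsets, true count and expected RPM.
#'
#' @param genome A `sim_genome` with planted loci (or a `locus_set` plus
#'   `contaminants`).
#' @param config A [simulation_config()].
#' @param tissue Tissue code (must appear in `config$tissues`).
#' @param replicate Replicate number.
#' @param contaminants Character vector of contaminant reference sequences
#'   (defaults to two generated rRNA/tRNA-like references derived from
#'   `config$seed`).
#' @return A list with `fastq` (data frame `id`, `sequence`, `quality`),
#'   `truth` (data frame `sequence`, `locus_id`, `arm`, `offset5`, `offset3`,
#'   `count`, `expected_rpm`), `counts` (insert-level tallies per category)
#'   and `library_id`.
#' @export
simulate_library <- function(genome, config, tissue, replicate,
                             contaminants = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!tissue %in% config$tissues)
    stop("unknown tissue '", tissue, "'; configured: ",
         paste(config$tissues, collapse = ", "))
  loci <- if (inherits(genome, "sim_genome")) genome$loci else genome
  if (length(loci) == 0) stop("no loci to simulate from")
  if (is.null(contaminants))
    contaminants <- default_contaminants(config$seed)
  tidx <- match(tissue, config$tissues)
  lib_seed <- derive_seed(config$seed, tidx, replicate)
  library_id <- paste0(tissue, replicate)

  abund <- config$locus_abundance
  if (is.null(abund))
    abund <- with_seed(derive_seed(config$seed, 999L),
                       stats::rlnorm(length(loci), sdlog = 1))
  abund <- rep_len(abund, length(loci))
  if (!is.null(config$tissue_effects))
    abund <- abund * rep_len(config$tissue_effects[, tidx], length(loci))
  share <- abund / sum(abund)

  cms <- config$cut_model
  if (inherits(cms, "cut_site_model")) cms <- rep(list(cms), length(loci))

  locus_depth <- config$depth *
    (1 - config$contaminant_fraction - config$low_complexity_fraction)
  truth <- with_seed(lib_seed, {
    rows <- lapply(seq_along(loci), function(i) {
      u <- enumerate_isomirs(loci[[i]], cms[[i]])
      u$locus_id <- loci[[i]]$locus_id
      u$mu <- locus_depth * share[i] * u$prob
      u
    })
    d <- do.call(rbind, rows)
    d$count <- if (config$dispersion == 0) as.integer(round(d$mu)) else
      stats::rnbinom(nrow(d), mu = d$mu, size = 1 / config$dispersion)
    d
  })
  truth$expected_rpm <- truth$mu / sum(truth$mu) * 1e6
  truth <- truth[c("sequence", "locus_id", "arm", "offset5", "offset3",
                   "count", "expected_rpm")]

  n_cont <- round(config$depth * config$contaminant_fraction)
  n_lc <- round(config$depth * config$low_complexity_fraction)
  spikes <- with_seed(derive_seed(lib_seed, 2L), {
    cont <- character(0)
    if (n_cont > 0) {
      ref <- sample(contaminants, n_cont, replace = TRUE)
      len <- sample(18:24, n_cont, replace = TRUE)
      st <- vapply(seq_len(n_cont),
                   function(i) sample.int(nchar(ref[i]) - len[i] + 1, 1),
                   integer(1))
      cont <- substr(ref, st, st + len - 1)
      # half of the contaminant reads come off the antisense strand
      flip <- seq_len(n_cont) %% 2 == 0
      cont[flip] <- revcomp(cont[flip])
    }
    lc <- character(0)
    if (n_lc > 0)
      lc <- strrep(sample(c("A", "C", "G", "T"), n_lc, replace = TRUE),
                   sample(18:24, n_lc, replace = TRUE))
    list(cont = cont, lc = lc)
  })

  inserts <- c(rep(truth$sequence, truth$count), spikes$cont, spikes$lc)
  reads <- substr(paste0(inserts, strrep(config$adapter3,
                                         ceiling(config$read_length / nchar(config$adapter3)) + 1)),
                  1, config$read_length)
  fastq <- data.frame(
    id = sprintf("%s_read%06d", library_id, seq_along(reads)),
    sequence = reads,
    quality = strrep("I", config$read_length),
    stringsAsFactors = FALSE)
  list(fastq = fastq, truth = truth,
       counts = c(total = length(inserts),
                  locus = sum(truth$count),
                  contaminant = length(spikes$cont),
                  low_complexity = length(spikes$lc)),
       library_id = library_id)
}

# Two fixed-length pseudo rRNA/tRNA references, reproducible from the seed.
default_contaminants <- function(seed) {
  with_seed(derive_seed(seed, 77L), {
    vapply(c(1500, 300), function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
  })
}

#' Simulate a full multi-tissue experiment
#'
#' Builds a genome, plants `n_loci` hairpin loci with random mature
#' sequences, and simulates every (tissue, replicate) library of the
#' configured design.
#'
#' @param config A [simulation_config()].
#' @param n_loci Number of hairpin loci to plant.
#' @param genome_length Genome length in nt.
#' @return A list with `genome` (a `sim_genome`), `contaminants`,
#'   `libraries` (named list of [simulate_library()] results) and `config`.
#' @export
simulate_experiment <- function(config = simulation_config(), n_loci = 20,
                                genome_length = 1e5) {
  genome <- make_genome(genome_length, seed = derive_seed(config$seed, 1L))
  span <- 120 + 30  # precursor footprint upper bound plus spacing
  if (n_loci * span > genome_length - span)
    stop("genome too short for ", n_loci, " loci")
  positions <- round(seq(50, genome_length - span, length.out = n_loci))
  matures <- with_seed(derive_seed(config$seed, 3L), {
    # 20-21 nt so every default cut-model variant stays in the 18-24 window
    lens <- sample(20:21, n_loci, replace = TRUE)
    vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  })
  for (i in seq_len(n_loci))
    genome <- plant_precursor(genome, positions[i], matures[i],
                              locus_id = sprintf("sim_%02d", i),
                              seed = derive_seed(config$seed, 4L, i))
  contaminants <- default_contaminants(config$seed)
  libraries <- list()
  for (tissue in config$tissues)
    for (rep_i in seq_len(config$replicates_per_tissue)) {
      lib <- simulate_library(genome, config, tissue, rep_i, contaminants)
      libraries[[lib$library_id]] <- lib
    }
  list(genome = genome, contaminants = contaminants,
       libraries = libraries, config = config)
}
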