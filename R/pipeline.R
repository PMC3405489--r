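#' Summarize per-library filtering statistics
#'
#' Totals and per-library means of the filtering cascade accounting: total
#' raw reads, mean raw reads, and mean genome-matched reads (means rounded
#' to the nearest integer; the total is exact integer arithmetic).
#'
#' @param rows A `filter_stats` data frame (see [load_table1_fixture()]).
#' @param n_expected Expected number of libraries; a different row count is
#'   an error (`NULL` to skip the check).
#' @return Named list: `total_raw`, `mean_raw`, `mean_genome_matched`.
#' @export
summarize_filter_stats <- function(rows, n_expected = 15) {
  stopifnot(inherits(rows, "data.frame"))
  if (!is.null(n_expected) && nrow(rows) != n_expected)
    stop("expected ", n_expected, " libraries, got ", nrow(rows))
  list(total_raw = sum(as.numeric(rows$raw)),
       mean_raw = round(mean(rows$raw)),
       mean_genome_matched = round(mean(rows$genome_matched_r)))
}

#' Run the simulation -> filtering -> catalog -> statistics pipeline
#'
#' End-to-end orchestration on synthetic data: simulates every library of
#' the configured design, runs the filtering cascade against the simulated
#' genome and loci, builds the annotated isomiR catalog, and computes the
#' downstream reports. Deterministic for a fixed configuration.
#'
#' @param config A [simulation_config()].
#' @param n_loci,genome_length Passed to [simulate_experiment()].
#' @param alpha Significance level for the differential tests.
#' @param exclusions Sequences/accessions excluded from concordance.
#' @param out_dir Optional directory; when given, the catalog and reports
#'   are written as TSV/Newick files with provenance headers.
#' @return A list of class `analysis_reports`: `experiment`, `libraries`
#'   (cascade results), `filter_stats`, `catalog`, `concordance`,
#'   `differential`, `dominance`, `clustering` (all-reads and dominant-only),
#'   `five_prime`.
#' @export
run_pipeline <- function(config = simulation_config(), n_loci = 20,
                         genome_length = 1e5, alpha = 0.05,
                         exclusions = character(), out_dir = NULL) {
  exp <- simulate_experiment(config, n_loci = n_loci,
                             genome_length = genome_length)
  fc <- filter_config(adapter3 = config$adapter3,
                      contaminant_set = exp$contaminants)
  libs <- lapply(exp$libraries, function(lib)
    run_cascade(lib$fastq, exp$genome, exp$genome$loci, fc,
                library_id = lib$library_id))
  stats_tab <- do.call(rbind, lapply(libs, `[[`, "stats"))
  rownames(stats_tab) <- NULL
  catalog <- build_catalog(libs, exp$genome$loci)
  conc <- concordance(catalog, exclusions = exclusions)
  diffs <- pairwise_ttests(catalog, alpha = alpha)
  doms <- dominance_table(catalog)
  clus <- list(all_reads = cluster_samples(catalog, "all_reads"),
               dominant_only = tryCatch(
                 cluster_samples(catalog, "dominant_only", "replicate"),
                 error = function(e) NULL))
  reports <- structure(list(experiment = exp, libraries = libs,
                            filter_stats = stats_tab, catalog = catalog,
                            concordance = conc, differential = diffs,
                            dominance = doms, clustering = clus,
                            five_prime = five_prime_composition(catalog)),
                       class = "analysis_reports")
  if (!is.null(out_dir)) write_reports(reports, out_dir, config)
  reports
}

#' @export
print.analysis_reports <- function(x, ...) {
  cat("<analysis_reports>\n")
  print(x$catalog)
  print(x$concordance)
  print(x$differential)
  invisible(x)
}

provenance_header <- function(config) {
  c(paste0("mirnome ", as.character(utils::packageVersion("mirnome"))),
    paste0("seed: ", config$seed),
    paste0("config: ", paste(deparse(config, control = c("all")),
                             collapse = "")))
}

# Re-read the RunConfig recorded in a provenance header written by
# write_reports().
parse_provenance <- function(path) {
  lines <- grep("^# ", readLines(path), value = TRUE)
  cfg_line <- sub("^# config: ", "", grep("^# config: ", lines, value = TRUE))
  eval(parse(text = cfg_line))
}

write_reports <- function(reports, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(config)
  write_tsv <- function(d, file) {
    con <- file(file.path(out_dir, file), "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_expression_matrix(reports$catalog$matrix,
                          file.path(out_dir, "catalog.tsv"), header = hdr)
  write_tsv(reports$filter_stats, "filter_stats.tsv")
  write_tsv(reports$concordance$pairs, "concordance.tsv")
  p <- reports$differential$p_values
  write_tsv(data.frame(sequence = rownames(p), p, check.names = FALSE),
            "ttests.tsv")
  write_tsv(reports$dominance$by_library, "dominance.tsv")
  write_tsv(reports$five_prime, "five_prime.tsv")
  if (!is.null(reports$clustering$all_reads))
    write_newick(reports$clustering$all_reads,
                 file.path(out_dir, "clusters_all_reads.nwk"))
  if (!is.null(reports$clustering$dominant_only))
    write_newick(reports$clustering$dominant_only,
                 file.path(out_dir, "clusters_dominant.nwk"))
  invisible(out_dir)
}

#' Recompute the reference results from the packaged dataset
#'
#' Recomputes every desk-checkable statistic of the packaged reference
#' dataset — Table-1 style summaries, within/cross-tissue Pearson averages,
#' the locus 3_16 arm ratios, the significant-comparison count of the locus
#' 4_21 dominant isomiR, and the sample-invariant dominant reads — and
#' compares each against its recorded reference value.
#'
#' @return A data frame of class `reproduction_report` with columns
#'   `metric`, `computed`, `reference`, `pass`.
#' @export
reproduce_study <- function() {
  t1 <- load_table1_fixture()
  em <- load_table2_fixture()
  s <- summarize_filter_stats(t1)
  conc <- concordance(em, exclusions = "HE860285")
  ar <- arm_ratio(em, "3_16", mature_acc = "HE860348", star_acc = "HE860347",
                  pools = list(`GF+GL` = c("GF", "GL")))
  tt <- pairwise_ttests(em)
  seq_4_21 <- accession_sequences(em, "HE860366", locus_id = "4_21")
  doms <- dominance_table(em)
  inv <- sample_invariant_dominants(doms)
  o_dom <- doms$by_library[doms$by_library$locus_id == "3_16" &
                             doms$by_library$library_id %in%
                             c("O1", "O2", "O3"), "dominant"]
  star_seq <- accession_sequences(em, "HE860347", locus_id = "3_16")

  ref <- list(
    total_raw = c(s$total_raw, 40764330),
    mean_raw = c(s$mean_raw, 2717622),
    mean_genome_matched = c(s$mean_genome_matched, 664777),
    pearson_BF = c(conc$tissue_means[["BF"]], 0.98),
    pearson_F = c(conc$tissue_means[["F"]], 0.95),
    pearson_GF = c(conc$tissue_means[["GF"]], 0.98),
    pearson_GL = c(conc$tissue_means[["GL"]], 0.95),
    pearson_O = c(conc$tissue_means[["O"]], 0.97),
    pearson_cross = c(conc$cross_mean, 0.66),
    arm_ratio_O = c(round(ar$tissue_means[["O"]], 1), 0.4),
    arm_ratio_GF_GL = c(round(ar$pooled[["GF+GL"]], 1), 5.7),
    sig_tests_4_21 = c(unname(tt$n_significant[seq_4_21]), 8),
    dominant_O_is_star = c(as.numeric(all(o_dom == star_seq)), 1),
    invariant_dominants = c(length(inv), 16))
  out <- data.frame(metric = names(ref),
                    computed = vapply(ref, `[`, numeric(1), 1),
                    reference = vapply(ref, `[`, numeric(1), 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pass <- out$computed == out$reference
  class(out) <- c("reproduction_report", "data.frame")
  out
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Reference-dataset reproduction:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-22s computed %12g  reference %12g  [%s]\n",
                x$metric[i], x$computed[i], x$reference[i],
                if (x$pass[i]) "pass" else "FAIL"))
  cat(if (all(x$pass)) "all checks pass\n" else "SOME CHECKS FAIL\n")
  invisible(x)
}
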