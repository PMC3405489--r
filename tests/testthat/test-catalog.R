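test_that("RPM normalization is exact and linear", {
  expect_equal(normalize_counts(0, 1000), 0)
  expect_equal(normalize_counts(7, 700000), 10)
  # arithmetic on a real library denominator
  expect_equal(normalize_counts(1, 797297), 1e6 / 797297, tolerance = 1e-12)
  expect_error(normalize_counts(5, 0, "BF1"), "BF1")
  # linearity: scaling counts and total together leaves RPM unchanged
  set.seed(71)
  raw <- rpois(50, 20)
  expect_equal(normalize_counts(raw, 12345),
               normalize_counts(raw * 7, 12345 * 7))
})

test_that("annotate_isomir recovers arm and offsets", {
  loc <- toy_locus()
  expect_equal(annotate_isomir(loc$mature_seq, loc)[c("arm", "offset5", "offset3")],
               list(arm = "mature", offset5 = 0L, offset3 = 0L))
  # star read one base longer at the 3' end
  star_plus <- substr(loc$precursor_seq, loc$star_start, loc$star_end + 1)
  got <- annotate_isomir(star_plus, loc)
  expect_equal(got[c("arm", "offset5", "offset3")],
               list(arm = "star", offset5 = 0L, offset3 = 1L))
  # brute-force placement oracle: exhaustive search over all precursor
  # substrings agrees with the reported placement
  plen <- nchar(loc$precursor_seq)
  L <- nchar(star_plus)
  brute <- which(vapply(seq_len(plen - L + 1), function(s)
    substr(loc$precursor_seq, s, s + L - 1) == star_plus, logical(1)))
  expect_equal(brute, loc$star_start + got$offset5)

  # unplaceable and far-out sequences are unaligned
  expect_equal(annotate_isomir("GGGGGGGGGGGGGGGGGG", loc)$arm, "unaligned")
  loop_read <- substr(loc$precursor_seq, loc$mature_end + 9, loc$mature_end + 28)
  expect_equal(annotate_isomir(loop_read, loc, max_offset = 8)$arm, "unaligned")
})

test_that("5' template variants differ by exactly their end offsets", {
  # two prevalent variants differing by one 5' T, as at locus 1_26
  v_short <- "TTGCCAACCCCGCCCATTCCAA"
  v_long <- "TTTGCCAACCCCGCCCATTCCAA"
  stem5 <- paste0("CA", v_long)
  pre <- paste0("ACGT", stem5, "GTCAAGTTCAAGTCA", mirnome:::revcomp(stem5), "ACGT")
  loc <- list(locus_id = "t26", precursor_seq = pre,
              mature_seq = v_short, mature_start = 7 + 1,
              mature_end = 7 + nchar(v_short))
  a_long <- annotate_isomir(v_long, loc)
  a_short <- annotate_isomir(v_short, loc)
  expect_equal(a_short$arm, "mature")
  expect_equal(a_long$arm, "mature")
  expect_equal(a_short$offset5 - a_long$offset5, 1L)
  expect_equal(a_short$offset3, a_long$offset3)
})

test_that("build_catalog reproduces the simulator's truth table", {
  cfg <- simulation_config(depth = 6000, contaminant_fraction = 0.05,
                           low_complexity_fraction = 0.02, seed = 81)
  exp <- simulate_experiment(cfg, n_loci = 6, genome_length = 3e4)
  fc <- filter_config(adapter3 = cfg$adapter3,
                      contaminant_set = exp$contaminants)
  libs <- lapply(exp$libraries[c("BF1", "BF2", "F1")], function(l)
    run_cascade(l$fastq, exp$genome, exp$genome$loci, fc, l$library_id))
  cat <- build_catalog(libs, exp$genome$loci)
  info <- cat$matrix$info
  key <- paste(info$locus_id, info$sequence)
  tru <- exp$libraries[["BF1"]]$truth
  tru <- tru[tru$count > 0, ]
  tk <- paste(tru$locus_id, tru$sequence)
  expect_true(all(tk %in% key))
  ix <- match(tk, key)
  expect_identical(info$arm[ix], tru$arm)
  expect_identical(info$offset5[ix], tru$offset5)
  expect_identical(info$offset3[ix], tru$offset3)
  # RPM equals count / genome-matched total x 1e6
  lib <- libs[["BF1"]]
  rpm <- cat$matrix$values[ix, "BF1"]
  expect_equal(rpm, unname(tru$count / lib$genome_matched_total * 1e6))
})

test_that("catalog built from the packaged table keeps its structure", {
  em <- load_table2_fixture()
  cat <- build_catalog(em)
  expect_equal(length(unique(cat$matrix$info$locus_id)), 26)
  expect_equal(ncol(cat$matrix$values), 15)
})

test_that("dominance ranking matches the reference catalog", {
  em <- load_table2_fixture()
  doms <- dominance_table(em)
  bl <- doms$by_library
  r <- bl[bl$locus_id == "1_25" & bl$library_id == "BF1", ]
  expect_equal(r$dominant, "TTTCCGAAACCTCCCATTCCAA")  # HE860304
  expect_equal(r$dominant_rpm, 1135.1)
  expect_equal(r$second, "GGGTGAGAGGTTGCCGGAAAGA")    # HE860434
  expect_equal(r$second_rpm, 32.6)
  # dominant rpm >= second rpm >= every other variant, per (locus, library)
  expect_true(all(r$dominant_rpm >= r$second_rpm))
  ix <- em$info$locus_id == "1_25"
  expect_true(all(r$second_rpm >= sort(em$values[ix, "BF1"],
                                       decreasing = TRUE)[-(1:2)]))
  # all three O replicates of locus 3_16 are dominated by the star read
  star_316 <- unique(em$info$sequence[em$info$accession == "HE860347"])
  o_doms <- bl$dominant[bl$locus_id == "3_16" &
                          bl$library_id %in% c("O1", "O2", "O3")]
  expect_identical(o_doms, rep(star_316, 3))
})

test_that("dominance handles degenerate loci", {
  libs <- design_libs()
  em <- toy_em(list(AAACCCGGGTTTAAACCCGG = rep(5, 15)), libs)
  d <- dominance_table(em)
  expect_identical(unique(d$by_library$dominant), "AAACCCGGGTTTAAACCCGG")
  expect_true(all(is.na(d$by_library$second)))
  em0 <- toy_em(list(AAACCCGGGTTTAAACCCGG = rep(0, 15)), libs)
  d0 <- dominance_table(em0)
  expect_true(all(is.na(d0$by_library$dominant)))
})

test_that("sample-invariant dominants respect the chosen level", {
  libs <- design_libs()
  # locus L1: same dominant everywhere; locus L2: dominance switch in O
  v1 <- rep(10, 15); v2 <- rep(3, 15)
  w1 <- c(rep(10, 12), 1, 1, 1); w2 <- c(rep(2, 12), 8, 8, 8)
  em <- expression_matrix(
    data.frame(locus_id = c("L1", "L1", "L2", "L2"),
               sequence = c("TACCGGTTACCGGTTACCGG", "CCGGTTAACCGGTTAACCGG",
                            "TTGGCCAATTGGCCAATTGG", "GGTTAACCGGTTAACCGGTT")),
    rbind(v1, v2, w1, w2) |> `colnames<-`(libs))
  d <- dominance_table(em)
  inv <- sample_invariant_dominants(d)
  expect_identical(inv, "TACCGGTTACCGGTTACCGG")
  expect_identical(sample_invariant_dominants(d, level = "tissue"), inv)
  # degenerate: everything invariant -> one read per locus
  em2 <- expression_matrix(em$info, rbind(v1, v2, v1, v2) |> `colnames<-`(libs))
  expect_length(sample_invariant_dominants(dominance_table(em2)), 2)
})

test_that("5' composition fractions are exact", {
  libs <- design_libs()
  em <- toy_em(list(TACCGGTTACCGGTTACCGG = rep(3, 15),
                    ACCGGTTACCGGTTACCGGT = rep(1, 15)), libs)
  fp <- five_prime_composition(em)
  expect_true(all(fp$fraction_5p_T == 0.75))
  expect_true(all(fp$dominant_starts_T))

  all_t <- toy_em(list(TACCGGTTACCGGTTACCGG = rep(2, 15),
                       TTACCGGTTACCGGTTACCG = rep(9, 15)), libs)
  expect_true(all(five_prime_composition(all_t)$fraction_5p_T == 1))

  # reference catalog: the locus 1_25 dominant starts with T (5' uridine)
  em2 <- load_table2_fixture()
  fp2 <- five_prime_composition(em2)
  expect_true(fp2$dominant_starts_T[fp2$locus_id == "1_25" &
                                      fp2$library_id == "BF1"])
  # zero-abundance locus reports a missing fraction
  em0 <- toy_em(list(TACCGGTTACCGGTTACCGG = rep(0, 15)), libs)
  expect_true(all(is.na(five_prime_composition(em0)$fraction_5p_T)))
})
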