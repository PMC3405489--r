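test_that("pearson matches the definition formula", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  u <- c(1, 2, 3, 4); v <- c(1, 2, 3, 10)
  direct <- mean((u - mean(u)) * (v - mean(v))) /
    (sqrt(mean((u - mean(u))^2)) * sqrt(mean((v - mean(v))^2)))
  expect_equal(pearson(u, v), direct, tolerance = 1e-12)
  expect_warning(r <- pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
})

test_that("concordance is scale-invariant and honours exclusions", {
  libs <- design_libs()
  set.seed(91)
  base <- matrix(rexp(40 * 15, 1 / 100), 40, 15, dimnames = list(NULL, libs))
  # two proportional libraries correlate perfectly regardless of scale
  base[, "BF2"] <- base[, "BF1"] * 3.7
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""), character(1))
  em <- expression_matrix(data.frame(locus_id = "L1", sequence = seqs), base)
  cr <- concordance(em, exclusions = character())
  expect_equal(cr$pairs$r[cr$pairs$lib1 == "BF1" & cr$pairs$lib2 == "BF2"], 1)

  # a synthetic analogue of the abnormally abundant read: excluding it gives
  # the same report as never having had it
  spike <- matrix(rep(3e5 * (1 + 0.001 * seq_len(15)), each = 1), 1, 15,
                  dimnames = list(NULL, libs))
  em_sp <- expression_matrix(
    rbind(em$info, data.frame(locus_id = "L2",
                              sequence = "TCGGACCAGGCTTCATTCCCA")),
    rbind(base, spike))
  cr_excl <- concordance(em_sp, exclusions = "TCGGACCAGGCTTCATTCCCA")
  expect_equal(cr_excl$tissue_means, cr$tissue_means)
  expect_equal(order(cr_excl$tissue_means), order(cr$tissue_means))
  # ... while keeping it pins every correlation near one
  cr_keep <- concordance(em_sp, exclusions = character())
  expect_true(all(cr_keep$pairs$r > 0.99))

  expect_warning(concordance(em, exclusions = "HEnothere"), "unknown")
})

test_that("pairwise t-tests reproduce the pooled-variance formula", {
  # identical groups
  libs <- design_libs()
  em <- toy_em(list(TACCGGTTACCGGTTACCGG = rep(c(1, 2, 3), 5)), libs)
  tt <- pairwise_ttests(em)
  expect_true(all(tt$p_values == 1))

  # closed-form oracle on two real expression triplets (BF vs O of the
  # locus 4_21 dominant): pooled t with df = 4
  a <- c(356.2, 210.4, 280.2); b <- c(540.3, 700.2, 723.5)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  p_oracle <- 2 * pt(-abs(t_stat), df = 4)
  em2 <- toy_em(list(TGTGTTCTCAGGTCGCCCCTG =
                       c(a, rep(1, 9), b)), libs)
  p_pkg <- pairwise_ttests(em2)$p_values[1, "BF-O"]
  expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
  expect_lt(p_pkg, 0.05)
  # and agrees with stats::t.test's pooled variant
  expect_equal(p_pkg, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  # random-data agreement with stats::t.test across many rows
  set.seed(92)
  m <- matrix(rnorm(30 * 15, 100, 20), 30, 15, dimnames = list(NULL, libs))
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), character(1))
  em3 <- expression_matrix(data.frame(locus_id = "L", sequence = seqs), m)
  tt3 <- pairwise_ttests(em3)
  for (k in sample(length(tt3$p_values), 10)) {
    rc <- arrayInd(k, dim(tt3$p_values))
    pair <- strsplit(colnames(tt3$p_values)[rc[2]], "-")[[1]]
    a <- m[rc[1], mirnome:::tissue_of(libs) == pair[1]]
    b <- m[rc[1], mirnome:::tissue_of(libs) == pair[2]]
    expect_equal(tt3$p_values[k], t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-9)
  }

  # degenerate: both groups constant and different -> p = 0, flagged
  # (BF = 5,5,5 and F = 9,9,9, rest 1)
  v <- c(5, 5, 5, 9, 9, 9, rep(1, 9))
  em4 <- toy_em(list(CCGGTTAACCGGTTAACCGG = v), libs)
  tt4 <- pairwise_ttests(em4)
  expect_equal(unname(tt4$p_values[1, "BF-F"]), 0)
  expect_true(tt4$degenerate[1, "BF-F"])
})

test_that("type-I error is controlled under the null simulation", {
  # no tissue effect, dispersion > 0: fraction of p < 0.05 within 0.05 +/- 0.02
  cfg <- simulation_config(depth = 4e4, dispersion = 0.05,
                           contaminant_fraction = 0,
                           low_complexity_fraction = 0,
                           locus_abundance = rep(1, 20), seed = 93)
  exp <- simulate_experiment(cfg, n_loci = 20, genome_length = 6e4)
  seqs <- NULL
  m <- vapply(exp$libraries, function(l) {
    tr <- l$truth
    if (is.null(seqs)) seqs <<- paste(tr$locus_id, tr$sequence)
    tr$count[match(seqs, paste(tr$locus_id, tr$sequence))] /
      sum(tr$count) * 1e6
  }, numeric(length(exp$libraries[[1]]$truth$sequence)))
  info <- data.frame(locus_id = sub(" .*", "", seqs),
                     sequence = sub(".* ", "", seqs))
  tt <- pairwise_ttests(expression_matrix(info, m))
  expect_gte(length(tt$p_values), 2000)
  rate <- mean(tt$p_values < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("power increases with simulated fold change", {
  base <- simulation_config(depth = 2e4, dispersion = 0.1,
                            contaminant_fraction = 0,
                            low_complexity_fraction = 0,
                            locus_abundance = rep(1, 8), seed = 94)
  sig_at_fc <- vapply(c(1, 2, 4), function(fc) {
    eff <- matrix(1, 8, 5)
    eff[1:4, 5] <- fc  # loci 1-4 shifted in tissue O
    counts <- vapply(1:6, function(k) {
      cfg <- simulation_config(depth = base$depth, dispersion = base$dispersion,
                               contaminant_fraction = 0,
                               low_complexity_fraction = 0,
                               locus_abundance = base$locus_abundance,
                               tissue_effects = eff, seed = 94 + k)
      exp <- simulate_experiment(cfg, n_loci = 8, genome_length = 3e4)
      seqs <- NULL
      m <- vapply(exp$libraries, function(l) {
        tr <- l$truth
        if (is.null(seqs)) seqs <<- paste(tr$locus_id, tr$sequence)
        tr$count[match(seqs, paste(tr$locus_id, tr$sequence))] /
          sum(tr$count) * 1e6
      }, numeric(nrow(exp$libraries[[1]]$truth)))
      info <- data.frame(locus_id = sub(" .*", "", seqs),
                         sequence = sub(".* ", "", seqs))
      tt <- pairwise_ttests(expression_matrix(info, m))
      affected <- info$locus_id %in% sprintf("sim_%02d", 1:4)
      mean(tt$n_significant[affected])
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  expect_true(all(diff(sig_at_fc) > 0))
})

test_that("canberra follows its definition and the metric axioms", {
  expect_equal(canberra(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(canberra(c(1, 0), c(0, 1)), 2)
  expect_equal(canberra(c(1, 3), c(3, 1)), 1)
  # agreement with stats::dist on strictly positive vectors (where the two
  # definitions coincide)
  set.seed(95)
  m <- matrix(rexp(5 * 20) + 0.1, 5, 20)
  expect_equal(canberra(m[1, ], m[2, ]),
               unname(dist(m[1:2, ], method = "canberra")[1]),
               tolerance = 1e-12)
  # metric axioms over random triples with zeros
  for (i in 1:1000) {
    u <- round(rexp(8, 1 / 5)) * rbinom(8, 1, 0.7)
    v <- round(rexp(8, 1 / 5)) * rbinom(8, 1, 0.7)
    w <- round(rexp(8, 1 / 5)) * rbinom(8, 1, 0.7)
    duv <- canberra(u, v); dvw <- canberra(v, w); duw <- canberra(u, w)
    expect_equal(duv, canberra(v, u))
    expect_equal(canberra(u, u), 0)
    expect_lte(duw, duv + dvw + 1e-12)
  }
})

test_that("sample clustering matches a brute-force linkage oracle", {
  # two identical columns merge at height zero
  libs <- c("A1", "A2", "B1")
  m <- cbind(A1 = c(5, 1, 0), A2 = c(5, 1, 0), B1 = c(0, 4, 4))
  seqs <- c("TACCGGTTACCGGTTACCGG", "CCGGTTAACCGGTTAACCGG",
            "GGTTAACCGGTTAACCGGTT")
  em <- expression_matrix(data.frame(locus_id = "L", sequence = seqs), m)
  cl <- cluster_samples(em, "all_reads", "replicate")
  expect_equal(min(cl$hclust$height), 0)
  merged0 <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(merged0, c("A1", "A2"))

  # 3-column toy: complete-linkage heights from hand-computed distances
  d12 <- canberra(m[, 1], m[, 2])
  d13 <- canberra(m[, 1], m[, 3])
  d23 <- canberra(m[, 2], m[, 3])
  expect_equal(sort(cl$hclust$height), sort(c(min(d12, d13, d23),
                                              max(d13, d23))))
  expect_error(cluster_samples(
    expression_matrix(data.frame(locus_id = "L", sequence = seqs),
                      m[, 1, drop = FALSE]), level = "replicate"),
    "at least two")
})

test_that("arm ratios reproduce the reference locus 3_16 values", {
  em <- load_table2_fixture()
  ar <- arm_ratio(em, "3_16", mature_acc = "HE860348", star_acc = "HE860347",
                  pools = list(`GF+GL` = c("GF", "GL")))
  expect_equal(round(ar$tissue_means[["O"]], 1), 0.4)
  expect_equal(unname(ar$classes["O"]), "inverted")
  expect_equal(round(ar$pooled[["GF+GL"]], 1), 5.7)
  expect_equal(unname(ar$pooled_classes["GF+GL"]), "low")
  # BF and F: mean ratio close to one
  expect_lt(abs(ar$tissue_means[["BF"]] - 1), 0.5)
  expect_lt(abs(ar$tissue_means[["F"]] - 1), 0.5)
})

test_that("arm ratio boundaries and zero-star handling are correct", {
  libs <- design_libs()
  em <- toy_em(list(TACCGGTTACCGGTTACCGG = rep(6, 15),
                    CCGGTTAACCGGTTAACCGG = rep(6, 15)), libs)
  ar <- arm_ratio(em, "L1", "TACCGGTTACCGGTTACCGG", "CCGGTTAACCGGTTAACCGG")
  expect_true(all(ar$tissue_means == 1))
  expect_true(all(ar$classes == "low"))  # bins: [100,Inf) [10,100) [1,10) [0,1)

  em0 <- toy_em(list(TACCGGTTACCGGTTACCGG = rep(6, 15),
                     CCGGTTAACCGGTTAACCGG = rep(0, 15)), libs)
  ar0 <- arm_ratio(em0, "L1", "TACCGGTTACCGGTTACCGG", "CCGGTTAACCGGTTAACCGG")
  expect_true(all(is.na(ar0$tissue_means)))
  expect_equal(ar0$dropped_zero_star, 15)
})
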