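#' Pearson correlation of two expression vectors
#'
#' Thin wrapper over the product-moment correlation that reports `NA` (with
#' a warning) instead of failing when a vector has zero variance.
#'
#' @param u,v Equal-length numeric vectors.
#' @return The correlation coefficient, or `NA` if undefined.
#' @export
pearson <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(u, v)
}

#' Replicate and cross-tissue concordance
#'
#' Pearson correlations between all library pairs of the de-duplicated
#' sequence view (each read counted once however many loci it maps to),
#' after removing the configured outlier sequences. Within-tissue averages
#' are compared to the ENCODE replicate-concordance band.
#'
#' @param em An `expression_matrix` or `isomir_catalog`.
#' @param exclusions Accessions (or sequences) removed before any
#'   correlation; the default drops the one abnormally abundant read whose
#'   presence would pin every correlation near 1.
#' @param encode_band Acceptable within-tissue Pearson range.
#' @return A list of class `concordance_report`: `pairs` (data frame of all
#'   library pairs with `r`), `tissue_means` (named, 2 dp), `cross_mean`
#'   (2 dp), `excluded`, `encode_band`, `in_band` (per tissue).
#' @export
concordance <- function(em, exclusions = "HE860285",
                        encode_band = c(0.92, 0.98)) {
  if (inherits(em, "isomir_catalog")) em <- em$matrix
  stopifnot(inherits(em, "expression_matrix"))
  m <- dedup_view(em)
  excl_seq <- character(0)
  if (length(exclusions) > 0) {
    by_acc <- if ("accession" %in% names(em$info))
      accession_sequences(em, exclusions) else character(0)
    direct <- intersect(exclusions, rownames(m))
    excl_seq <- union(by_acc, direct)
    unknown <- exclusions[!exclusions %in% c(em$info$accession, rownames(m))]
    if (length(unknown) > 0)
      warning("unknown exclusion(s): ", paste(unknown, collapse = ", "))
    m <- m[!rownames(m) %in% excl_seq, , drop = FALSE]
  }
  libs <- colnames(m)
  cmb <- utils::combn(libs, 2)
  r <- apply(cmb, 2, function(p) pearson(m[, p[1]], m[, p[2]]))
  pairs <- data.frame(lib1 = cmb[1, ], lib2 = cmb[2, ], r = r,
                      within_tissue = tissue_of(cmb[1, ]) == tissue_of(cmb[2, ]),
                      stringsAsFactors = FALSE)
  tissues <- unique(tissue_of(libs))
  tissue_means <- vapply(tissues, function(tt)
    round(mean(pairs$r[pairs$within_tissue & tissue_of(pairs$lib1) == tt]), 2),
    numeric(1))
  cross_mean <- round(mean(pairs$r[!pairs$within_tissue]), 2)
  structure(list(pairs = pairs, tissue_means = tissue_means,
                 cross_mean = cross_mean, excluded = excl_seq,
                 encode_band = encode_band,
                 in_band = tissue_means >= encode_band[1] &
                   tissue_means <= encode_band[2]),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n  within-tissue Pearson averages:\n")
  for (tt in names(x$tissue_means))
    cat(sprintf("    %-3s %.2f  [ENCODE band %s]\n", tt, x$tissue_means[tt],
                if (x$in_band[tt]) "ok" else "OUTSIDE"))
  cat(sprintf("  cross-tissue average: %.2f over %d pairs\n", x$cross_mean,
              sum(!x$pairs$within_tissue)))
  if (length(x$excluded))
    cat("  excluded sequence(s):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

# Vectorised two-sided pooled-variance (Student) t-test across matrix rows.
# Degenerate rows (zero pooled variance): p = 1 when the group means agree,
# p = 0 when they differ.
pooled_t_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  deg <- sp2 == 0
  p[deg & m1 == m2] <- 1
  p[deg & m1 != m2] <- 0
  list(p = p, t = t, degenerate = deg)
}

#' Pairwise differential tests across tissues
#'
#' For every isomiR (de-duplicated sequence view), a two-sided two-sample
#' Student t-test with pooled variance between the replicates of every pair
#' of tissues. Significance is `p < alpha` with no multiplicity correction.
#'
#' @param em An `expression_matrix` or `isomir_catalog`.
#' @param alpha Significance level.
#' @param dedup Use the de-duplicated sequence view (default) or the
#'   per-locus layout.
#' @return A list of class `differential_report`: `p_values` (sequences x
#'   tissue pairs), `significant` (logical matrix), `n_significant` (per
#'   sequence, 0..n pairs), `degenerate` (both groups constant but unequal),
#'   `alpha`.
#' @export
pairwise_ttests <- function(em, alpha = 0.05, dedup = TRUE) {
  if (inherits(em, "isomir_catalog")) em <- em$matrix
  stopifnot(inherits(em, "expression_matrix"))
  m <- if (dedup) dedup_view(em) else
    `rownames<-`(em$values, paste(em$info$locus_id, em$info$sequence))
  tissues <- unique(tissue_of(colnames(m)))
  cmb <- utils::combn(tissues, 2)
  pair_names <- paste(cmb[1, ], cmb[2, ], sep = "-")
  p <- deg <- matrix(NA, nrow(m), ncol(cmb),
                     dimnames = list(rownames(m), pair_names))
  for (k in seq_len(ncol(cmb))) {
    a <- m[, tissue_of(colnames(m)) == cmb[1, k], drop = FALSE]
    b <- m[, tissue_of(colnames(m)) == cmb[2, k], drop = FALSE]
    res <- pooled_t_rows(a, b)
    p[, k] <- res$p
    deg[, k] <- res$degenerate & res$p == 0
  }
  sig <- p < alpha
  structure(list(p_values = p, significant = sig,
                 n_significant = rowSums(sig), degenerate = deg,
                 alpha = alpha),
            class = "differential_report")
}

#' @export
print.differential_report <- function(x, ...) {
  cat("<differential_report>", nrow(x$p_values), "isomiRs x",
      ncol(x$p_values), "tissue pairs at alpha =", x$alpha, "\n")
  cat("  significant fraction:",
      round(mean(x$significant), 3), "\n")
  invisible(x)
}

#' Canberra distance
#'
#' `sum_i |u_i - v_i| / (|u_i| + |v_i|)`, with 0/0 terms contributing 0 (no
#' rescaling). A weighted L1 metric that is sensitive to proportional
#' change near zero, which suits sparse expression vectors.
#'
#' @param u,v Equal-length non-negative numeric vectors.
#' @return The distance.
#' @export
canberra <- function(u, v) {
  stopifnot(length(u) == length(v))
  s <- abs(u) + abs(v)
  i <- s > 0
  sum(abs(u[i] - v[i]) / s[i])
}

# Full pairwise Canberra distance matrix over the columns of `m`.
canberra_dist <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- canberra(m[, i], m[, j])
    }
  }
  stats::as.dist(d)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering (complete linkage) of libraries or tissues on
#' Canberra distances between expression vectors, in two modes: all reads of
#' the de-duplicated sequence view, or only the sample-invariant dominant
#' reads of each locus.
#'
#' @param em An `expression_matrix` or `isomir_catalog`.
#' @param mode `"all_reads"` or `"dominant_only"`.
#' @param level `"tissue"` (replicate-averaged columns, default) or
#'   `"replicate"` (one column per library).
#' @param dominance_level Passed to [sample_invariant_dominants()] when
#'   `mode = "dominant_only"`.
#' @return A list of class `sample_clustering`: `hclust`, `dist`, `mode`,
#'   `level`, `n_reads`.
#' @export
cluster_samples <- function(em, mode = c("all_reads", "dominant_only"),
                            level = c("tissue", "replicate"),
                            dominance_level = "library") {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (inherits(em, "isomir_catalog")) em <- em$matrix
  stopifnot(inherits(em, "expression_matrix"))
  m <- dedup_view(em)
  if (mode == "dominant_only") {
    doms <- sample_invariant_dominants(dominance_table(em),
                                       level = dominance_level)
    m <- m[rownames(m) %in% doms, , drop = FALSE]
  }
  if (level == "tissue") {
    tissues <- unique(tissue_of(colnames(m)))
    m <- vapply(tissues, function(tt)
      rowMeans(m[, tissue_of(colnames(m)) == tt, drop = FALSE]),
      numeric(nrow(m)))
  }
  if (ncol(m) < 2) stop("need at least two columns to cluster")
  d <- canberra_dist(m)
  structure(list(hclust = stats::hclust(d, method = "complete"), dist = d,
                 mode = mode, level = level, n_reads = nrow(m)),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering>", x$mode, "/", x$level, "on", x$n_reads,
      "reads;", length(x$hclust$labels), "leaves\n")
  invisible(x)
}

#' @export
plot.sample_clustering <- function(x, ...) {
  plot(x$hclust, main = sprintf("Canberra / complete linkage (%s, %s)",
                                x$mode, x$level),
       xlab = "", sub = "", ...)
}

#' Write a clustering as a Newick tree
#'
#' @param clustering A [cluster_samples()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' miRNA/miRNA* arm ratio at a locus
#'
#' Per-replicate ratio of the mature-arm read's RPM to the star-arm read's
#' RPM, averaged per tissue (replicates with a zero star RPM are excluded
#' and flagged), and classified into the standard duplex-asymmetry bins:
#' high (>= 100), intermediate ([10, 100)), low ([1, 10)), inverted (< 1).
#'
#' @param em An `expression_matrix` or `isomir_catalog`.
#' @param locus_id Locus to analyse.
#' @param mature_acc,star_acc Accessions (or sequences) of the mature and
#'   star reads at that locus.
#' @param pools Optional named list of tissue groups to additionally
#'   average over (e.g. `list("GF+GL" = c("GF", "GL"))`).
#' @return A list of class `arm_ratio_report`: `ratios` (data frame
#'   `library_id`, `tissue`, `mature_rpm`, `star_rpm`, `ratio`),
#'   `tissue_means` (1 dp alongside the exact value), `classes`, `pooled`.
#' @export
arm_ratio <- function(em, locus_id, mature_acc, star_acc, pools = NULL) {
  if (inherits(em, "isomir_catalog")) em <- em$matrix
  stopifnot(inherits(em, "expression_matrix"))
  pick <- function(acc) {
    by_acc <- if ("accession" %in% names(em$info))
      em$info$accession %in% acc else FALSE
    ix <- which(em$info$locus_id == locus_id &
                  (by_acc | em$info$sequence %in% acc))
    if (length(ix) == 0)
      stop("no row for ", acc, " at locus ", locus_id)
    em$values[ix[1], ]
  }
  mat <- pick(mature_acc)
  st <- pick(star_acc)
  ratio <- ifelse(st > 0, mat / st, NA_real_)
  ratios <- data.frame(library_id = em$libraries,
                       tissue = tissue_of(em$libraries),
                       mature_rpm = unname(mat), star_rpm = unname(st),
                       ratio = unname(ratio), stringsAsFactors = FALSE)
  mean_of <- function(tt) {
    r <- ratios$ratio[ratios$tissue %in% tt]
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  }
  tissues <- unique(ratios$tissue)
  tissue_means <- vapply(tissues, mean_of, numeric(1))
  classify <- function(r) {
    if (is.na(r)) return(NA_character_)
    if (r >= 100) "high" else if (r >= 10) "intermediate"
    else if (r >= 1) "low" else "inverted"
  }
  pooled <- pooled_classes <- NULL
  if (!is.null(pools)) {
    pooled <- vapply(pools, mean_of, numeric(1))
    pooled_classes <- vapply(pooled, classify, character(1))
  }
  structure(list(locus_id = locus_id, ratios = ratios,
                 tissue_means = tissue_means,
                 classes = vapply(tissue_means, classify, character(1)),
                 pooled = pooled, pooled_classes = pooled_classes,
                 dropped_zero_star = sum(is.na(ratio))),
            class = "arm_ratio_report")
}

#' @export
print.arm_ratio_report <- function(x, ...) {
  cat("<arm_ratio_report> locus", x$locus_id, "\n")
  for (tt in names(x$tissue_means))
    cat(sprintf("  %-3s mean miRNA/miRNA* = %.1f (%s)\n", tt,
                x$tissue_means[tt], x$classes[tt]))
  if (!is.null(x$pooled))
    for (pp in names(x$pooled))
      cat(sprintf("  pooled %s: %.1f\n", pp, x$pooled[pp]))
  if (x$dropped_zero_star > 0)
    cat("  replicates dropped for zero star RPM:", x$dropped_zero_star, "\n")
  invisible(x)
}
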