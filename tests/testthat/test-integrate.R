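# integrate: gene/class joins, class-pair summaries, connectivity,
# correlations.

mk_labels <- function() {
  data.frame(chrom = "chr1", bin = c(0L, 1L, 2L),
             label = factor(c("Core", "Other", "ExCore"),
                            levels = c("Core", "Peri", "AltCore", "ExCore",
                                       "Other")))
}

test_that("genes_by_class assigns single and multiple labels", {
  layout <- genome_layout("chr1", 1e6)
  genes <- data.frame(
    gene_id = c("inCore", "straddle", "outside"),
    chrom = "chr1",
    start = c(10000, 190000, 800000),
    end = c(20000, 210000, 810000),
    logFC_c1 = c(-1, 2, 0.1), de_c1 = c(1L, 1L, 0L))
  j <- genes_by_class(genes, mk_labels(), layout)
  expect_equal(j$label[j$gene_id == "inCore"], "Core")
  expect_false(j$multi_label[j$gene_id == "inCore"])
  straddle <- j[j$gene_id == "straddle", ]
  expect_setequal(straddle$label, c("Core", "Other"))
  expect_true(all(straddle$multi_label))
  expect_equal(j$label[j$gene_id == "outside"], "Background")
})

test_that("genes_by_class handles an empty gene table", {
  layout <- genome_layout("chr1", 1e6)
  genes <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      logFC_c1 = numeric(), de_c1 = integer())
  j <- genes_by_class(genes, mk_labels(), layout)
  expect_equal(nrow(j), 0L)
})

test_that("class_expression_summary summarizes DE genes only", {
  layout <- genome_layout("chr1", 1e6)
  genes <- data.frame(
    gene_id = c("a", "b", "c"), chrom = "chr1",
    start = c(1000, 2000, 3000), end = c(1500, 2500, 3500),
    logFC_c1 = c(-1, -3, 5), de_c1 = c(1L, 1L, 0L))
  j <- genes_by_class(genes, mk_labels(), layout)
  s <- class_expression_summary(j, "c1")
  expect_equal(s$n[s$label == "Core"], 2L)          # "c" is not DE
  expect_equal(s$median_logFC[s$label == "Core"], -2)
  expect_equal(s$n[s$label == "ExCore"], 0L)
  expect_error(class_expression_summary(j, "nope"), "not present")
})

test_that("interactions_by_class_pair matches the hand count", {
  net <- toy_net(c(0, 3, 0), c(1, 0, 2), c(1, 2, -1))
  labels <- data.frame(chrom = "chr1", bin = c(0L, 1L, 2L, 3L),
                       label = c("Core", "Core", "ExCore", "Core"))
  tab <- interactions_by_class_pair(net, labels)
  cc <- tab[tab$label_i == "Core" & tab$label_j == "Core", ]
  ce <- tab[tab$label_i == "Core" & tab$label_j == "ExCore", ]
  expect_equal(cc$n, 2L)
  expect_equal(cc$median_logFC, 1.5)
  expect_equal(ce$n, 1L)
  expect_equal(ce$median_logFC, -1)
  expect_equal(nrow(tab), 15L)              # all unordered pairs reported
  expect_equal(sum(tab$n), 3L)              # conservation
  expect_true(all(tab$n[cc$n == 0] >= 0))
})

test_that("interactions_by_class_pair errors on unlabeled bins", {
  net <- toy_net(0, 1, 1)
  labels <- data.frame(chrom = "chr1", bin = 0L, label = "Core")
  expect_error(interactions_by_class_pair(net, labels), "1")
})

test_that("binset_connectivity compares sets and respects the mask", {
  # 5x5 toy with one masked bin, hand-computed row means
  M <- matrix(1, 5, 5)
  M[1, ] <- M[, 1] <- 2; M[1, 1] <- 2
  mask <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  bm <- list(matrix = M, mask = mask)
  out <- binset_connectivity(bm, bins_of_interest = 0L,
                             background = c(1L, 2L))
  expect_equal(out$per_bin$mean_contact[out$per_bin$set == "interest"], 2)
  expect_equal(out$per_bin$mean_contact[out$per_bin$set == "background"],
               c(5 / 4, 5 / 4))
  s <- out$summary
  expect_gt(s$median[s$set == "interest"], s$median[s$set == "background"])
})

test_that("binset_connectivity validates its sets", {
  bm <- list(matrix = matrix(1, 4, 4), mask = c(rep(FALSE, 3), TRUE))
  expect_error(binset_connectivity(bm, integer(0), 1L), "non-empty")
  expect_error(binset_connectivity(bm, 0L, 0L), "disjoint")
  expect_error(binset_connectivity(bm, 3L, 0L), "unmasked")
  expect_error(binset_connectivity(bm, 9L, 0L), "out of range")
})

test_that("constant matrices give equal set medians", {
  bm <- list(matrix = matrix(2, 6, 6), mask = rep(FALSE, 6))
  out <- binset_connectivity(bm, 0:2, 3:5)
  expect_equal(out$summary$median[1], out$summary$median[2])
})

test_that("track_correlation handles the simple identities", {
  a <- data.frame(chrom = "chr1", bin = 0:9, value = 1:10)
  b <- a; b$value <- -a$value
  expect_equal(track_correlation(a, a)$estimate, 1)
  expect_equal(track_correlation(a, b)$estimate, -1)
  expect_equal(track_correlation(a, b)$n, 10L)
  expect_equal(track_correlation(a, b)$estimate,
               track_correlation(b, a)$estimate)
  small <- a[1:2, ]
  expect_error(track_correlation(small, small), "at least 3")
})

test_that("track_correlation estimates a planted r within sampling error", {
  set.seed(99)
  n <- 10000
  r <- 0.45
  x <- stats::rnorm(n)
  y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
  a <- data.frame(chrom = "chr1", bin = 0:(n - 1), value = x)
  b <- data.frame(chrom = "chr1", bin = 0:(n - 1), value = y)
  expect_lt(abs(track_correlation(a, b)$estimate - r), 0.03)
})

test_that("track_correlation applies the log transform to track a", {
  a <- data.frame(chrom = "chr1", bin = 0:9, value = exp(1:10) - 1)
  b <- data.frame(chrom = "chr1", bin = 0:9, value = 1:10)
  out <- track_correlation(a, b, log_transform_a = TRUE)
  expect_equal(out$estimate, 1)
  expect_true(out$log_transform_a)
})

test_that("kmax_feature_report correlates and flags degenerate inputs", {
  kmax <- data.frame(chrom = c("c1", "c2", "c3", "c4"),
                     k_max = c(2, 5, 7, 11))
  feats <- data.frame(chrom = kmax$chrom,
                      same = kmax$k_max,
                      const = 3)
  out <- kmax_feature_report(kmax, feats)
  expect_equal(out$pearson[out$feature == "same"], 1)
  expect_true(is.na(out$pearson[out$feature == "const"]))
  expect_true(is.na(out$spearman[out$feature == "const"]))
  expect_error(kmax_feature_report(kmax[1:2, ], feats[1:2, ]),
               "at least 3")
})

test_that("k-max tracks planted clique size against peak density", {
  # clique size and peak rate rise together across five 1-chromosome specs
  sizes <- c(7, 8, 10, 12, 14)
  rates <- c(20, 40, 80, 160, 320)
  spear <- vapply(1:20, function(s) {
    kmax <- numeric(5); npk <- numeric(5)
    for (i in 1:5) {
      spec <- synthetic_spec(
        seed = s * 100 + i, chrom_names = "chr1", chrom_lengths = 25e6,
        peak_bg_per_mb = rates[i], core_bins = seq_len(sizes[i]) - 1L,
        dense_enrichment = 1)
      nets <- build_networks(simulate_diffnet(spec)$tables[[1]])
      kmax[i] <- kcore_decompose(nets[[1]])$k_max
      npk[i] <- nrow(simulate_peaks(spec)$peaks)
    }
    tab <- kmax_feature_report(
      data.frame(chrom = paste0("c", 1:5), k_max = kmax),
      data.frame(chrom = paste0("c", 1:5), n_peaks = npk))
    tab$spearman[1]
  }, 1)
  expect_true(all(spear > 0.8))
})
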