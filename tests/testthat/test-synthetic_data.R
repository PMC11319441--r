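# synthetic_data: generators, planted truth, determinism.

test_that("identical specs give byte-identical output directories", {
  spec <- synthetic_spec(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic(spec, d1)
  write_synthetic(spec, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
})

test_that("peak counts follow the Poisson background model", {
  shrink <- list(dense_start = 2e6, dense_length = 1e6, core_bins = 2:9,
                 peri_bins = 11:13, altcore_bins = 20:24,
                 excore_bins = 30:32, other_bins = 40:41)
  spec <- do.call(synthetic_spec, c(
    list(seed = 6, chrom_names = "chr1", chrom_lengths = 10e6,
         peak_bg_per_mb = 10, dense_enrichment = 1), shrink))
  pk <- simulate_peaks(spec)
  expect_gte(nrow(pk$peaks), stats::qpois(0.005, 100))
  expect_lte(nrow(pk$peaks), stats::qpois(0.995, 100))
  expect_true(all(pk$peaks$end - pk$peaks$start == 200))
  # zero rate and no enrichment -> empty set
  spec0 <- do.call(synthetic_spec, c(
    list(seed = 6, chrom_names = "chr1", chrom_lengths = 10e6,
         peak_bg_per_mb = 0, dense_enrichment = 1), shrink))
  expect_equal(nrow(simulate_peaks(spec0)$peaks), 0L)
})

test_that("the second contrast is the exact row-wise sign flip", {
  spec <- synthetic_spec(seed = 7, noise_p = 0.02)
  dn <- simulate_diffnet(spec)
  t1 <- dn$tables[[1]]; t2 <- dn$tables[[2]]
  expect_equal(t1[, c("chrom", "bin_i", "bin_j")],
               t2[, c("chrom", "bin_i", "bin_j")])
  expect_equal(t2$logFC, -t1$logFC)
})

test_that("planted cliques have the expected core numbers at noise 0", {
  spec <- synthetic_spec(seed = 8)
  dn <- simulate_diffnet(spec)
  nets <- build_networks(dn$tables[[1]])
  for (net in nets) {
    dec <- kcore_decompose(net)
    expect_equal(unname(dec$core_number[as.character(spec$planted$Core)]),
                 rep(length(spec$planted$Core) - 1L, 8))
    expect_equal(unname(dec$core_number[as.character(spec$planted$AltCore)]),
                 rep(length(spec$planted$AltCore) - 1L, 5))
  }
})

test_that("overlapping planted memberships are a spec error", {
  expect_error(synthetic_spec(core_bins = 20:27, peri_bins = 27:29),
               "overlap")
  expect_error(synthetic_spec(core_bins = 500:507), "outside")
})

test_that("generated tables pass genomic_io validation unchanged", {
  spec <- synthetic_spec(seed = 9, noise_p = 0.02)
  dn <- simulate_diffnet(spec)
  layout <- spec_layout(spec)
  p <- withr::local_tempfile()
  write_diff_interactions(dn$tables[[1]], layout, p)
  back <- read_diff_interactions(p, layout)
  expect_equal(back$bin_i, dn$tables[[1]]$bin_i)
  expect_equal(back$bin_j, dn$tables[[1]]$bin_j)
  expect_equal(back$logFC, dn$tables[[1]]$logFC)
  expect_equal(attr(back, "n_dedup_dropped"), 0L)
  expect_equal(attr(back, "n_trans_dropped"), 0L)
  expect_true(all(back$bin_i < back$bin_j))
})

test_that("contacts are symmetric with alternating truth blocks", {
  spec <- synthetic_spec(seed = 10, chrom_names = "chrZ",
                         chrom_lengths = 20e6)
  ct <- simulate_contacts(spec)
  M <- ct$matrices[[1]]$matrix
  expect_equal(M, t(M))
  expect_true(all(M >= 0))
  lab <- ct$truth$label
  expect_equal(lab[1:25],
               rep(rep(c("A", "B"), each = 10), length.out = 25))
})

test_that("no noise and no boost give an exactly flat O/E", {
  spec <- synthetic_spec(seed = 11, chrom_names = "chrZ",
                         chrom_lengths = 20e6, block_boost = 1,
                         contact_sd = 0)
  ct <- simulate_contacts(spec)
  M <- ct$matrices[[1]]$matrix     # an exact function of distance
  OE <- distance_correct(list(matrix = M, mask = rep(FALSE, nrow(M))))
  expect_lt(max(abs(OE - 1), na.rm = TRUE), 1e-12)
})

test_that("zero expression sd gives exact class means", {
  spec <- synthetic_spec(seed = 12, expr_sd = 0)
  dn <- simulate_diffnet(spec)
  genes <- simulate_expression(spec, dn$truth)
  joined <- genes_by_class(genes, dn$truth, spec_layout(spec))
  core <- joined[joined$label == "Core", ]
  expect_true(all(core[[paste0("logFC_", spec$contrasts[1])]] ==
                    spec$expr_means[["Core"]]))
  expect_true(all(core[[paste0("logFC_", spec$contrasts[2])]] ==
                    -spec$expr_means[["Core"]]))
})

test_that("expression with no labelled bins still works", {
  spec <- synthetic_spec(seed = 13)
  empty <- data.frame(chrom = character(), bin = integer(),
                      label = character())
  genes <- simulate_expression(spec, empty)
  expect_true(all(grepl("^bg_", genes$gene_id)))
  expect_gt(nrow(genes), 0L)
})

test_that("substreams are independent: one generator does not move another", {
  spec <- synthetic_spec(seed = 14)
  pk1 <- simulate_peaks(spec)
  invisible(simulate_contacts(spec))   # consumes its own substream
  pk2 <- simulate_peaks(spec)
  expect_equal(pk1, pk2)
})
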