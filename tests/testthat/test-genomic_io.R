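# genomic_io: readers, writers, bin mapping.

test_that("read_chrom_sizes parses and bins correctly", {
  p <- withr::local_tempfile(lines = "chr1\t1000000")
  layout <- read_chrom_sizes(p, bin_size = 200000L)
  expect_equal(layout$chrom_names, "chr1")
  expect_equal(n_bins(layout, "chr1"), 5L)

  p2 <- withr::local_tempfile(lines = "chrA 400001")
  l2 <- read_chrom_sizes(p2, bin_size = 200000L)
  expect_equal(n_bins(l2, "chrA"), 3L)
  expect_equal(bin_start(l2, "chrA", 2L), 400000)
  expect_equal(bin_end(l2, "chrA", 2L), 400001)
})

test_that("read_chrom_sizes rejects bad input naming the line", {
  p <- withr::local_tempfile(lines = c("chr1 100", "chr2 -5"))
  expect_error(read_chrom_sizes(p), "line 2")
  p2 <- withr::local_tempfile(lines = c("chr1 100", "chr1 200"))
  expect_error(read_chrom_sizes(p2), "duplicate")
  p3 <- withr::local_tempfile(lines = "")
  expect_error(read_chrom_sizes(p3), "empty")
})

test_that("bin mapping follows floor(c / bin_size)", {
  layout <- genome_layout("chr1", 1e6, bin_size = 200000L)
  cs <- c(0, 1, 199999, 200000, 999999)
  expect_equal(bin_of(layout, "chr1", cs), floor(cs / 200000))
  for (b in 0:4) {
    expect_equal(bin_of(layout, "chr1", bin_start(layout, "chr1", b)), b)
    expect_equal(bin_of(layout, "chr1", bin_end(layout, "chr1", b) - 1), b)
  }
})

test_that("read_intervals parses, sorts, and validates", {
  p <- withr::local_tempfile(lines = "chr1\t100\t200")
  x <- read_intervals(p)
  expect_equal(nrow(x), 1L)
  expect_equal(x$end - x$start, 100)

  p2 <- withr::local_tempfile(
    lines = c("chr2\t10\t20", "chr1\t50\t60", "chr1\t5\t15"))
  x2 <- read_intervals(p2)
  expect_equal(x2$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(x2$start, c(5, 50, 10))

  p3 <- withr::local_tempfile(lines = "chr1\t200\t100")
  expect_error(read_intervals(p3), "start >= end")
})

test_that("interval write/read round-trips identically", {
  x <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  start = c(0, 500, 100), end = c(100, 900, 350),
                  name = c("a", "b", "c"), score = c(1.5, 2, 0.25))
  p <- withr::local_tempfile()
  write_intervals(x, p)
  y <- read_intervals(p)
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$name, x$name)
  expect_equal(y$score, x$score)
})

make_diff_file <- function(rows) {
  header <- paste(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "logFC", "FDR"), collapse = "\t")
  withr::local_tempfile(lines = c(header, rows),
                        .local_envir = parent.frame())
}

test_that("read_diff_interactions filters trans and FDR rows", {
  p <- make_diff_file(c(
    "chr1\t0\t200000\tchr1\t400000\t600000\t1.5\t0.01",
    "chr1\t0\t200000\tchr2\t0\t200000\t2.0\t0.01",        # trans
    "chr1\t200000\t400000\tchr1\t800000\t1000000\t-1.0\t0.2",  # fdr
    "chr1\t0\t200000\tchr1\t800000\t1000000\t0.5\t0.04"))
  layout <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  tab <- read_diff_interactions(p, layout)
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "n_trans_dropped"), 1L)
  expect_equal(attr(tab, "n_filtered"), 1L)
  expect_true(all(tab$bin_i <= tab$bin_j))
})

test_that("read_diff_interactions deduplicates deterministically", {
  p <- make_diff_file(c(
    "chr1\t0\t200000\tchr1\t400000\t600000\t1.5\t0.01",
    "chr1\t400000\t600000\tchr1\t0\t200000\t-9\t0.001",
    "chr1\t0\t200000\tchr1\t400000\t600000\t3\t0.001"))
  layout <- genome_layout("chr1", 1e6)
  tab <- read_diff_interactions(p, layout)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$fdr, 0.001)
  expect_equal(tab$logFC, -9)   # larger |logFC| wins the fdr tie
  expect_equal(attr(tab, "n_dedup_dropped"), 2L)
})

test_that("read_diff_interactions computes bin indices and checks the grid", {
  layout <- genome_layout("chr1", 2e6)
  starts <- c(0, 200000, 600000, 1400000)
  rows <- sprintf("chr1\t%d\t%d\tchr1\t%d\t%d\t1\t0.01",
                  starts, starts + 200000, starts + 200000,
                  starts + 400000)
  p <- make_diff_file(rows)
  tab <- read_diff_interactions(p, layout)
  expect_equal(tab$bin_i, as.integer(starts / 200000))
  expect_equal(tab$bin_j, as.integer(starts / 200000) + 1L)

  p2 <- make_diff_file("chr1\t100\t200100\tchr1\t400000\t600000\t1\t0.01")
  expect_error(read_diff_interactions(p2, layout), "not aligned")
  p3 <- make_diff_file("chrX\t0\t200000\tchrX\t400000\t600000\t1\t0.01")
  expect_error(read_diff_interactions(p3, layout), "chrX")
})

test_that("diff-interaction write/read round-trips identically", {
  layout <- genome_layout("chr1", 1e6)
  tab <- data.frame(chrom = "chr1", bin_i = c(0L, 1L), bin_j = c(2L, 4L),
                    logFC = c(1.23456789012345, -0.5), fdr = c(0.01, 0.03))
  p <- withr::local_tempfile()
  write_diff_interactions(tab, layout, p)
  back <- read_diff_interactions(p, layout)
  expect_equal(back$bin_i, tab$bin_i)
  expect_equal(back$bin_j, tab$bin_j)
  expect_equal(back$logFC, tab$logFC)
  expect_equal(back$fdr, tab$fdr)
})

test_that("bin_signal computes coverage-weighted means", {
  layout <- genome_layout("chr1", 6e5)
  p <- withr::local_tempfile(lines = c("chr1\t0\t100000\t2",
                                       "chr1\t100000\t200000\t4"))
  tr <- bin_signal(p, layout)
  expect_equal(tr$value[tr$bin == 0], 3.0)
  expect_true(all(is.na(tr$value[tr$bin > 0])))

  # half-covered bin takes the covering record's value
  p2 <- withr::local_tempfile(lines = "chr1\t200000\t300000\t7")
  tr2 <- bin_signal(p2, layout)
  expect_equal(tr2$value[tr2$bin == 1], 7)

  p3 <- withr::local_tempfile(lines = character(0))
  tr3 <- bin_signal(p3, layout)
  expect_true(all(is.na(tr3$value)))

  p4 <- withr::local_tempfile(lines = c("chr1\t0\t150000\t1",
                                        "chr1\t100000\t200000\t2"))
  expect_error(bin_signal(p4, layout), "overlap")
})

test_that("bin_signal conserves mass", {
  layout <- genome_layout("chr1", 1e6)
  set.seed(11)
  starts <- seq(0, 9e5, by = 5e4)
  w <- sample(1e4:5e4, length(starts))
  vals <- round(stats::runif(length(starts), 0, 10), 3)
  p <- withr::local_tempfile(
    lines = sprintf("chr1\t%d\t%d\t%s", starts, starts + w, vals))
  tr <- bin_signal(p, layout)
  # recompute per-bin covered bases for the mass identity
  covered <- vapply(tr$bin, function(b) {
    lo <- pmax(starts, b * 2e5); hi <- pmin(starts + w, (b + 1) * 2e5)
    sum(pmax(hi - lo, 0))
  }, 1)
  lhs <- sum(tr$value * covered, na.rm = TRUE)
  rhs <- sum(vals * w)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("at_fraction counts A/T over non-N bases", {
  fa <- withr::local_tempfile(lines = c(">chr1", "ATATGCGCATGNNNNN"))
  layout <- genome_layout("chr1", 16, bin_size = 4L)
  tr <- at_fraction(fa, layout)
  expect_equal(tr$value, c(1, 0, 2 / 3, NA))
  layout2 <- genome_layout(c("chr1", "chr9"), c(16, 16), bin_size = 4L)
  expect_error(at_fraction(fa, layout2), "chr9")
})

test_that("contact matrix triplet write/read round-trips", {
  layout <- genome_layout("chr1", 1e6)
  set.seed(4)
  M <- matrix(rpois(25, 5), 5, 5)
  M <- M + t(M)
  cm <- contact_matrix("chr1", M, 200000L, mask = rep(FALSE, 5))
  p <- withr::local_tempfile()
  write_contacts(cm, p)
  cm2 <- read_contacts(p, layout, "chr1")
  expect_equal(cm2$matrix, cm$matrix)
})

test_that("read_genes returns the contrast names", {
  p <- withr::local_tempfile(lines = c(
    "gene_id\tchrom\tstart\tend\tlogFC_c1\tde_c1",
    "g1\tchr1\t100\t500\t-1.2\t1"))
  g <- read_genes(p)
  expect_equal(attr(g, "contrasts"), "c1")
  expect_equal(g$logFC_c1, -1.2)
  p2 <- withr::local_tempfile(lines = c(
    "gene_id\tchrom\tstart\tend\tlogFC_c1\tde_c1",
    "g1\tchr1\t500\t100\t-1.2\t1"))
  expect_error(read_genes(p2), "start >= end")
})
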