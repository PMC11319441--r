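# Shared test utilities.

# Build a single-chromosome DiffNetwork from raw edges.
toy_net <- function(bin_i, bin_j, logFC, chrom = "chr1", fdr = 0.01) {
  tab <- data.frame(chrom = chrom, bin_i = bin_i, bin_j = bin_j,
                    logFC = logFC, fdr = fdr)
  build_networks(tab)[[1L]]
}

# Edge lists of a clique over the given bins.
clique_edges <- function(bins) {
  cmb <- utils::combn(bins, 2L)
  list(i = cmb[1L, ], j = cmb[2L, ])
}

# Independent brute-force core-number oracle: for ascending k, repeatedly
# delete all vertices of degree < k; survivors of the k-pruning have core
# number >= k.
oracle_core <- function(n, ei, ej) {
  core <- integer(n)
  if (length(ei) == 0L || n == 0L) return(core)
  k <- 1L
  repeat {
    alive <- rep(TRUE, n)
    repeat {
      keep <- alive[ei] & alive[ej]
      deg <- tabulate(c(ei[keep], ej[keep]), nbins = n)
      rm <- alive & deg < k
      if (!any(rm)) break
      alive[rm] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Seeded Erdos-Renyi edge list (simple graph, vertices 1..n).
er_edges <- function(n, p, seed) {
  set.seed(seed)
  cmb <- utils::combn(n, 2L)
  hit <- stats::runif(ncol(cmb)) < p
  list(i = cmb[1L, hit], j = cmb[2L, hit])
}

# Directly-constructed RollingDensityProfile from a bare count vector, for
# threshold tests that need an exact curve.
fake_profile <- function(counts) {
  n <- length(counts)
  layout <- genome_layout("chrT", n * 5000 + 95000, bin_size = 200000L)
  structure(list(
    windows = list(chrT = data.frame(start = (seq_len(n) - 1L) * 5000,
                                     end = (seq_len(n) - 1L) * 5000 + 100000,
                                     count = as.integer(counts))),
    window_size = 1e5, step = 5000, layout = layout),
    class = "RollingDensityProfile")
}

# Coverage (in bp, as a sorted two-column matrix of merged intervals) of a
# region table, for superset checks.
region_cover_bp <- function(regions) {
  if (nrow(regions) == 0L) return(0)
  sum(regions$end - regions$start)
}

# TRUE iff every interval of `a` is contained in some interval of `b`
# (both on one chromosome set).
regions_contained <- function(a, b) {
  if (nrow(a) == 0L) return(TRUE)
  all(vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start <= a$start[i] & b$end >= a$end[i])
  }, TRUE))
}

# Agreement between predicted labels and a truth table over the truth bins.
label_agreement <- function(labels, truth) {
  pred <- labels$label[match(paste(truth$chrom, truth$bin),
                             paste(labels$chrom, labels$bin))]
  mean(as.character(pred) == as.character(truth$label))
}
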