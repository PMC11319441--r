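# Synthetic input generators with planted ground truth. Every generator is
# deterministic given the spec's seed: one global seed expands into fixed
# per-generator substreams so adding a generator never perturbs the others.

# Substream derivation: documented, stable, < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Specification of a synthetic dataset
#'
#' Defaults are sized for a desk-scale fixture (3 chromosomes of 25 Mb at
#' 200 kb bins) and chosen so that every planted structure is recovered with
#' margin by the default analysis parameters; they are not calibrated to any
#' real dataset. The planted network bins per chromosome are fixed
#' (Core 20-27, Peri 30-32, AltCore 60-64, ExCore 80-82, Other 90-91) so
#' that planted roles never overlap and AltCore is detached from Core.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param chrom_names,chrom_lengths the synthetic genome.
#' @param bin_size bin width in bp.
#' @param peak_bg_per_mb background peak rate (Poisson, peaks per Mb).
#' @param peak_width fixed peak width in bp (only midpoints matter
#'   downstream).
#' @param dense_start,dense_length planted dense interval per chromosome
#'   (bp offsets).
#' @param dense_enrichment peak density multiplier inside the planted
#'   interval (>= 1).
#' @param core_bins,peri_bins,altcore_bins,excore_bins,other_bins planted
#'   role bins (0-based, per chromosome; must be disjoint and in range).
#' @param peri_edges increased edges from each Peri bin onto Core.
#' @param excore_edges decreased edges from each ExCore bin onto
#'   Core/AltCore.
#' @param noise_p probability of a noise edge (random sign) per bin pair.
#' @param logfc_means,logfc_sd per-role |logFC| means and common sd for the
#'   first contrast; the second contrast is the exact row-wise sign flip.
#' @param contrasts names of the two simulated contrasts.
#' @param contact_scale,contact_alpha,block_len,block_boost,contact_sd
#'   contact model: expected count `scale * max(d, 0.5)^(-alpha)`, times
#'   `block_boost` when both bins share a planted compartment label
#'   (alternating blocks of `block_len` bins), times lognormal noise
#'   `exp(N(0, contact_sd))`.
#' @param expr_means per-class gene logFC means for the first contrast
#'   (negated for the second), `expr_sd` the common sd,
#'   `genes_per_bin` genes planted inside each labelled bin,
#'   `bg_genes_per_chrom` extra background genes per chromosome,
#'   `de_threshold` the |logFC| cutoff for the DE flag.
#' @return list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           chrom_names = c("chrA", "chrB", "chrC"),
                           chrom_lengths = rep(25e6, 3),
                           bin_size = 200000L,
                           peak_bg_per_mb = 100,
                           peak_width = 200L,
                           dense_start = 10e6,
                           dense_length = 2e6,
                           dense_enrichment = 10,
                           core_bins = 20:27,
                           peri_bins = 30:32,
                           altcore_bins = 60:64,
                           excore_bins = 80:82,
                           other_bins = 90:91,
                           peri_edges = 2L,
                           excore_edges = 2L,
                           noise_p = 0,
                           logfc_means = c(core = 1.5, peri = 1.0,
                                           altcore = 1.2, excore = 1.5,
                                           other = 0.8, noise = 0.8),
                           logfc_sd = 0.3,
                           contrasts = c("OIS_vs_Grow", "shA1_vs_OIS"),
                           contact_scale = 100,
                           contact_alpha = 1,
                           block_len = 10L,
                           block_boost = 1.5,
                           contact_sd = 0.1,
                           expr_means = c(Core = -1, Peri = -0.8,
                                          AltCore = -0.8, ExCore = 1,
                                          Other = 0),
                           expr_sd = 0.5,
                           genes_per_bin = 2L,
                           bg_genes_per_chrom = 30L,
                           de_threshold = 0.5) {
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths lengths differ")
  if (noise_p < 0 || noise_p > 1) stop("noise_p must be in [0, 1]")
  if (dense_enrichment < 1) stop("dense_enrichment must be >= 1")
  if (block_boost < 1) stop("block_boost must be >= 1")
  if (contact_alpha <= 0) stop("contact_alpha must be > 0")
  planted <- list(Core = core_bins, Peri = peri_bins, AltCore = altcore_bins,
                  ExCore = excore_bins, Other = other_bins)
  all_bins <- unlist(planted)
  if (anyDuplicated(all_bins))
    stop("planted role bin sets overlap")
  n_bins_min <- floor(min(chrom_lengths) / bin_size)
  if (max(all_bins) >= n_bins_min || min(all_bins) < 0)
    stop("planted bins outside the binned genome")
  if (dense_start + dense_length > min(chrom_lengths))
    stop("planted dense interval outside the genome")
  if (length(contrasts) != 2L) stop("exactly two contrasts are required")
  stopifnot(all(c("core", "peri", "altcore", "excore", "other", "noise")
                %in% names(logfc_means)),
            all(CLASS_LEVELS %in% names(expr_means)))
  structure(list(
    seed = as.integer(seed), chrom_names = chrom_names,
    chrom_lengths = as.numeric(chrom_lengths),
    bin_size = as.integer(bin_size),
    peak_bg_per_mb = peak_bg_per_mb, peak_width = as.integer(peak_width),
    dense_start = dense_start, dense_length = dense_length,
    dense_enrichment = dense_enrichment,
    planted = planted, peri_edges = as.integer(peri_edges),
    excore_edges = as.integer(excore_edges), noise_p = noise_p,
    logfc_means = logfc_means, logfc_sd = logfc_sd, contrasts = contrasts,
    contact_scale = contact_scale, contact_alpha = contact_alpha,
    block_len = as.integer(block_len), block_boost = block_boost,
    contact_sd = contact_sd, expr_means = expr_means, expr_sd = expr_sd,
    genes_per_bin = as.integer(genes_per_bin),
    bg_genes_per_chrom = as.integer(bg_genes_per_chrom),
    de_threshold = de_threshold),
    class = "SyntheticSpec")
}

#' Genome layout of a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return the corresponding [genome_layout()].
#' @export
spec_layout <- function(spec) {
  genome_layout(spec$chrom_names, spec$chrom_lengths, spec$bin_size)
}

#' Simulate ChIP-seq peaks with planted dense intervals
#'
#' Homogeneous Poisson background peaks plus an enriched Poisson layer
#' inside one planted interval per chromosome (total density =
#' `dense_enrichment` times background there). Fixed peak width.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `peaks` (interval data.frame, sorted) and `truth` (planted
#'   dense intervals, one per chromosome).
#' @export
simulate_peaks <- function(spec) {
  set.seed(derive_seed(spec$seed, 1L))
  rows <- lapply(seq_along(spec$chrom_names), function(ci) {
    ch <- spec$chrom_names[ci]
    len <- spec$chrom_lengths[ci]
    n_bg <- stats::rpois(1L, spec$peak_bg_per_mb * len / 1e6)
    pos <- stats::runif(n_bg, 0, len - spec$peak_width)
    rate_extra <- (spec$dense_enrichment - 1) * spec$peak_bg_per_mb *
      spec$dense_length / 1e6
    n_extra <- stats::rpois(1L, rate_extra)
    pos <- c(pos, stats::runif(n_extra, spec$dense_start,
                               spec$dense_start + spec$dense_length -
                                 spec$peak_width))
    start <- floor(sort(pos))
    data.frame(chrom = rep(ch, length(start)), start = start,
               end = start + spec$peak_width)
  })
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  truth <- data.frame(chrom = spec$chrom_names,
                      start = spec$dense_start,
                      end = spec$dense_start + spec$dense_length)
  list(peaks = peaks, truth = truth)
}

#' Simulate a differential interaction table with planted class structure
#'
#' Per chromosome: an increased-edge clique on the Core bins, a disjoint
#' detached increased-edge clique on the AltCore bins, `peri_edges`
#' increased edges from each Peri bin onto sampled Core bins,
#' `excore_edges` decreased edges from each ExCore bin onto sampled
#' Core/AltCore bins, one increased edge from each Other bin onto a sampled
#' Peri bin, and noise edges (random sign, |logFC| ~ the noise role) drawn
#' per bin pair with probability `noise_p`, skipping planted pairs.
#' Edge logFC is `sign * |N(role mean, sd)|` in the first contrast and its
#' exact row-wise negation in the second.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `tables` (one diff-interaction data.frame per contrast,
#'   named by contrast) and `truth` (data.frame `chrom`, `bin`, `label`
#'   over the planted bins).
#' @export
simulate_diffnet <- function(spec) {
  set.seed(derive_seed(spec$seed, 2L))
  p <- spec$planted
  mu <- spec$logfc_means
  sdv <- spec$logfc_sd
  draw <- function(n, role, sign) sign * abs(stats::rnorm(n, mu[[role]], sdv))
  per_chrom <- lapply(spec$chrom_names, function(ch) {
    bi <- integer(0); bj <- integer(0); lfc <- numeric(0)
    add <- function(a, b, role, sign) {
      bi <<- c(bi, pmin(a, b)); bj <<- c(bj, pmax(a, b))
      lfc <<- c(lfc, draw(length(a), role, sign))
    }
    cl <- function(bins) {
      cmb <- utils::combn(bins, 2L)
      list(i = cmb[1L, ], j = cmb[2L, ])
    }
    cc <- cl(p$Core); add(cc$i, cc$j, "core", +1)
    ac <- cl(p$AltCore); add(ac$i, ac$j, "altcore", +1)
    for (b in p$Peri)
      add(rep(b, spec$peri_edges),
          sample(p$Core, spec$peri_edges), "peri", +1)
    ex_targets <- c(p$Core, p$AltCore)
    for (b in p$ExCore)
      add(rep(b, spec$excore_edges),
          sample(ex_targets, spec$excore_edges), "excore", -1)
    for (b in p$Other)
      add(b, sample(p$Peri, 1L), "other", +1)
    if (spec$noise_p > 0) {
      n_bins <- floor(spec$chrom_lengths[spec$chrom_names == ch] /
                        spec$bin_size)
      cmb <- utils::combn(0:(n_bins - 1L), 2L)
      hit <- stats::runif(ncol(cmb)) < spec$noise_p
      planted_keys <- paste(bi, bj)
      ni <- cmb[1L, hit]; nj <- cmb[2L, hit]
      new <- !(paste(ni, nj) %in% planted_keys)
      ni <- ni[new]; nj <- nj[new]
      signs <- sample(c(-1, 1), length(ni), replace = TRUE)
      bi <- c(bi, ni); bj <- c(bj, nj)
      lfc <- c(lfc, draw(length(ni), "noise", 1) * signs)
    }
    data.frame(chrom = ch, bin_i = bi, bin_j = bj, logFC = lfc,
               fdr = stats::runif(length(bi), 0, 0.04))
  })
  t1 <- do.call(rbind, per_chrom)
  ord <- order(match(t1$chrom, spec$chrom_names), t1$bin_i, t1$bin_j)
  t1 <- t1[ord, , drop = FALSE]
  rownames(t1) <- NULL
  t2 <- t1
  t2$logFC <- -t1$logFC
  tables <- stats::setNames(list(t1, t2), spec$contrasts)
  truth <- do.call(rbind, lapply(spec$chrom_names, function(ch)
    data.frame(chrom = ch,
               bin = unlist(p, use.names = FALSE),
               label = rep(names(p), lengths(p)))))
  truth <- truth[order(match(truth$chrom, spec$chrom_names), truth$bin), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  list(tables = tables, truth = truth)
}

#' Simulate contact matrices with a planted compartment checkerboard
#'
#' Expected count `scale * max(d, 0.5)^(-alpha)` at bin separation `d`,
#' multiplied by `block_boost` when the two bins share a planted label
#' (alternating A/B blocks of `block_len` bins) and by lognormal noise;
#' symmetrized by construction. Counts are left continuous by default;
#' `poisson = TRUE` samples Poisson counts instead.
#'
#' @param spec a [synthetic_spec()].
#' @param poisson sample integer counts (default `FALSE`).
#' @return list: `matrices` (one [contact_matrix()] per chromosome, named)
#'   and `truth` (data.frame `chrom`, `bin`, `label` with "A"/"B").
#' @export
simulate_contacts <- function(spec, poisson = FALSE) {
  set.seed(derive_seed(spec$seed, 3L))
  out <- lapply(seq_along(spec$chrom_names), function(ci) {
    ch <- spec$chrom_names[ci]
    n <- floor(spec$chrom_lengths[ci] / spec$bin_size)
    lab <- ifelse(floor((0:(n - 1L)) / spec$block_len) %% 2L == 0L,
                  "A", "B")
    d <- abs(outer(0:(n - 1L), 0:(n - 1L), "-"))
    expected <- spec$contact_scale * pmax(d, 0.5)^(-spec$contact_alpha)
    same <- outer(lab, lab, "==")
    expected <- expected * ifelse(same, spec$block_boost, 1)
    M <- matrix(0, n, n)
    ut <- upper.tri(M, diag = TRUE)
    noise <- exp(stats::rnorm(sum(ut), 0, spec$contact_sd))
    M[ut] <- expected[ut] * noise
    M <- M + t(M) - diag(diag(M))
    if (poisson) {
      counts <- stats::rpois(sum(ut), M[ut])
      M[ut] <- counts
      M[lower.tri(M)] <- 0
      M <- M + t(M) - diag(diag(M))
    }
    list(cm = contact_matrix(ch, M, spec$bin_size),
         truth = data.frame(chrom = ch, bin = 0:(n - 1L), label = lab))
  })
  list(matrices = stats::setNames(lapply(out, `[[`, "cm"),
                                  spec$chrom_names),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Simulate a gene expression table with class-dependent effects
#'
#' Plants `genes_per_bin` genes fully inside each labelled bin plus
#' background genes at sampled unlabelled bins. Per contrast, gene logFC is
#' Normal(class mean, sd) — class means negated in the second contrast,
#' background genes centred at zero — and the DE flag is
#' `|logFC| > de_threshold`.
#'
#' @param spec a [synthetic_spec()].
#' @param labels truth labels from [simulate_diffnet()] (`chrom`, `bin`,
#'   `label`).
#' @return a [read_genes()]-style data.frame with `logFC_<contrast>` and
#'   `de_<contrast>` columns; attribute `contrasts`.
#' @export
simulate_expression <- function(spec, labels) {
  set.seed(derive_seed(spec$seed, 4L))
  bs <- spec$bin_size
  gw <- 10000L
  planted <- if (nrow(labels)) do.call(rbind, lapply(
    seq_len(nrow(labels)), function(i) {
      b <- labels$bin[i]
      off <- gw + (seq_len(spec$genes_per_bin) - 1L) *
        floor((bs - 3L * gw) / max(spec$genes_per_bin - 1L, 1L))
      data.frame(gene_id = sprintf("g_%s_%d_%d", labels$chrom[i], b,
                                   seq_len(spec$genes_per_bin)),
                 chrom = labels$chrom[i],
                 start = b * bs + off, end = b * bs + off + gw,
                 class = as.character(labels$label[i]))
    })) else NULL
  bg <- do.call(rbind, lapply(seq_along(spec$chrom_names), function(ci) {
    ch <- spec$chrom_names[ci]
    n <- floor(spec$chrom_lengths[ci] / spec$bin_size)
    labelled <- labels$bin[labels$chrom == ch]
    free <- setdiff(0:(n - 1L), labelled)
    bins <- sort(sample(free, min(spec$bg_genes_per_chrom, length(free))))
    data.frame(gene_id = sprintf("bg_%s_%d", ch, bins), chrom = ch,
               start = bins * bs + gw, end = bins * bs + 2L * gw,
               class = "Background")
  }))
  genes <- rbind(planted, bg)
  mu1 <- ifelse(genes$class == "Background", 0,
                spec$expr_means[genes$class])
  for (k in 1:2) {
    mu <- if (k == 1L) mu1 else -mu1
    lfc <- stats::rnorm(nrow(genes), mu, spec$expr_sd)
    genes[[paste0("logFC_", spec$contrasts[k])]] <- lfc
    genes[[paste0("de_", spec$contrasts[k])]] <-
      as.integer(abs(lfc) > spec$de_threshold)
  }
  genes$class <- NULL
  genes <- genes[order(match(genes$chrom, spec$chrom_names), genes$start,
                       genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  attr(genes, "contrasts") <- spec$contrasts
  genes
}

#' Write a full synthetic dataset to disk
#'
#' Runs all four generators and writes chrom.sizes, peaks BED,
#' diff-interaction TSVs (one per contrast, in anchor coordinates),
#' contact triplet TSVs (one per chromosome), the genes TSV, the truth
#' files (planted dense intervals BED, planted labels BED, compartment
#' labels bedGraph under `truth/`) and a JSON manifest recording the full
#' spec. All files use LF line endings and deterministic number formatting,
#' so identical specs give byte-identical directories.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written file paths.
#' @export
write_synthetic <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  layout <- spec_layout(spec)
  pk <- simulate_peaks(spec)
  dn <- simulate_diffnet(spec)
  ct <- simulate_contacts(spec)
  genes <- simulate_expression(spec, dn$truth)

  paths <- list(chrom_sizes = file.path(dir, "chrom.sizes"),
                peaks = file.path(dir, "peaks.bed"),
                genes = file.path(dir, "genes.tsv"),
                truth_dense = file.path(dir, "truth", "dense_intervals.bed"),
                truth_labels = file.path(dir, "truth", "labels.bed"),
                truth_compartments = file.path(dir, "truth",
                                               "compartments.bedgraph"),
                manifest = file.path(dir, "manifest.json"))

  write_lines_lf(sprintf("%s\t%s", spec$chrom_names,
                         fmt_coord(spec$chrom_lengths)),
                 paths$chrom_sizes)
  write_intervals(pk$peaks, paths$peaks)
  for (co in spec$contrasts) {
    path <- file.path(dir, paste0("diffnet_", co, ".tsv"))
    write_diff_interactions(dn$tables[[co]], layout, path)
    paths[[paste0("diffnet_", co)]] <- path
  }
  for (ch in spec$chrom_names) {
    path <- file.path(dir, paste0("contacts_", ch, ".tsv"))
    write_contacts(ct$matrices[[ch]], path)
    paths[[paste0("contacts_", ch)]] <- path
  }
  write_tsv_report(genes, paths$genes)
  write_intervals(pk$truth, paths$truth_dense)
  labs <- dn$truth
  write_intervals(
    data.frame(chrom = labs$chrom,
               start = labs$bin * spec$bin_size,
               end = mapply(function(ch, b) bin_end(layout, ch, b),
                            labs$chrom, labs$bin),
               name = as.character(labs$label)),
    paths$truth_labels)
  comp <- ct$truth
  write_bedgraph(
    data.frame(chrom = comp$chrom, bin = comp$bin,
               value = ifelse(comp$label == "A", 1, -1)),
    layout, paths$truth_compartments)
  manifest <- list(generator = "chromcore write_synthetic",
                   spec = unclass(spec),
                   files = lapply(paths[names(paths) != "manifest"],
                                  basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
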