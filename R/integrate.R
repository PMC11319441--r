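# Joining class labels with gene expression, interaction logFC, contact
# connectivity and chromosome-level features.

#' Assign class labels to genes by interval overlap
#'
#' A gene receives every class label whose bins its interval overlaps
#' (multi-label allowed and flagged); genes overlapping no labelled bin are
#' `Background`. Multi-label retention is deliberate: genes frequently
#' straddle 200 kb bins, and dropping secondary labels would silently move
#' genes between classes.
#'
#' @param genes a [read_genes()]-style table.
#' @param labels a [classify_all()] label table.
#' @param layout a [genome_layout()].
#' @return long data.frame: one row per (gene, label), with the gene's
#'   `logFC_*`/`de_*` columns and a `multi_label` flag.
#' @export
genes_by_class <- function(genes, labels, layout) {
  meta_cols <- setdiff(names(genes), c("gene_id", "chrom", "start", "end"))
  empty <- cbind(data.frame(gene_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            label = character(), multi_label = logical()),
                 genes[0, meta_cols, drop = FALSE])
  if (nrow(genes) == 0L) return(empty)
  bs <- layout$bin_size
  key_lab <- paste(labels$chrom, labels$bin)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    b0 <- floor(g$start / bs); b1 <- floor((g$end - 1) / bs)
    hits <- match(paste(g$chrom, b0:b1), key_lab)
    labs <- unique(as.character(labels$label[hits[!is.na(hits)]]))
    if (length(labs) == 0L) labs <- "Background"
    out <- g[rep(1L, length(labs)), , drop = FALSE]
    out$label <- labs
    out$multi_label <- length(labs) > 1L
    out
  })
  out <- do.call(rbind, rows)
  out <- out[, c("gene_id", "chrom", "start", "end", "label", "multi_label",
                 meta_cols)]
  rownames(out) <- NULL
  out
}

#' Per-class expression summary of DE genes
#'
#' @param joined a [genes_by_class()] table.
#' @param contrast contrast name (expects columns `logFC_<contrast>` and
#'   `de_<contrast>`).
#' @return data.frame (`label`, `contrast`, `n`, `median_logFC`, `q25`,
#'   `q75`) over DE genes; classes without DE genes get `n = 0` and `NA`
#'   summaries.
#' @export
class_expression_summary <- function(joined, contrast) {
  lf <- paste0("logFC_", contrast); de <- paste0("de_", contrast)
  if (!all(c(lf, de) %in% names(joined)))
    stop("contrast ", contrast, " not present in the joined table")
  lvls <- c(CLASS_LEVELS, "Background")
  rows <- lapply(lvls, function(lv) {
    v <- joined[[lf]][joined$label == lv & joined[[de]] != 0]
    data.frame(label = lv, contrast = contrast, n = length(v),
               median_logFC = if (length(v)) stats::median(v) else NA_real_,
               q25 = if (length(v)) unname(stats::quantile(v, 0.25))
                     else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75))
                     else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interaction logFC summaries per unordered class pair
#'
#' Every edge contributes to exactly one unordered label pair; all 15 pairs
#' over the five classes are reported, unpopulated pairs with `n = 0`.
#'
#' @param net a `DiffNetwork`.
#' @param labels label table covering every node of `net` (error otherwise).
#' @return data.frame (`label_i`, `label_j`, `n`, `median_logFC`, `q25`,
#'   `q75`).
#' @export
interactions_by_class_pair <- function(net, labels) {
  e <- network_edges(net)
  lab <- labels[labels$chrom == net$chrom, , drop = FALSE]
  li <- as.character(lab$label[match(e$bin_i, lab$bin)])
  lj <- as.character(lab$label[match(e$bin_j, lab$bin)])
  if (anyNA(li) || anyNA(lj)) {
    missing_bin <- c(e$bin_i[is.na(li)], e$bin_j[is.na(lj)])[1L]
    stop("unlabeled network bin on ", net$chrom, ": ", missing_bin)
  }
  pair_i <- pmin(li, lj); pair_j <- pmax(li, lj)
  combos <- expand.grid(a = CLASS_LEVELS, b = CLASS_LEVELS,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$a <= combos$b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    sel <- pair_i == combos$a[k] & pair_j == combos$b[k]
    v <- e$logFC[sel]
    data.frame(label_i = combos$a[k], label_j = combos$b[k], n = sum(sel),
               median_logFC = if (length(v)) stats::median(v) else NA_real_,
               q25 = if (length(v)) unname(stats::quantile(v, 0.25))
                     else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75))
                     else NA_real_)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$label_i, CLASS_LEVELS),
               match(out$label_j, CLASS_LEVELS))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool class-pair summaries across chromosomes
#'
#' @param nets list of `DiffNetwork`.
#' @param labels genome-wide label table.
#' @return one [interactions_by_class_pair()]-style table computed over the
#'   pooled edges of all networks.
#' @export
interactions_by_class_pair_all <- function(nets, labels) {
  per <- lapply(nets, function(net) {
    e <- network_edges(net)
    lab <- labels[labels$chrom == net$chrom, , drop = FALSE]
    li <- as.character(lab$label[match(e$bin_i, lab$bin)])
    lj <- as.character(lab$label[match(e$bin_j, lab$bin)])
    if (anyNA(li) || anyNA(lj))
      stop("unlabeled network bin on ", net$chrom)
    data.frame(label_i = pmin(li, lj), label_j = pmax(li, lj),
               logFC = e$logFC)
  })
  pooled <- do.call(rbind, per)
  combos <- expand.grid(a = CLASS_LEVELS, b = CLASS_LEVELS,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$a <= combos$b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    v <- pooled$logFC[pooled$label_i == combos$a[k] &
                        pooled$label_j == combos$b[k]]
    data.frame(label_i = combos$a[k], label_j = combos$b[k], n = length(v),
               median_logFC = if (length(v)) stats::median(v) else NA_real_,
               q25 = if (length(v)) unname(stats::quantile(v, 0.25))
                     else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75))
                     else NA_real_)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$label_i, CLASS_LEVELS),
               match(out$label_j, CLASS_LEVELS))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean contact frequency of bin sets
#'
#' Per-bin connectivity is the mean of the (balanced) matrix row over
#' unmasked columns; the two disjoint bin sets are compared by their
#' medians and a two-sided Wilcoxon rank-sum test.
#'
#' @param bm a [ice_balance()] result (or a [contact_matrix()]; its raw
#'   matrix is then used with its mask).
#' @param bins_of_interest,background disjoint 0-based bin index vectors;
#'   all bins must be unmasked and non-empty sets are required.
#' @return list with `per_bin` (data.frame `bin`, `set`, `mean_contact`)
#'   and `summary` (per-set n/median/quartiles plus `wilcoxon_p`).
#' @export
binset_connectivity <- function(bm, bins_of_interest, background) {
  if (length(bins_of_interest) == 0L || length(background) == 0L)
    stop("both bin sets must be non-empty")
  if (length(intersect(bins_of_interest, background)))
    stop("bin sets must be disjoint")
  M <- bm$matrix
  mask <- bm$mask
  idx_all <- c(bins_of_interest, background) + 1L
  if (any(idx_all < 1L | idx_all > nrow(M)))
    stop("bin index out of range")
  if (any(mask[idx_all]))
    stop("bin sets must be unmasked")
  unmasked_cols <- which(!mask)
  row_mean <- function(i) mean(M[i, unmasked_cols], na.rm = TRUE)
  per_bin <- data.frame(
    bin = c(bins_of_interest, background),
    set = rep(c("interest", "background"),
              c(length(bins_of_interest), length(background))),
    mean_contact = vapply(idx_all, row_mean, 1))
  q <- function(v, p) unname(stats::quantile(v, p))
  s <- split(per_bin$mean_contact, per_bin$set)
  summary <- data.frame(
    set = names(s), n = vapply(s, length, 1L),
    median = vapply(s, stats::median, 1),
    q25 = vapply(s, q, 1, p = 0.25), q75 = vapply(s, q, 1, p = 0.75))
  summary$wilcoxon_p <- suppressWarnings(
    stats::wilcox.test(s$interest, s$background)$p.value)
  rownames(summary) <- NULL
  list(per_bin = per_bin, summary = summary)
}

#' Pearson correlation between two binned tracks
#'
#' @param a,b binned tracks (`chrom`, `bin`, `value`).
#' @param log_transform_a apply `log(a + 1)` (natural log, pseudocount 1)
#'   to track `a` before correlating.
#' @return list (`estimate`, `n`, `log_transform_a`); errors with fewer
#'   than 3 jointly non-missing bins.
#' @export
track_correlation <- function(a, b, log_transform_a = FALSE) {
  key_a <- paste(a$chrom, a$bin); key_b <- paste(b$chrom, b$bin)
  common <- intersect(key_a, key_b)
  va <- a$value[match(common, key_a)]
  vb <- b$value[match(common, key_b)]
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3L)
    stop("need at least 3 jointly non-missing bins (have ", sum(ok), ")")
  va <- va[ok]; vb <- vb[ok]
  if (log_transform_a) va <- log(va + 1)
  list(estimate = stats::cor(va, vb), n = sum(ok),
       log_transform_a = log_transform_a)
}

#' Correlate per-chromosome k-max with chromosome features
#'
#' @param kmax_table a [kmax_by_chromosome()] table.
#' @param features data.frame with a `chrom` column and one numeric column
#'   per feature (e.g. peak counts, mean signal, AT fraction).
#' @return data.frame (`feature`, `pearson`, `spearman`, `n`); a constant
#'   feature (or constant k-max) yields `NA` correlations.
#' @export
kmax_feature_report <- function(kmax_table, features) {
  merged <- merge(kmax_table, features, by = "chrom")
  if (nrow(merged) < 3L)
    stop("need at least 3 chromosomes for a k-max feature report (have ",
         nrow(merged), ")")
  feat_cols <- setdiff(names(features), "chrom")
  kmax_constant <- stats::sd(merged$k_max) == 0
  rows <- lapply(feat_cols, function(fc) {
    v <- merged[[fc]]
    if (kmax_constant || length(unique(v)) < 2L || stats::sd(v) == 0)
      return(data.frame(feature = fc, pearson = NA_real_,
                        spearman = NA_real_, n = nrow(merged)))
    data.frame(feature = fc,
               pearson = stats::cor(merged$k_max, v, method = "pearson"),
               spearman = stats::cor(merged$k_max, v, method = "spearman"),
               n = nrow(merged))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
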