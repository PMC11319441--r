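# Per-chromosome differential interaction networks: bins as nodes, signed
# differential contacts as edges.

#' Build per-chromosome differential networks
#'
#' One igraph per chromosome with at least one retained row. Edges carry
#' `sign` ("increased" for positive logFC, "decreased" for negative),
#' `logFC`, `weight = |logFC|` and `fdr`. Rows with `logFC == 0` are
#' signless and excluded (count logged as an attribute).
#'
#' @param table a [read_diff_interactions()] table.
#' @return named list of `DiffNetwork` objects (`chrom`, `graph`), with
#'   attribute `n_zero_logfc_dropped`.
#' @export
build_networks <- function(table) {
  zero <- table$logFC == 0
  n_zero <- sum(zero)
  table <- table[!zero, , drop = FALSE]
  chroms <- unique(table$chrom)
  nets <- lapply(chroms, function(ch) {
    rows <- table[table$chrom == ch, , drop = FALSE]
    verts <- as.character(sort(unique(c(rows$bin_i, rows$bin_j))))
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(rows$bin_i),
                 to = as.character(rows$bin_j),
                 sign = ifelse(rows$logFC > 0, "increased", "decreased"),
                 logFC = rows$logFC, weight = abs(rows$logFC),
                 fdr = rows$fdr),
      directed = FALSE, vertices = verts)
    structure(list(chrom = ch, graph = g), class = "DiffNetwork")
  })
  names(nets) <- chroms
  attr(nets, "n_zero_logfc_dropped") <- n_zero
  nets
}

#' @export
print.DiffNetwork <- function(x, ...) {
  s <- igraph::E(x$graph)$sign
  cat(sprintf("DiffNetwork %s: %d node(s), %d edge(s) (%d increased / %d decreased)\n",
              x$chrom, igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(s == "increased"), sum(s == "decreased")))
  invisible(x)
}

#' Edge table of a differential network
#'
#' @param net a `DiffNetwork`.
#' @return data.frame (`chrom`, `bin_i`, `bin_j`, `sign`, `logFC`, `fdr`)
#'   with `bin_i <= bin_j`.
#' @export
network_edges <- function(net) {
  g <- net$graph
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L)
    return(data.frame(chrom = character(), bin_i = integer(),
                      bin_j = integer(), sign = character(),
                      logFC = numeric(), fdr = numeric()))
  bi <- as.integer(el[, 1L]); bj <- as.integer(el[, 2L])
  data.frame(chrom = net$chrom, bin_i = pmin(bi, bj), bin_j = pmax(bi, bj),
             sign = igraph::E(g)$sign, logFC = igraph::E(g)$logFC,
             fdr = igraph::E(g)$fdr)
}

#' Local/distal range class of a bin pair
#'
#' Distance is measured between bin midpoints; pairs within the distal
#' threshold (2 Mb, inclusive) are "local", farther pairs "distal".
#'
#' @param layout a [genome_layout()].
#' @param chrom_i,chrom_j chromosome of each anchor (must match: the
#'   networks are cis-only).
#' @param bin_i,bin_j bin indices.
#' @param distal_threshold bp; distances strictly greater are distal.
#' @return character vector `"local"`/`"distal"`.
#' @export
range_class <- function(layout, chrom_i, bin_i, chrom_j, bin_j,
                        distal_threshold = 2e6) {
  if (any(chrom_i != chrom_j))
    stop("range_class is defined for cis pairs only")
  d <- abs(bin_midpoint(layout, chrom_i[1L], bin_i) -
             bin_midpoint(layout, chrom_j[1L], bin_j))
  ifelse(d <= distal_threshold, "local", "distal")
}

#' Bins bound by a factor, by per-bin peak count
#'
#' A bin is "bound" when at least `min_peaks` peak midpoints fall in it
#' (the working definition of an HMGA1-bound 200 kb bin).
#'
#' @param peaks interval data.frame.
#' @param layout a [genome_layout()].
#' @param min_peaks minimum midpoint count (default 5).
#' @return data.frame (`chrom`, `bin`, `n_peaks`) of bound bins.
#' @export
hmga1_bound_bins <- function(peaks, layout, min_peaks = 5L) {
  if (min_peaks < 1L) stop("min_peaks must be >= 1")
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), bin = integer(),
                      n_peaks = integer()))
  unk <- setdiff(unique(peaks$chrom), layout$chrom_names)
  if (length(unk)) stop("peaks on unknown chromosome(s): ",
                        paste(unk, collapse = ", "))
  mids <- floor((peaks$start + peaks$end) / 2)
  bin <- floor(mids / layout$bin_size)
  tab <- stats::aggregate(list(n_peaks = bin),
                          by = list(chrom = peaks$chrom, bin = bin), length)
  tab <- tab[tab$n_peaks >= min_peaks, , drop = FALSE]
  tab <- tab[order(match(tab$chrom, layout$chrom_names), tab$bin), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Cross-tabulate network edges by range, compartment pair and bound anchors
#'
#' Every edge falls into exactly one cell per factor: range class
#' (local/distal on midpoint distance), compartment pair (AA/BB/AB from the
#' sign of the A/B score of each anchor, or "NA" when either score is
#' missing) and the number of bound anchors (0/1/2).
#'
#' @param net a `DiffNetwork`.
#' @param compartments a compartment track data.frame (`chrom`, `bin`,
#'   `score`), or `NULL` (all edges fall in the "NA" compartment cell).
#' @param bound data.frame (`chrom`, `bin`) of bound bins, or `NULL`.
#' @param layout a [genome_layout()].
#' @param distal_threshold bp (default 2 Mb).
#' @return data.frame with one row per populated cell:
#'   `compartment_pair`, `range_class`, `n_bound_anchors`, `sign`, `n`,
#'   `median_logFC`, `q25`, `q75`.
#' @export
categorize_edges <- function(net, compartments = NULL, bound = NULL, layout,
                             distal_threshold = 2e6) {
  e <- network_edges(net)
  if (nrow(e) == 0L)
    return(data.frame(compartment_pair = character(),
                      range_class = character(),
                      n_bound_anchors = integer(), sign = character(),
                      n = integer(), median_logFC = numeric(),
                      q25 = numeric(), q75 = numeric()))
  e$range_class <- range_class(layout, rep(net$chrom, nrow(e)), e$bin_i,
                               rep(net$chrom, nrow(e)), e$bin_j,
                               distal_threshold)
  comp_of <- function(bins) {
    if (is.null(compartments)) return(rep(NA_character_, length(bins)))
    sc <- compartments$score[match(paste(net$chrom, bins),
                                   paste(compartments$chrom,
                                         compartments$bin))]
    ifelse(is.na(sc), NA_character_, ifelse(sc >= 0, "A", "B"))
  }
  ci <- comp_of(e$bin_i); cj <- comp_of(e$bin_j)
  e$compartment_pair <- ifelse(
    is.na(ci) | is.na(cj), "NA",
    paste0(pmin(ci, cj), pmax(ci, cj)))
  bset <- if (is.null(bound)) character(0) else
    paste(bound$chrom[bound$chrom == net$chrom],
          bound$bin[bound$chrom == net$chrom])
  e$n_bound_anchors <- (paste(net$chrom, e$bin_i) %in% bset) +
    (paste(net$chrom, e$bin_j) %in% bset)
  agg <- summarize_groups(
    e, c("compartment_pair", "range_class", "n_bound_anchors", "sign"),
    "logFC")
  agg[order(agg$compartment_pair, agg$range_class, agg$n_bound_anchors,
            agg$sign), , drop = FALSE]
}

# n / median / quartiles of `value_col` by the given grouping columns.
summarize_groups <- function(df, group_cols, value_col) {
  key <- interaction(df[group_cols], drop = TRUE, lex.order = TRUE)
  sp <- split(df[[value_col]], key)
  meta <- df[!duplicated(key), group_cols, drop = FALSE]
  meta <- meta[match(names(sp), key[!duplicated(key)]), , drop = FALSE]
  out <- cbind(meta,
               n = vapply(sp, length, 1L),
               median_logFC = vapply(sp, stats::median, 1),
               q25 = vapply(sp, function(v)
                 unname(stats::quantile(v, 0.25)), 1),
               q75 = vapply(sp, function(v)
                 unname(stats::quantile(v, 0.75)), 1))
  rownames(out) <- NULL
  out
}
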