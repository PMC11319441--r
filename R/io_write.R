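# Writers. All emit tab-separated, LF-terminated text with plain decimal
# coordinates so that re-running a pipeline reproduces byte-identical files.

fmt_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
fmt_num <- function(x, digits = 17L) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write an interval set as BED
#'
#' @param x data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score` columns.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_intervals <- function(x, path) {
  ncol_out <- if (!is.null(x$score) && any(!is.na(x$score))) 5L
              else if (!is.null(x$name) && any(!is.na(x$name))) 4L else 3L
  lines <- character(nrow(x))
  if (nrow(x)) {
    f <- paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end), sep = "\t")
    if (ncol_out >= 4L) {
      nm <- if (is.null(x$name)) rep(".", nrow(x)) else
        ifelse(is.na(x$name), ".", x$name)
      f <- paste(f, nm, sep = "\t")
    }
    if (ncol_out >= 5L) {
      sc <- ifelse(is.na(x$score), "0", fmt_num(x$score, 10L))
      f <- paste(f, sc, sep = "\t")
    }
    lines <- f
  }
  write_lines_lf(lines, path)
}

#' Write a differential-interaction table
#'
#' Emits the same dialect [read_diff_interactions()] consumes; bin indices
#' are expanded back to bin-aligned anchors.
#'
#' @param x table as returned by [read_diff_interactions()].
#' @param layout a [genome_layout()].
#' @param path output file.
#' @export
write_diff_interactions <- function(x, layout, path) {
  bs <- layout$bin_size
  header <- paste(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "logFC", "FDR"), collapse = "\t")
  lines <- header
  if (nrow(x)) {
    e1 <- pmin((x$bin_i + 1) * bs, layout$chrom_lengths[x$chrom])
    e2 <- pmin((x$bin_j + 1) * bs, layout$chrom_lengths[x$chrom])
    lines <- c(header, paste(
      x$chrom, fmt_coord(x$bin_i * bs), fmt_coord(e1),
      x$chrom, fmt_coord(x$bin_j * bs), fmt_coord(e2),
      fmt_num(x$logFC), fmt_num(x$fdr), sep = "\t"))
  }
  write_lines_lf(lines, path)
}

#' Write a binned track as bedGraph
#'
#' `NA` bins are omitted (uncovered), matching the missing-value convention
#' of [bin_signal()].
#'
#' @param track data.frame (`chrom`, `bin`, `value`).
#' @param layout a [genome_layout()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, layout, path) {
  keep <- !is.na(track$value)
  x <- track[keep, , drop = FALSE]
  lines <- character(0)
  if (nrow(x)) {
    s <- bin_start_vec(layout, x$chrom, x$bin)
    e <- bin_end_vec(layout, x$chrom, x$bin)
    lines <- paste(x$chrom, fmt_coord(s), fmt_coord(e), fmt_num(x$value, 10L),
                   sep = "\t")
  }
  write_lines_lf(lines, path)
}

bin_start_vec <- function(layout, chrom, bin) bin * layout$bin_size
bin_end_vec <- function(layout, chrom, bin)
  pmin((bin + 1) * layout$bin_size, unname(layout$chrom_lengths[chrom]))

#' Write a contact matrix as a sparse triplet TSV
#'
#' Upper triangle (including the diagonal) of non-zero entries, with header
#' `chrom bin_i bin_j count`.
#'
#' @param cm a [contact_matrix()].
#' @param path output file.
#' @export
write_contacts <- function(cm, path) {
  M <- cm$matrix
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  header <- "chrom\tbin_i\tbin_j\tcount"
  lines <- header
  if (nrow(idx)) {
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    lines <- c(header, paste(cm$chrom, idx[, 1L] - 1L, idx[, 2L] - 1L,
                             fmt_num(M[idx]), sep = "\t"))
  }
  write_lines_lf(lines, path)
}

#' Write a plain data frame as a headered TSV
#'
#' Numeric columns are formatted with up to 10 significant digits; used for
#' all report tables.
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv_report <- function(df, path) {
  fmt <- lapply(df, function(col) {
    if (is.numeric(col) && !all(col == floor(col), na.rm = TRUE))
      fmt_num(col, 10L)
    else if (is.numeric(col)) {
      out <- format(col, scientific = FALSE, trim = TRUE)
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  })
  lines <- paste(names(df), collapse = "\t")
  if (nrow(df))
    lines <- c(lines, do.call(paste, c(fmt, sep = "\t")))
  write_lines_lf(lines, path)
}

#' Export a differential network as GraphML
#'
#' Node attributes: bin index, start/end coordinates and (optionally) a
#' bound flag; edge attributes: sign, logFC, fdr.
#'
#' @param net a `DiffNetwork` (see [build_networks()]).
#' @param layout a [genome_layout()].
#' @param path output file.
#' @param bound optional data.frame (`chrom`, `bin`) of protein-bound bins.
#' @export
write_graphml <- function(net, layout, path, bound = NULL) {
  g <- net$graph
  bins <- as.integer(igraph::V(g)$name)
  igraph::V(g)$bin <- bins
  igraph::V(g)$start <- bin_start(layout, net$chrom, bins)
  igraph::V(g)$end <- bin_end(layout, net$chrom, bins)
  if (!is.null(bound)) {
    bb <- bound$bin[bound$chrom == net$chrom]
    igraph::V(g)$bound <- as.integer(bins %in% bb)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
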