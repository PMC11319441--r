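# Readers for the plain-text genomic formats the pipeline consumes.
# Coordinates are 0-based half-open (BED convention) everywhere internally.

#' Read a chrom.sizes file into a genome layout
#'
#' @param path two-column whitespace-separated file: chromosome name, length.
#' @param bin_size bin width in bp for the resulting layout.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path, bin_size = 200000L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("chrom.sizes line ", bad[1L], " has fewer than 2 fields: '",
         lines[bad[1L]], "'")
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(len) | len <= 0 | len != floor(len))
  if (length(bad))
    stop("chrom.sizes line ", bad[1L], " has a non-positive-integer length: '",
         lines[bad[1L]], "'")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name in ", path, ": ", nm[duplicated(nm)][1L])
  genome_layout(nm, len, bin_size = bin_size)
}

#' Read a BED/narrowPeak file as an interval set
#'
#' Columns beyond the third are kept as `name` (col 4) and `score` (col 5);
#' further narrowPeak columns are ignored. Output is sorted by
#' (chrom, start, end).
#'
#' @param path BED3+ file, tab-separated, no header.
#' @param layout optional [genome_layout()]; when given, chromosome names are
#'   validated against it.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_intervals <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 3L))
    stop("BED line ", which(nf < 3L)[1L], " has fewer than 3 columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop("BED line ", bad[1L], " has non-numeric coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("BED line ", bad[1L], " has start >= end (or negative start): '",
         lines[bad[1L]], "'")
  name <- ifelse(nf >= 4L, vapply(parts, function(p)
    if (length(p) >= 4L) p[[4L]] else NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(
    nf >= 5L,
    vapply(parts, function(p) if (length(p) >= 5L) p[[5L]] else NA_character_,
           ""),
    NA_character_)))
  if (!is.null(layout)) {
    unk <- setdiff(unique(chrom), layout$chrom_names)
    if (length(unk)) stop("unknown chromosome(s) in ", path, ": ",
                          paste(unk, collapse = ", "))
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = name, score = score)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a differential-interaction table
#'
#' Loads a BEDPE-like TSV of cis differential Hi-C calls, converts anchors to
#' bin indices on the given layout, applies significance filters, and
#' deterministically collapses duplicate pairs.
#'
#' The input must carry the header
#' `chrom1 start1 end1 chrom2 start2 end2 logFC FDR` and each anchor must be
#' aligned to the layout's bin grid. Trans (inter-chromosomal) rows and
#' self-pairs are dropped with logged counts; rows failing
#' `fdr <= fdr_max` or `|logFC| >= min_abs_logfc` are dropped; duplicate
#' `(chrom, bin_i, bin_j)` keys keep the row with smallest FDR, then largest
#' `|logFC|`, then first occurrence.
#'
#' @param path tab-separated file with the header above.
#' @param layout a [genome_layout()].
#' @param fdr_max keep rows with adjusted significance at or below this
#'   (default 0.05).
#' @param min_abs_logfc keep rows with `|logFC|` at or above this (default 0).
#' @return data.frame with columns `chrom`, `bin_i`, `bin_j`, `logFC`, `fdr`
#'   (`bin_i <= bin_j`), carrying attributes `bin_size`, `n_trans_dropped`,
#'   `n_self_dropped`, `n_filtered`, `n_dedup_dropped`.
#' @export
read_diff_interactions <- function(path, layout, fdr_max = 0.05,
                                   min_abs_logfc = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "logFC", "FDR")
  if (!all(need %in% names(df)))
    stop("differential-interaction table must have header columns: ",
         paste(need, collapse = " "))
  diff_interactions_from_anchors(df, layout, fdr_max = fdr_max,
                                 min_abs_logfc = min_abs_logfc)
}

# Shared anchor -> bin conversion, filtering and deduplication; `df` has the
# eight canonical columns already.
diff_interactions_from_anchors <- function(df, layout, fdr_max = 0.05,
                                           min_abs_logfc = 0) {
  bs <- layout$bin_size
  unk <- setdiff(unique(c(df$chrom1, df$chrom2)), layout$chrom_names)
  if (length(unk))
    stop("unknown chromosome(s) in interaction table: ",
         paste(unk, collapse = ", "))
  check_anchor <- function(chrom, start, end, which) {
    len <- layout$chrom_lengths[chrom]
    ok <- (start %% bs == 0) & (end == pmin(start + bs, len)) &
      start >= 0 & end <= len
    if (any(!ok))
      stop("anchor ", which, " not aligned to the ", bs,
           " bp bin grid at row ", which(!ok)[1L])
  }
  if (nrow(df)) {
    check_anchor(df$chrom1, df$start1, df$end1, 1L)
    check_anchor(df$chrom2, df$start2, df$end2, 2L)
  }

  is_trans <- df$chrom1 != df$chrom2
  n_trans <- sum(is_trans)
  df <- df[!is_trans, , drop = FALSE]

  bin_i <- as.integer(df$start1 / bs)
  bin_j <- as.integer(df$start2 / bs)
  swap <- bin_i > bin_j
  tmp <- bin_i[swap]; bin_i[swap] <- bin_j[swap]; bin_j[swap] <- tmp

  is_self <- bin_i == bin_j
  n_self <- sum(is_self)

  keep <- !is_self & df$FDR <= fdr_max & abs(df$logFC) >= min_abs_logfc
  n_filtered <- sum(!keep & !is_self)

  out <- data.frame(chrom = df$chrom1[keep], bin_i = bin_i[keep],
                    bin_j = bin_j[keep], logFC = df$logFC[keep],
                    fdr = df$FDR[keep])

  # deterministic dedup: smallest fdr, then largest |logFC|, then input order
  ord <- order(out$chrom, out$bin_i, out$bin_j, out$fdr, -abs(out$logFC),
               seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  key <- paste(out$chrom, out$bin_i, out$bin_j, sep = ":")
  dup <- duplicated(key)
  n_dedup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  out <- out[order(match(out$chrom, layout$chrom_names), out$bin_i,
                   out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_size") <- bs
  attr(out, "n_trans_dropped") <- n_trans
  attr(out, "n_self_dropped") <- n_self
  attr(out, "n_filtered") <- n_filtered
  attr(out, "n_dedup_dropped") <- n_dedup
  out
}

#' Summarize a bedGraph signal onto a bin grid
#'
#' Each bin's value is the coverage-weighted mean of the bedGraph record
#' values over the covered portion of the bin; bins with no covered bases are
#' `NA`. Records must not overlap within a chromosome.
#'
#' @param path bedGraph file (4 columns, no header; `track` lines skipped).
#' @param layout a [genome_layout()].
#' @return data.frame (`chrom`, `bin`, `value`) covering every bin of the
#'   layout, with attribute `bin_size` and `source`.
#' @export
bin_signal <- function(path, layout) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  grid <- layout_bins(layout)
  grid$value <- NA_real_
  if (length(lines) == 0L) {
    attr(grid, "bin_size") <- layout$bin_size
    attr(grid, "source") <- path
    return(grid)
  }
  parts <- strsplit(lines, "\\s+")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  val <- as.numeric(vapply(parts, `[[`, "", 4L))
  if (any(!is.finite(start) | !is.finite(end) | !is.finite(val)))
    stop("non-numeric field in bedGraph ", path)
  if (any(start >= end)) stop("bedGraph record with start >= end in ", path)
  unk <- setdiff(unique(chrom), layout$chrom_names)
  if (length(unk)) stop("unknown chromosome(s) in ", path, ": ",
                        paste(unk, collapse = ", "))
  ord <- order(chrom, start)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]; val <- val[ord]
  same <- chrom[-1L] == chrom[-length(chrom)]
  if (any(same & start[-1L] < end[-length(end)]))
    stop("overlapping bedGraph records in ", path)

  bs <- layout$bin_size
  acc_num <- new.env(parent = emptyenv())
  acc_den <- new.env(parent = emptyenv())
  for (r in seq_along(chrom)) {
    len <- layout$chrom_lengths[[chrom[r]]]
    s <- start[r]; e <- min(end[r], len)
    if (e <= s) next
    b0 <- floor(s / bs); b1 <- floor((e - 1) / bs)
    for (b in b0:b1) {
      lo <- max(s, b * bs); hi <- min(e, (b + 1) * bs)
      k <- paste0(chrom[r], ":", b)
      acc_num[[k]] <- (if (is.null(acc_num[[k]])) 0 else acc_num[[k]]) +
        val[r] * (hi - lo)
      acc_den[[k]] <- (if (is.null(acc_den[[k]])) 0 else acc_den[[k]]) +
        (hi - lo)
    }
  }
  key <- paste0(grid$chrom, ":", grid$bin)
  num <- vapply(key, function(k)
    if (is.null(acc_num[[k]])) NA_real_ else acc_num[[k]], 0)
  den <- vapply(key, function(k)
    if (is.null(acc_den[[k]])) NA_real_ else acc_den[[k]], 0)
  grid$value <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  rownames(grid) <- NULL
  attr(grid, "bin_size") <- bs
  attr(grid, "source") <- path
  grid
}

#' Read a sparse triplet contact matrix
#'
#' The interchange format is a tab-separated table with header
#' `chrom bin_i bin_j count` holding the upper triangle (or both triangles)
#' of a symmetric binned contact matrix.
#'
#' @param path triplet TSV.
#' @param layout a [genome_layout()].
#' @param chrom chromosome to extract.
#' @param mask_quantile bins whose raw marginal falls below this quantile of
#'   the positive marginals are masked (see [contact_matrix()]).
#' @return a `ContactMatrix` (see [contact_matrix()]).
#' @export
read_contacts <- function(path, layout, chrom, mask_quantile = 0.02) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "bin_i", "bin_j", "count")
  if (!all(need %in% names(df)))
    stop("contact triplet table must have header columns: ",
         paste(need, collapse = " "))
  df <- df[df$chrom == chrom, , drop = FALSE]
  nb <- n_bins(layout, chrom)
  if (nrow(df) && (max(df$bin_i, df$bin_j) >= nb || min(df$bin_i, df$bin_j) < 0))
    stop("bin index out of range for ", chrom)
  M <- matrix(0, nb, nb)
  if (nrow(df)) {
    M[cbind(df$bin_i + 1L, df$bin_j + 1L)] <- df$count
    M[cbind(df$bin_j + 1L, df$bin_i + 1L)] <- df$count
  }
  contact_matrix(chrom, M, layout$bin_size, mask_quantile = mask_quantile)
}

#' Read a gene table
#'
#' @param path TSV with header columns `gene_id chrom start end` plus one
#'   `logFC_<contrast>` and `de_<contrast>` pair per contrast.
#' @param layout optional layout for chromosome validation.
#' @return data.frame; contrast names are stored in attribute `contrasts`.
#' @export
read_genes <- function(path, layout = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene table must have header columns: ", paste(need, collapse = " "))
  if (any(df$start >= df$end)) stop("gene with start >= end in ", path)
  if (!is.null(layout)) {
    unk <- setdiff(unique(df$chrom), layout$chrom_names)
    if (length(unk)) stop("unknown chromosome(s) in ", path, ": ",
                          paste(unk, collapse = ", "))
  }
  lf <- grep("^logFC_", names(df), value = TRUE)
  attr(df, "contrasts") <- sub("^logFC_", "", lf)
  df
}
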