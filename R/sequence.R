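#' Per-bin AT fraction from a FASTA sequence
#'
#' Counts A/T bases (case-insensitive) over the non-N bases of each bin.
#' Bins consisting entirely of N (or other ambiguity codes) are `NA` rather
#' than 0, so assembly gaps are not mistaken for GC-rich sequence.
#'
#' @param fasta path to a FASTA file whose sequence names match the layout's
#'   chromosome names (description after the first whitespace is ignored).
#' @param layout a [genome_layout()].
#' @return data.frame (`chrom`, `bin`, `value`) with AT fraction in `[0, 1]`.
#' @export
at_fraction <- function(fasta, layout) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(layout$chrom_names, names(seqs))
  if (length(missing))
    stop("chromosome(s) absent from FASTA: ", paste(missing, collapse = ", "))
  out <- lapply(layout$chrom_names, function(ch) {
    x <- seqs[[ch]]
    if (length(x) != layout$chrom_lengths[[ch]])
      stop("FASTA length for ", ch, " (", length(x),
           ") differs from layout (", layout$chrom_lengths[[ch]], ")")
    nb <- n_bins(layout, ch)
    b <- seq_len(nb) - 1L
    v <- Biostrings::Views(x, start = bin_start(layout, ch, b) + 1L,
                           end = bin_end(layout, ch, b))
    af <- Biostrings::alphabetFrequency(v, baseOnly = TRUE)
    denom <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    at <- rowSums(af[, c("A", "T"), drop = FALSE])
    data.frame(chrom = ch, bin = b,
               value = ifelse(denom == 0, NA_real_, at / denom))
  })
  res <- do.call(rbind, out)
  attr(res, "bin_size") <- layout$bin_size
  attr(res, "source") <- fasta
  res
}
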