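#' Genome layout: chromosomes, lengths and a fixed bin grid
#'
#' A `GenomeLayout` ties an ordered set of chromosomes to a fixed bin size.
#' Bin `b` (0-based) on a chromosome of length `L` covers the half-open
#' interval `[b * bin_size, min((b + 1) * bin_size, L))`; a chromosome has
#' `ceiling(L / bin_size)` bins, the last of which may be partial.
#'
#' @param chrom_names character vector of chromosome identifiers, in order.
#' @param chrom_lengths integer vector of chromosome lengths in bp (> 0).
#' @param bin_size bin width in bp (> 0). 200 kb is the working resolution
#'   for interaction networks and contact matrices.
#' @return An object of class `GenomeLayout`.
#' @export
genome_layout <- function(chrom_names, chrom_lengths, bin_size = 200000L) {
  if (length(chrom_names) == 0L) stop("layout needs at least one chromosome")
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths differ in length")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome name: ",
         chrom_names[duplicated(chrom_names)][1L])
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be positive")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = stats::setNames(chrom_lengths,
                                         as.character(chrom_names)),
         bin_size = as.numeric(bin_size)),
    class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosome(s), %.0f bp bins\n",
              length(x$chrom_names), x$bin_size))
  for (ch in x$chrom_names)
    cat(sprintf("  %s  %.0f bp  (%d bins)\n", ch, x$chrom_lengths[[ch]],
                n_bins(x, ch)))
  invisible(x)
}

#' Number of bins on a chromosome
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @return integer bin count, `ceiling(length / bin_size)`.
#' @export
n_bins <- function(layout, chrom) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!chrom %in% layout$chrom_names) stop("unknown chromosome: ", chrom)
  as.integer(ceiling(layout$chrom_lengths[[chrom]] / layout$bin_size))
}

#' Map coordinates to bin indices
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name (checked against the layout).
#' @param pos 0-based coordinate vector.
#' @return 0-based bin indices, `floor(pos / bin_size)`.
#' @export
bin_of <- function(layout, chrom, pos) {
  nb <- n_bins(layout, chrom)
  if (any(pos < 0 | pos >= layout$chrom_lengths[[chrom]]))
    stop("coordinate outside chromosome ", chrom)
  b <- floor(pos / layout$bin_size)
  stopifnot(all(b < nb))
  as.integer(b)
}

#' Bin interval boundaries
#'
#' `bin_start()` and `bin_end()` return the half-open interval covered by a
#' bin; the final bin is clipped to the chromosome end. `bin_midpoint()` is
#' the midpoint of that (possibly clipped) interval.
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @param bin 0-based bin index vector.
#' @return numeric coordinates.
#' @export
bin_start <- function(layout, chrom, bin) {
  nb <- n_bins(layout, chrom)
  if (any(bin < 0 | bin >= nb)) stop("bin index out of range on ", chrom)
  bin * layout$bin_size
}

#' @rdname bin_start
#' @export
bin_end <- function(layout, chrom, bin) {
  pmin(bin_start(layout, chrom, bin) + layout$bin_size,
       layout$chrom_lengths[[chrom]])
}

#' @rdname bin_start
#' @export
bin_midpoint <- function(layout, chrom, bin) {
  (bin_start(layout, chrom, bin) + bin_end(layout, chrom, bin)) / 2
}

#' All bins of a layout as a data frame
#' @param layout a [genome_layout()].
#' @return data.frame with columns `chrom`, `bin`, `start`, `end`.
#' @export
layout_bins <- function(layout) {
  out <- lapply(layout$chrom_names, function(ch) {
    nb <- n_bins(layout, ch)
    b <- seq_len(nb) - 1L
    data.frame(chrom = ch, bin = b,
               start = bin_start(layout, ch, b),
               end = bin_end(layout, ch, b))
  })
  do.call(rbind, out)
}
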