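# Calling protein-dense genomic regions from a ChIP-seq peak set.
#
# Peak density is profiled in rolling windows (100 kb windows advancing in
# 5 kb steps by default), a single genome-wide threshold is picked at the
# knee of the sorted count curve, and above-threshold windows are stitched
# into maximal regions.

#' Rolling-window peak counts
#'
#' For every window `[w, w + window_size)` (starts advancing by `step`,
#' final windows clipped at the chromosome end), counts the peaks whose
#' midpoint `floor((start + end) / 2)` lies in the window. Midpoint
#' assignment makes each peak contribute to exactly `window_size / step`
#' windows regardless of its width.
#'
#' @param peaks interval data.frame (`chrom`, `start`, `end`), e.g. from
#'   [read_intervals()].
#' @param layout a [genome_layout()].
#' @param window_size window width in bp (default 100,000).
#' @param step window stride in bp (default 5,000).
#' @return a `RollingDensityProfile`: list with per-chromosome data.frames
#'   (`start`, `end`, `count`) plus `window_size`/`step` metadata.
#' @export
rolling_peak_counts <- function(peaks, layout, window_size = 100000,
                                step = 5000) {
  if (window_size <= 0 || step <= 0)
    stop("window_size and step must be positive")
  if (step > window_size) stop("step must not exceed window_size")
  unk <- setdiff(unique(peaks$chrom), layout$chrom_names)
  if (length(unk)) stop("peaks on unknown chromosome(s): ",
                        paste(unk, collapse = ", "))
  profile <- lapply(layout$chrom_names, function(ch) {
    len <- layout$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    ends <- pmin(starts + window_size, len)
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    mids <- sort(floor((p$start + p$end) / 2))
    count <- findInterval(ends - 0.5, mids) - findInterval(starts - 0.5, mids)
    data.frame(start = starts, end = ends, count = as.integer(count))
  })
  names(profile) <- layout$chrom_names
  structure(list(windows = profile, window_size = window_size, step = step,
                 layout = layout),
            class = "RollingDensityProfile")
}

#' @export
print.RollingDensityProfile <- function(x, ...) {
  n <- sum(vapply(x$windows, nrow, 1L))
  cat(sprintf("RollingDensityProfile: %d windows (%g bp / step %g bp), %d chromosome(s)\n",
              n, x$window_size, x$step, length(x$windows)))
  invisible(x)
}

all_counts <- function(profile) {
  unlist(lapply(profile$windows, function(w) w$count), use.names = FALSE)
}

#' Knee-point density threshold
#'
#' Pools window counts genome-wide, sorts the distinct count values in
#' decreasing order to form a count-vs-rank curve, and returns the count at
#' the point of maximum perpendicular distance to the chord joining the
#' curve's endpoints. Ties on distance break toward the smaller rank (the
#' larger, more stringent count). With `values = "all"` the curve keeps one
#' point per window instead of one per distinct value.
#'
#' A constant profile has no knee and raises an error; callers may then
#' force a manual threshold in [stitch_dense_regions()].
#'
#' @param profile a [rolling_peak_counts()] result.
#' @param values `"distinct"` (default) or `"all"`: whether the rank curve
#'   has one point per distinct count value or one per window.
#' @return integer threshold (a count value present in the profile).
#' @export
inflection_threshold <- function(profile, values = c("distinct", "all")) {
  values <- match.arg(values)
  counts <- all_counts(profile)
  if (length(unique(counts)) < 2L)
    stop("degenerate density profile: all window counts are equal (",
         counts[1L], "); supply a manual threshold")
  y <- if (values == "distinct") sort(unique(counts), decreasing = TRUE)
       else sort(counts, decreasing = TRUE)
  x <- seq_along(y)
  d <- chord_distances(x, y)
  idx <- which(d == max(d))[1L]   # tie -> smaller rank -> larger count
  as.integer(y[idx])
}

# Perpendicular distances from curve points to the chord through the curve's
# endpoints (raw coordinates).
chord_distances <- function(x, y) {
  n <- length(x)
  x1 <- x[1L]; y1 <- y[1L]; x2 <- x[n]; y2 <- y[n]
  abs((y1 - y2) * x + (x2 - x1) * y + x1 * y2 - x2 * y1) /
    sqrt((y1 - y2)^2 + (x2 - x1)^2)
}

#' Stitch above-threshold windows into dense regions
#'
#' Windows with count strictly greater than `threshold` are expanded to
#' their full (clipped) extent; overlapping or book-ended extents are merged
#' into maximal regions. Per-region statistics summarise the selected
#' windows a region absorbed.
#'
#' @param profile a [rolling_peak_counts()] result.
#' @param threshold integer count; regions consist of windows with
#'   `count > threshold` (strict, "beyond" the threshold).
#' @param merge_gap merge regions separated by at most this many bp
#'   (default 0: only touching/overlapping extents merge).
#' @return a `DenseRegionSet`: list with `regions` (data.frame `chrom`,
#'   `start`, `end`, `name`, `score` = max window count, `n_windows`,
#'   `max_count`, `mean_count`), `threshold`, `window_size`, `step`.
#' @export
stitch_dense_regions <- function(profile, threshold, merge_gap = 0) {
  if (threshold < 0) stop("threshold must be >= 0")
  sel <- lapply(names(profile$windows), function(ch) {
    w <- profile$windows[[ch]]
    w <- w[w$count > threshold, , drop = FALSE]
    if (nrow(w)) cbind(chrom = ch, w) else NULL
  })
  sel <- do.call(rbind, sel)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      n_windows = integer(), max_count = integer(),
                      mean_count = numeric())
  if (is.null(sel) || nrow(sel) == 0L)
    return(structure(list(regions = empty, threshold = threshold,
                          window_size = profile$window_size,
                          step = profile$step),
                     class = "DenseRegionSet"))
  gr <- GenomicRanges::GRanges(sel$chrom,
                               IRanges::IRanges(sel$start + 1, sel$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  cnt <- sel$count
  idx <- S4Vectors::subjectHits(hits)
  stats_n <- as.integer(table(factor(idx, levels = seq_along(merged))))
  stats_max <- vapply(seq_along(merged), function(i)
    max(cnt[S4Vectors::queryHits(hits)[idx == i]]), 1L)
  stats_mean <- vapply(seq_along(merged), function(i)
    mean(cnt[S4Vectors::queryHits(hits)[idx == i]]), 1)
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = GenomicRanges::end(merged),
    name = sprintf("dense_%d", seq_along(merged)),
    score = as.numeric(stats_max),
    n_windows = stats_n, max_count = as.integer(stats_max),
    mean_count = stats_mean)
  ord <- order(match(regions$chrom, profile$layout$chrom_names),
               regions$start)
  regions <- regions[ord, , drop = FALSE]
  regions$name <- sprintf("dense_%d", seq_len(nrow(regions)))
  rownames(regions) <- NULL
  structure(list(regions = regions, threshold = threshold,
                 window_size = profile$window_size, step = profile$step),
            class = "DenseRegionSet")
}

#' @export
print.DenseRegionSet <- function(x, ...) {
  cat(sprintf("DenseRegionSet: %d region(s) above count threshold %d\n",
              nrow(x$regions), x$threshold))
  invisible(x)
}

#' Call dense regions from a peak set in one step
#'
#' Convenience wrapper: [rolling_peak_counts()], [inflection_threshold()],
#' [stitch_dense_regions()].
#'
#' @inheritParams rolling_peak_counts
#' @inheritParams stitch_dense_regions
#' @param threshold optional manual threshold; when `NULL` the knee threshold
#'   is computed.
#' @return a `DenseRegionSet`.
#' @export
call_dense_regions <- function(peaks, layout, window_size = 100000,
                               step = 5000, threshold = NULL, merge_gap = 0) {
  profile <- rolling_peak_counts(peaks, layout, window_size, step)
  if (is.null(threshold)) threshold <- inflection_threshold(profile)
  stitch_dense_regions(profile, threshold, merge_gap = merge_gap)
}

#' Jaccard overlap between two interval sets
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`).
#' @param restrict_to_overlapping if `TRUE`, intervals of `a` that do not
#'   touch `b` are ignored, so the score measures how well `b` is recovered
#'   by the regions that hit it.
#' @return intersection width / union width (0 when both are empty-width).
#' @export
interval_jaccard <- function(a, b, restrict_to_overlapping = FALSE) {
  to_gr <- function(x) {
    if (is.null(x) || nrow(x) == 0L)
      return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1, x$end)))
  }
  ga <- to_gr(a); gb <- to_gr(b)
  if (restrict_to_overlapping && length(ga))
    ga <- ga[IRanges::overlapsAny(ga, gb)]
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) return(0)
  inter / uni
}
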