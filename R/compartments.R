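# A/B compartment scoring from binned contact matrices: coverage masking,
# iterative correction (ICE), distance normalisation (observed/expected),
# and the first principal component of the O/E correlation matrix, sign-
# oriented against a reference track of "A-ness".

#' Construct a contact matrix with a coverage mask
#'
#' @param chrom chromosome id.
#' @param M symmetric non-negative numeric matrix of binned contact counts.
#' @param bin_size bin width in bp.
#' @param mask optional logical vector of bins to exclude; when `NULL`,
#'   bins whose marginal is zero or below `mask_quantile` of the positive
#'   marginals are masked.
#' @param mask_quantile coverage quantile for the default mask (default 2%).
#' @return list of class `ContactMatrix` (`chrom`, `matrix`, `mask`,
#'   `bin_size`).
#' @export
contact_matrix <- function(chrom, M, bin_size, mask = NULL,
                           mask_quantile = 0.02) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("contact matrix must be square")
  if (any(M < 0)) stop("contact counts must be non-negative")
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(M)))
    stop("contact matrix must be symmetric")
  M <- (M + t(M)) / 2
  if (is.null(mask)) {
    marg <- rowSums(M)
    pos <- marg[marg > 0]
    if (length(pos) == 0L) {
      mask <- rep(TRUE, nrow(M))
    } else {
      thr <- stats::quantile(pos, mask_quantile)
      mask <- marg == 0 | marg < thr
    }
  }
  stopifnot(length(mask) == nrow(M))
  structure(list(chrom = chrom, matrix = M, mask = as.logical(mask),
                 bin_size = bin_size),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s: %d x %d bins (%g bp), %d masked\n",
              x$chrom, nrow(x$matrix), ncol(x$matrix), x$bin_size,
              sum(x$mask)))
  invisible(x)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Repeatedly divides rows and columns by their marginal sums until all
#' unmasked marginals agree with their mean to within `tol` (maximum
#' relative deviation, which also bounds the coefficient of variation).
#' Returns the balanced matrix and the per-bin bias vector such that
#' `M[i, j] ~ bias[i] * bias[j] * B[i, j]`.
#'
#' @param cm a [contact_matrix()].
#' @param tol convergence tolerance on the relative spread of the unmasked
#'   row sums (default 1e-5).
#' @param max_iter iteration cap (default 200); on non-convergence the
#'   partial result is returned with `converged = FALSE` and a warning.
#' @return list of class `BalancedMatrix`: `chrom`, `matrix` (balanced, `NA`
#'   on masked rows/columns), `bias` (`NA` on masked bins), `mask`,
#'   `converged`, `n_iter`, `bin_size`.
#' @export
ice_balance <- function(cm, tol = 1e-5, max_iter = 200L) {
  mask <- cm$mask
  keep <- which(!mask)
  if (length(keep) == 0L) stop("all bins are masked; nothing to balance")
  W <- cm$matrix[keep, keep, drop = FALSE]
  bias_sub <- rep(1, length(keep))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- rowSums(W)
    if (any(s == 0))
      stop("unmasked bin with zero marginal during balancing; widen the mask")
    m <- mean(s)
    if (max(abs(s / m - 1)) < tol) { converged <- TRUE; break }
    f <- s / m
    bias_sub <- bias_sub * f
    W <- W / outer(f, f)
  }
  if (!converged) {
    s <- rowSums(W)
    converged <- max(abs(s / mean(s) - 1)) < tol
    if (!converged)
      warning("ICE did not converge in ", max_iter,
              " iterations; returning the partial result")
  }
  n <- nrow(cm$matrix)
  B <- matrix(NA_real_, n, n)
  B[keep, keep] <- W
  bias <- rep(NA_real_, n)
  bias[keep] <- bias_sub
  structure(list(chrom = cm$chrom, matrix = B, bias = bias, mask = mask,
                 converged = converged, n_iter = iter,
                 bin_size = cm$bin_size),
            class = "BalancedMatrix")
}

#' Distance correction: observed / expected
#'
#' The expected value at separation `d` is the mean of the balanced matrix
#' over all unmasked pairs at that separation; each entry is divided by the
#' expected value of its diagonal. Diagonals with zero or undefined expected
#' value become `NA`.
#'
#' @param bm a [ice_balance()] result (or any list with `matrix` and `mask`).
#' @return matrix of observed/expected ratios (`NA` on masked bins and
#'   undefined diagonals), with the expected-by-distance profile in
#'   attribute `expected`.
#' @export
distance_correct <- function(bm) {
  B <- bm$matrix
  n <- nrow(B)
  keep <- which(!bm$mask)
  expected <- rep(NA_real_, n)
  sub <- B[keep, keep, drop = FALSE]
  d_sub <- abs(outer(keep, keep, "-"))
  for (d in 0:(n - 1L)) {
    v <- sub[d_sub == d]
    if (length(v)) expected[d + 1L] <- mean(v)
  }
  d_idx <- abs(row(B) - col(B))
  exp_mat <- matrix(expected[d_idx + 1L], n, n)
  OE <- matrix(NA_real_, n, n)
  ok <- !is.na(B) & !is.na(exp_mat) & exp_mat > 0
  OE[ok] <- B[ok] / exp_mat[ok]
  attr(OE, "expected") <- expected
  OE
}

#' A/B compartment score from an observed/expected matrix
#'
#' Computes the Pearson correlation matrix of the O/E columns over unmasked
#' bins and takes the first principal component (leading eigenvector) as the
#' per-bin score; positive score means A by convention, enforced by flipping
#' the sign when the score correlates negatively with a reference track in
#' which larger values mean more A-like chromatin (gene density, active
#' marks, or 1 - AT fraction).
#'
#' @param OE an observed/expected matrix from [distance_correct()].
#' @param chrom chromosome id for the output track.
#' @param reference data.frame (`chrom`, `bin`, `value`) used only to orient
#'   the sign; `NULL` or unusable returns an unoriented score with
#'   attribute `oriented = FALSE` and a warning.
#' @param min_unmasked minimum number of scoreable bins (default 10).
#' @return data.frame (`chrom`, `bin`, `score`) over all bins (`NA` where
#'   masked), with attributes `explained_variance`, `oriented`, `reference`.
#' @export
compartment_score <- function(OE, chrom, reference = NULL,
                              min_unmasked = 10L) {
  n <- nrow(OE)
  keep <- which(apply(OE, 1L, function(r) any(is.finite(r))))
  if (length(keep) < min_unmasked)
    stop("fewer than ", min_unmasked,
         " unmasked bins; cannot score compartments")
  sub <- OE[keep, keep, drop = FALSE]
  C <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  v1 <- eg$vectors[, 1L]
  pos <- pmax(eg$values, 0)
  explained <- if (sum(pos) > 0) pos[1L] / sum(pos) else NA_real_

  oriented <- FALSE
  ref_name <- NA_character_
  if (!is.null(reference)) {
    ref_name <- attr(reference, "source")
    if (is.null(ref_name)) ref_name <- "reference"
    rv <- reference$value[match(paste(chrom, keep - 1L),
                                paste(reference$chrom, reference$bin))]
    ok <- is.finite(rv)
    if (sum(ok) >= 3L && stats::sd(rv[ok]) > 0 && stats::sd(v1[ok]) > 0) {
      r <- stats::cor(v1[ok], rv[ok])
      if (is.finite(r)) {
        if (r < 0) v1 <- -v1
        oriented <- TRUE
      }
    }
  }
  if (!oriented)
    warning("compartment score left unoriented (no usable reference track)")

  score <- rep(NA_real_, n)
  score[keep] <- v1
  out <- data.frame(chrom = chrom, bin = seq_len(n) - 1L, score = score)
  attr(out, "explained_variance") <- explained
  attr(out, "oriented") <- oriented
  attr(out, "reference") <- ref_name
  out
}

#' Full compartment pipeline for one contact matrix
#'
#' Mask, balance, distance-correct and score in one call.
#'
#' @param cm a [contact_matrix()].
#' @param reference orientation track (see [compartment_score()]).
#' @param tol,max_iter passed to [ice_balance()].
#' @return the [compartment_score()] track, with the balanced matrix in
#'   attribute `balanced`.
#' @export
compartment_track <- function(cm, reference = NULL, tol = 1e-5,
                              max_iter = 200L) {
  bm <- ice_balance(cm, tol = tol, max_iter = max_iter)
  OE <- distance_correct(bm)
  out <- compartment_score(OE, cm$chrom, reference = reference)
  attr(out, "balanced") <- bm
  out
}
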