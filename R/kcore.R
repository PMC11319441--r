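# k-core decomposition of differential interaction networks.
#
# A k-core is the maximal subgraph in which every node keeps at least k
# neighbours; a node's core number is the largest k for which it survives.
# The degeneracy core (the non-empty core with the largest k, "k-max") marks
# the most densely inter-connected set of bins gaining contacts.

#' Core numbers by bucket peeling
#'
#' Batagelj-Zaversnik O(V+E) algorithm on a simple undirected graph given as
#' an edge list over vertices `1..n`. Self-loops and duplicate edges are not
#' allowed. The result does not depend on any iteration order: it is the
#' standard core-number function.
#'
#' @param n number of vertices.
#' @param ei,ej integer endpoint vectors (1-based, `ei[k] != ej[k]`).
#' @return integer vector of length `n` with each vertex's core number.
#' @export
core_numbers <- function(n, ei, ej) {
  stopifnot(length(ei) == length(ej))
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  if (length(ei)) {
    ei <- as.integer(ei); ej <- as.integer(ej)
    if (any(ei == ej)) stop("self-loop in edge list")
    key <- paste(pmin(ei, ej), pmax(ei, ej))
    if (anyDuplicated(key)) stop("duplicate edge in edge list")
    if (min(ei, ej) < 1L || max(ei, ej) > n) stop("vertex index out of range")
  }
  deg <- tabulate(c(ei, ej), nbins = n)
  # adjacency as flat arrays
  adj_start <- cumsum(c(1L, deg))
  fill <- integer(n)
  adj <- integer(2L * length(ei))
  for (k in seq_along(ei)) {
    a <- ei[k]; b <- ej[k]
    adj[adj_start[a] + fill[a]] <- b; fill[a] <- fill[a] + 1L
    adj[adj_start[b] + fill[b]] <- a; fill[b] <- fill[b] + 1L
  }
  md <- max(deg, 0L)
  # vertices bucketed by current degree
  bin <- integer(md + 1L)                 # bin[d+1] = start of degree-d block
  cnt <- tabulate(deg + 1L, nbins = md + 1L)
  bin[1L] <- 1L
  if (md > 0L) for (d in seq_len(md)) bin[d + 1L] <- bin[d] + cnt[d]
  pos <- integer(n); vert <- integer(n)
  nxt <- bin
  for (v in seq_len(n)) {
    pos[v] <- nxt[deg[v] + 1L]
    vert[pos[v]] <- v
    nxt[deg[v] + 1L] <- nxt[deg[v] + 1L] + 1L
  }
  core <- deg
  for (i in seq_len(n)) {
    v <- vert[i]
    if (deg[v] > 0L) {
      nb <- adj[seq.int(adj_start[v], length.out = core_adj_len(adj_start, v))]
      for (u in nb) {
        if (deg[u] > deg[v]) {
          du <- deg[u]
          pu <- pos[u]
          pw <- bin[du + 1L]            # first slot of degree-du block
          w <- vert[pw]
          if (u != w) {                  # swap u to the block start
            vert[pu] <- w; vert[pw] <- u
            pos[u] <- pw; pos[w] <- pu
          }
          bin[du + 1L] <- bin[du + 1L] + 1L
          deg[u] <- du - 1L
        }
      }
    }
    core[v] <- deg[v]
  }
  core
}

core_adj_len <- function(adj_start, v) adj_start[v + 1L] - adj_start[v]

#' k-core decomposition of a differential network
#'
#' Runs the decomposition on the unweighted simple graph of edges carrying
#' the requested sign (the increased-interaction subgraph by default, the
#' side on which dense gained-contact clusters live). Nodes of the network
#' without any edge of that sign get core number 0.
#'
#' @param net a `DiffNetwork` (see [build_networks()]).
#' @param edge_sign `"increased"`, `"decreased"` or `"all"`.
#' @return a `CoreDecomposition`: list with `chrom`, `core_number` (named by
#'   bin index), `k_max`, `degeneracy_core` (bin indices with
#'   `core == k_max`), `tier` (named factor low/medium/high) and `edge_sign`.
#' @export
kcore_decompose <- function(net, edge_sign = c("increased", "decreased",
                                               "all")) {
  edge_sign <- match.arg(edge_sign)
  g <- net$graph
  bins <- igraph::V(g)$name
  nv <- length(bins)
  if (nv == 0L) {
    return(structure(list(chrom = net$chrom,
                          core_number = stats::setNames(integer(0),
                                                        character(0)),
                          k_max = 0L, degeneracy_core = integer(0),
                          tier = factor(character(0),
                                        levels = c("low", "medium", "high")),
                          edge_sign = edge_sign),
                     class = "CoreDecomposition"))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  if (edge_sign != "all") {
    keep <- igraph::E(g)$sign == edge_sign
    el <- el[keep, , drop = FALSE]
  }
  core <- core_numbers(nv, el[, 1L], el[, 2L])
  names(core) <- bins
  k_max <- max(core, 0L)
  structure(list(chrom = net$chrom, core_number = core,
                 k_max = as.integer(k_max),
                 degeneracy_core = as.integer(bins[core == k_max]),
                 tier = tier_of(core), edge_sign = edge_sign),
            class = "CoreDecomposition")
}

#' @export
print.CoreDecomposition <- function(x, ...) {
  cat(sprintf("CoreDecomposition (%s, %s edges): %d node(s), k-max %d, degeneracy core of %d bin(s)\n",
              x$chrom, x$edge_sign, length(x$core_number), x$k_max,
              length(x$degeneracy_core)))
  invisible(x)
}

#' Map core numbers to connectivity tiers
#'
#' Low (< 3), medium (3-5, inclusive) and high (> 5) connectivity tiers;
#' high starts at 6, consistent with the Core class cutoff of the
#' classifier.
#'
#' @param k non-negative core numbers.
#' @return factor with levels low/medium/high, named like `k`.
#' @export
tier_of <- function(k) {
  if (any(k < 0)) stop("core numbers must be non-negative")
  out <- factor(ifelse(k < 3, "low", ifelse(k <= 5, "medium", "high")),
                levels = c("low", "medium", "high"))
  names(out) <- names(k)
  out
}

#' Per-chromosome k-max table
#'
#' @param decompositions list of [kcore_decompose()] results.
#' @param nets optional matching list of networks, used to report node and
#'   edge counts.
#' @return data.frame (`chrom`, `k_max`, `n_nodes`, `n_edges`), one row per
#'   chromosome, in input order.
#' @export
kmax_by_chromosome <- function(decompositions, nets = NULL) {
  if (length(decompositions) == 0L)
    return(data.frame(chrom = character(), k_max = integer(),
                      n_nodes = integer(), n_edges = integer()))
  rows <- lapply(seq_along(decompositions), function(i) {
    d <- decompositions[[i]]
    ne <- if (!is.null(nets)) igraph::ecount(nets[[i]]$graph) else NA_integer_
    data.frame(chrom = d$chrom, k_max = d$k_max,
               n_nodes = length(d$core_number), n_edges = ne)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Core decomposition as a per-bin table
#'
#' @param decomp a [kcore_decompose()] result.
#' @param layout a [genome_layout()].
#' @return data.frame (`chrom`, `bin_start`, `bin_end`, `bin`,
#'   `core_number`, `tier`, `in_degeneracy_core`).
#' @export
core_table <- function(decomp, layout) {
  bins <- as.integer(names(decomp$core_number))
  ord <- order(bins)
  bins <- bins[ord]
  data.frame(chrom = decomp$chrom,
             bin_start = bin_start(layout, decomp$chrom, bins),
             bin_end = bin_end(layout, decomp$chrom, bins),
             bin = bins,
             core_number = as.integer(decomp$core_number[ord]),
             tier = as.character(decomp$tier[ord]),
             in_degeneracy_core = as.integer(bins %in% decomp$degeneracy_core))
}
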