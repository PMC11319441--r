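# Five-way classification of network bins from the signed differential
# network and its k-core decomposition:
#   Core    — bins in high-k cores of the increased subgraph,
#   AltCore — smaller dense clusters detached from Core,
#   Peri    — bins with increased interactions onto Core,
#   ExCore  — bins pushed away from Core/AltCore by decreased interactions,
#   Other   — remaining network bins.
# Bins absent from the network are Background, a separate non-network label.

CLASS_LEVELS <- c("Core", "Peri", "AltCore", "ExCore", "Other")

#' Classifier parameters
#'
#' @param core_min_k minimum core number for Core (default 6).
#' @param altcore_min_k minimum core number for AltCore candidates
#'   (default 4); must be below `core_min_k` and at least 1.
#' @param peri_min_edges minimum increased edges to a Core bin for Peri
#'   (default 1).
#' @param excore_min_edges minimum decreased edges to a Core or AltCore bin
#'   for ExCore (default 1).
#' @param altcore_attach_min_edges an AltCore candidate cluster with at
#'   least this many increased edges onto Core counts as attached and its
#'   members fall through to Peri/ExCore/Other; defaults to `altcore_min_k`,
#'   so attachment needs as much evidence as cluster membership itself and a
#'   single spurious edge cannot dissolve a detached cluster.
#' @return list of class `ClassifierParams`.
#' @export
classifier_params <- function(core_min_k = 6L, altcore_min_k = 4L,
                              peri_min_edges = 1L, excore_min_edges = 1L,
                              altcore_attach_min_edges = altcore_min_k) {
  if (!(core_min_k > altcore_min_k && altcore_min_k >= 1L))
    stop("need core_min_k > altcore_min_k >= 1")
  if (peri_min_edges < 1L || excore_min_edges < 1L ||
      altcore_attach_min_edges < 1L)
    stop("edge-count parameters must be >= 1")
  structure(list(core_min_k = as.integer(core_min_k),
                 altcore_min_k = as.integer(altcore_min_k),
                 peri_min_edges = as.integer(peri_min_edges),
                 excore_min_edges = as.integer(excore_min_edges),
                 altcore_attach_min_edges =
                   as.integer(altcore_attach_min_edges)),
            class = "ClassifierParams")
}

#' Classify network bins into Core/Peri/AltCore/ExCore/Other
#'
#' Labels are assigned with strict precedence:
#' \enumerate{
#'   \item Core: `core_number >= core_min_k` in the increased subgraph.
#'   \item AltCore: candidate bins (`core_number >= altcore_min_k`, not
#'     Core) are grouped into clusters (connected components of the
#'     increased subgraph induced on the candidates); a cluster is AltCore
#'     unless it has at least `altcore_attach_min_edges` increased edges
#'     onto Core bins ("attached"), in which case its members fall through.
#'     Decreased edges never attach a cluster, only exclude
#'     (the "independent or detached" reading).
#'   \item Peri: remaining bins with at least `peri_min_edges` increased
#'     edges to a Core bin.
#'   \item ExCore: remaining bins with at least `excore_min_edges` decreased
#'     edges to a Core or AltCore bin.
#'   \item Other: all remaining network bins.
#' }
#'
#' @param net a `DiffNetwork`.
#' @param cores the [kcore_decompose()] of `net`'s increased subgraph.
#' @param params a [classifier_params()].
#' @return data.frame (`chrom`, `bin`, `label`, `core_number`), one row per
#'   network node, `label` a factor over the five classes.
#' @export
classify_bins <- function(net, cores, params = classifier_params()) {
  if (!identical(net$chrom, cores$chrom))
    stop("network (", net$chrom, ") and decomposition (", cores$chrom,
         ") chromosomes differ")
  g <- net$graph
  bins <- igraph::V(g)$name
  if (!setequal(bins, names(cores$core_number)))
    stop("decomposition does not cover the network's nodes")
  core_num <- cores$core_number[bins]
  n <- length(bins)
  if (n == 0L)
    return(data.frame(chrom = character(), bin = integer(),
                      label = factor(character(), levels = CLASS_LEVELS),
                      core_number = integer()))

  g_inc <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$sign == "increased"], delete.vertices = FALSE)
  g_dec <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$sign == "decreased"], delete.vertices = FALSE)

  label <- rep(NA_character_, n)
  names(label) <- bins

  is_core <- core_num >= params$core_min_k
  label[is_core] <- "Core"
  core_bins <- bins[is_core]

  # AltCore: detached candidate clusters
  cand <- bins[!is_core & core_num >= params$altcore_min_k]
  if (length(cand)) {
    sub <- igraph::induced_subgraph(g_inc, cand)
    comp <- igraph::components(sub)
    memb <- comp$membership[cand]
    for (cl in seq_len(comp$no)) {
      members <- cand[memb == cl]
      # increased edges from the cluster onto Core
      attach_edges <- 0L
      if (length(core_bins)) {
        nbrs <- igraph::adjacent_vertices(g_inc, members)
        attach_edges <- sum(vapply(nbrs, function(vs)
          sum(names(vs) %in% core_bins), 1L))
      }
      if (attach_edges < params$altcore_attach_min_edges)
        label[members] <- "AltCore"
    }
  }
  altcore_bins <- bins[!is.na(label) & label == "AltCore"]

  # Peri: increased edges onto Core
  rest <- bins[is.na(label)]
  if (length(rest) && length(core_bins)) {
    nbrs <- igraph::adjacent_vertices(g_inc, rest)
    n_to_core <- vapply(nbrs, function(vs) sum(names(vs) %in% core_bins), 1L)
    label[rest[n_to_core >= params$peri_min_edges]] <- "Peri"
  }

  # ExCore: decreased edges onto Core or AltCore
  rest <- bins[is.na(label)]
  targets <- c(core_bins, altcore_bins)
  if (length(rest) && length(targets)) {
    nbrs <- igraph::adjacent_vertices(g_dec, rest)
    n_to_t <- vapply(nbrs, function(vs) sum(names(vs) %in% targets), 1L)
    label[rest[n_to_t >= params$excore_min_edges]] <- "ExCore"
  }

  label[is.na(label)] <- "Other"
  out <- data.frame(chrom = net$chrom, bin = as.integer(bins),
                    label = factor(label, levels = CLASS_LEVELS),
                    core_number = as.integer(core_num))
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide class labels from per-chromosome networks
#'
#' @param nets list of `DiffNetwork` from [build_networks()].
#' @param decomps matching list from [kcore_decompose()].
#' @param params a [classifier_params()].
#' @return row-bound [classify_bins()] tables.
#' @export
classify_all <- function(nets, decomps, params = classifier_params()) {
  out <- do.call(rbind, Map(classify_bins, nets, decomps,
                            MoreArgs = list(params = params)))
  rownames(out) <- NULL
  out
}

#' Class-size summary
#'
#' One row per class plus a Background row for genome bins absent from the
#' differential network; fractions are over the five network classes and
#' sum to 1.
#'
#' @param labels a [classify_bins()]/[classify_all()] table.
#' @param layout a [genome_layout()].
#' @return data.frame (`label`, `n_bins`, `mb_covered`,
#'   `fraction_of_network`).
#' @export
class_summary <- function(labels, layout) {
  grid <- layout_bins(layout)
  widths <- grid$end - grid$start
  key_all <- paste(grid$chrom, grid$bin)
  key_lab <- paste(labels$chrom, labels$bin)
  n_net <- nrow(labels)
  rows <- lapply(CLASS_LEVELS, function(lv) {
    sel <- labels$label == lv
    mb <- sum(widths[match(key_lab[sel], key_all)]) / 1e6
    data.frame(label = lv, n_bins = sum(sel), mb_covered = mb,
               fraction_of_network = if (n_net > 0) sum(sel) / n_net else 0)
  })
  bg <- !(key_all %in% key_lab)
  rows <- c(rows, list(data.frame(label = "Background", n_bins = sum(bg),
                                  mb_covered = sum(widths[bg]) / 1e6,
                                  fraction_of_network = NA_real_)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Class labels as a BED table
#'
#' @param labels a label table.
#' @param layout a [genome_layout()].
#' @return data.frame ready for [write_intervals()] (name = label,
#'   score = core number).
#' @export
labels_bed <- function(labels, layout) {
  ord <- order(match(labels$chrom, layout$chrom_names), labels$bin)
  x <- labels[ord, , drop = FALSE]
  data.frame(chrom = x$chrom,
             start = mapply(function(ch, b) bin_start(layout, ch, b),
                            x$chrom, x$bin),
             end = mapply(function(ch, b) bin_end(layout, ch, b),
                          x$chrom, x$bin),
             name = as.character(x$label), score = x$core_number)
}
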