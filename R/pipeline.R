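# End-to-end orchestration: config (YAML or list) -> validated inputs ->
# stages in dependency order -> output directory with a reproducibility
# manifest. Re-running with an identical config and inputs reproduces
# byte-identical primary outputs (labels BED, core TSV, dense-regions BED,
# compartment bedGraph, report TSVs); only the manifest's timings differ.

#' Default pipeline configuration
#'
#' Every default equals the corresponding module-level default.
#'
#' @return nested list; see [run_pipeline()] for the fields.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = NULL,
    bin_size = 200000L,
    seed = 1L,
    simulate = NULL,
    inputs = list(chrom_sizes = NULL, peaks = NULL, diffnet = list(),
                  contacts = list(), genes = NULL, reference = NULL),
    dense = list(window_size = 100000, step = 5000, merge_gap = 0,
                 threshold = NULL),
    interactions = list(fdr_max = 0.05, min_abs_logfc = 0,
                        distal_threshold = 2e6, min_peaks = 5L),
    classifier = list(core_min_k = 6L, altcore_min_k = 4L,
                      peri_min_edges = 1L, excore_min_edges = 1L),
    compartments = list(tol = 1e-5, max_iter = 200L, mask_quantile = 0.02))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: io, dense_regions, diffnet, kcore,
#' classifier, compartments, integrate. In simulate mode
#' (`config$simulate` a list of [synthetic_spec()] overrides, or `TRUE`
#' for the defaults) the synthetic inputs are first written under
#' `<out_dir>/inputs` and then consumed through the same readers as user
#' data. All inputs are validated before any stage runs; a stage failure
#' keeps the outputs produced so far and marks the failed stage in the
#' manifest before re-raising the error.
#'
#' @param config a YAML file path or a nested list; unset keys take the
#'   [default_pipeline_config()] values. `inputs$diffnet` is a named list
#'   (contrast -> path), `inputs$contacts` a named list (chromosome ->
#'   path), `inputs$reference` an optional bedGraph used to orient
#'   compartment scores.
#' @return invisibly, a list with the effective `config`, the `manifest`
#'   (also written as `manifest.json`) and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- simulate mode: generate inputs first --------------------------------
  if (!is.null(config$simulate) && !identical(config$simulate, FALSE)) {
    overrides <- if (isTRUE(config$simulate)) list() else config$simulate
    spec <- do.call(synthetic_spec,
                    utils::modifyList(list(seed = config$seed,
                                           bin_size = config$bin_size),
                                      overrides))
    sim_paths <- write_synthetic(spec, file.path(out_dir, "inputs"))
    config$inputs$chrom_sizes <- sim_paths$chrom_sizes
    config$inputs$peaks <- sim_paths$peaks
    config$inputs$genes <- sim_paths$genes
    config$inputs$diffnet <- stats::setNames(
      lapply(spec$contrasts, function(co)
        sim_paths[[paste0("diffnet_", co)]]), spec$contrasts)
    config$inputs$contacts <- stats::setNames(
      lapply(spec$chrom_names, function(ch)
        sim_paths[[paste0("contacts_", ch)]]), spec$chrom_names)
    if (is.null(config$inputs$reference))
      config$inputs$reference <- sim_paths$truth_compartments
  }

  # --- validation before any stage -----------------------------------------
  inp <- config$inputs
  required <- c(chrom_sizes = inp$chrom_sizes, peaks = inp$peaks,
                unlist(inp$diffnet))
  if (is.null(inp$chrom_sizes) || is.null(inp$peaks) ||
      length(inp$diffnet) == 0L)
    stop("config$inputs must provide chrom_sizes, peaks and at least one ",
         "diffnet table")
  all_paths <- c(required, unlist(inp$contacts), inp$genes, inp$reference)
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  # --- stage machinery ------------------------------------------------------
  events_path <- file.path(out_dir, "events.jsonl")
  unlink(events_path)
  timings <- list()
  failed <- NULL
  run_stage <- function(name, fun) {
    message("[", name, "] start")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      failed <<- list(stage = name, error = conditionMessage(e))
      e
    })
    secs <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- secs
    status <- if (inherits(res, "error")) "failed" else "ok"
    cat(jsonlite::toJSON(list(stage = name, status = status,
                              seconds = round(secs, 3)),
                         auto_unbox = TRUE), "\n",
        file = events_path, append = TRUE)
    message("[", name, "] ", status, " (", round(secs, 2), " s)")
    if (inherits(res, "error")) {
      write_manifest()
      stop(res)
    }
    res
  }

  paths <- list(
    dense_regions = file.path(out_dir, "dense_regions.bed"),
    dense_stats = file.path(out_dir, "dense_region_stats.tsv"),
    core = file.path(out_dir, "core.tsv"),
    kmax = file.path(out_dir, "kmax.tsv"),
    labels = file.path(out_dir, "labels.bed"),
    class_summary = file.path(out_dir, "class_summary.tsv"),
    compartments = file.path(out_dir, "compartments.bedgraph"),
    edge_categories = file.path(out_dir, "edge_categories.tsv"),
    kmax_features = file.path(out_dir, "kmax_features.tsv"),
    manifest = file.path(out_dir, "manifest.json"))

  write_manifest <- function() {
    checksum <- function(p) {
      v <- unlist(p, use.names = FALSE)
      v <- v[file.exists(v)]
      if (length(v) == 0L) return(stats::setNames(list(), character(0)))
      as.list(tools::md5sum(v))
    }
    manifest <- list(
      tool = "chromcore",
      version = as.character(utils::packageVersion("chromcore")),
      seed = config$seed,
      parameters = config[setdiff(names(config), "inputs")],
      inputs = checksum(all_paths),
      outputs = checksum(paths[names(paths) != "manifest"]),
      stage_seconds = lapply(timings, function(s) round(s, 3)),
      failed_stage = failed)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    manifest
  }

  # --- stages ---------------------------------------------------------------
  st <- new.env(parent = emptyenv())

  run_stage("io", function() {
    st$layout <- read_chrom_sizes(inp$chrom_sizes,
                                  bin_size = config$bin_size)
    st$peaks <- read_intervals(inp$peaks, st$layout)
    st$diff <- lapply(inp$diffnet, function(p)
      read_diff_interactions(p, st$layout,
                             fdr_max = config$interactions$fdr_max,
                             min_abs_logfc =
                               config$interactions$min_abs_logfc))
    st$contacts <- lapply(names(inp$contacts), function(ch)
      read_contacts(inp$contacts[[ch]], st$layout, ch,
                    mask_quantile = config$compartments$mask_quantile))
    names(st$contacts) <- names(inp$contacts)
    st$genes <- if (!is.null(inp$genes)) read_genes(inp$genes, st$layout)
    st$reference <- if (!is.null(inp$reference))
      bin_signal(inp$reference, st$layout)
    invisible(NULL)
  })

  run_stage("dense_regions", function() {
    dr <- call_dense_regions(st$peaks, st$layout,
                             window_size = config$dense$window_size,
                             step = config$dense$step,
                             threshold = config$dense$threshold,
                             merge_gap = config$dense$merge_gap)
    st$dense <- dr
    write_intervals(dr$regions, paths$dense_regions)
    stats <- dr$regions[, c("chrom", "start", "end", "name", "n_windows",
                            "max_count", "mean_count")]
    stats$width <- stats$end - stats$start
    stats$threshold <- dr$threshold
    write_tsv_report(stats, paths$dense_stats)
    invisible(NULL)
  })

  run_stage("diffnet", function() {
    st$nets <- lapply(st$diff, build_networks)
    st$bound <- hmga1_bound_bins(st$peaks, st$layout,
                                 min_peaks = config$interactions$min_peaks)
    invisible(NULL)
  })

  run_stage("kcore", function() {
    nets1 <- st$nets[[1L]]
    st$decomps <- lapply(nets1, kcore_decompose)
    core <- do.call(rbind, lapply(st$decomps, core_table,
                                  layout = st$layout))
    rownames(core) <- NULL
    write_tsv_report(core, paths$core)
    write_tsv_report(kmax_by_chromosome(st$decomps, nets1), paths$kmax)
    invisible(NULL)
  })

  run_stage("classifier", function() {
    params <- do.call(classifier_params, config$classifier)
    st$labels <- classify_all(st$nets[[1L]], st$decomps, params)
    write_intervals(labels_bed(st$labels, st$layout), paths$labels)
    write_tsv_report(class_summary(st$labels, st$layout),
                     paths$class_summary)
    invisible(NULL)
  })

  run_stage("compartments", function() {
    tracks <- lapply(st$contacts, function(cm)
      compartment_track(cm, reference = st$reference,
                        tol = config$compartments$tol,
                        max_iter = config$compartments$max_iter))
    st$compartments <- do.call(rbind, lapply(tracks, function(tr)
      data.frame(chrom = tr$chrom, bin = tr$bin, value = tr$score)))
    rownames(st$compartments) <- NULL
    write_bedgraph(st$compartments, st$layout, paths$compartments)
    invisible(NULL)
  })

  run_stage("integrate", function() {
    comp_track <- if (!is.null(st$compartments))
      data.frame(chrom = st$compartments$chrom, bin = st$compartments$bin,
                 score = st$compartments$value)
    # edge cross-tabulation on the first contrast's networks
    cats <- do.call(rbind, lapply(st$nets[[1L]], function(net) {
      tab <- categorize_edges(
        net, comp_track, st$bound, st$layout,
        distal_threshold = config$interactions$distal_threshold)
      if (nrow(tab)) cbind(chrom = net$chrom, tab) else NULL
    }))
    if (is.null(cats))
      cats <- data.frame(chrom = character(), compartment_pair = character(),
                         range_class = character(),
                         n_bound_anchors = integer(), sign = character(),
                         n = integer(), median_logFC = numeric(),
                         q25 = numeric(), q75 = numeric())
    rownames(cats) <- NULL
    write_tsv_report(cats, paths$edge_categories)

    # class-pair interaction summaries per contrast (contrast-1 labels)
    for (co in names(st$nets)) {
      tab <- interactions_by_class_pair_all(st$nets[[co]], st$labels)
      p <- file.path(out_dir,
                     paste0("interactions_by_class_pair_", co, ".tsv"))
      write_tsv_report(tab, p)
      paths[[paste0("interactions_", co)]] <<- p
    }

    # per-class expression summaries
    if (!is.null(st$genes)) {
      joined <- genes_by_class(st$genes, st$labels, st$layout)
      for (co in attr(st$genes, "contrasts")) {
        p <- file.path(out_dir, paste0("expression_by_class_", co, ".tsv"))
        write_tsv_report(class_expression_summary(joined, co), p)
        paths[[paste0("expression_", co)]] <<- p
      }
    }

    # k-max vs per-chromosome peak features
    kmax <- kmax_by_chromosome(st$decomps, st$nets[[1L]])
    feats <- data.frame(chrom = st$layout$chrom_names)
    feats$n_peaks <- vapply(feats$chrom, function(ch)
      sum(st$peaks$chrom == ch), 1L)
    dr <- st$dense$regions
    feats$dense_bp <- vapply(feats$chrom, function(ch)
      sum(dr$end[dr$chrom == ch] - dr$start[dr$chrom == ch]), 1)
    rep_tab <- if (nrow(kmax) >= 3L) kmax_feature_report(kmax, feats) else
      data.frame(feature = character(), pearson = numeric(),
                 spearman = numeric(), n = integer())
    write_tsv_report(rep_tab, paths$kmax_features)
    invisible(NULL)
  })

  manifest <- write_manifest()
  invisible(list(config = config, manifest = manifest, paths = paths))
}
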