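# End-to-end pipeline: simulate (or load) -> sample QC -> CNVR
# construction -> cross-population comparison -> CNV matrices ->
# PCA / UPGMA+bootstrap -> V_ST scan -> annotation.
#
# Every stage writes its outputs under the run directory and the run
# manifest records inputs, parameters and the seed; a rerun with the
# same config and seed is byte-identical (no timestamps are written).

#' Read a pipeline configuration
#'
#' The YAML file has one section per stage (`simulate` or `inputs`,
#' `qc`, `matrix`, `tree`, `vst`, `annotate`) plus a top-level `seed`.
#' See `inst/extdata/demo_config.yaml` for a complete example.
#'
#' @param path YAML config path.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

# Paths in a config resolve against the working directory first; a
# path of the form "extdata/<file>" falls back to the installed
# package fixtures so the shipped demo config works from anywhere.
resolve_path <- function(path) {
  if (file.exists(path)) return(path)
  if (startsWith(path, "extdata/")) {
    cand <- system.file(path, package = "cnvpop")
    if (nzchar(cand)) return(cand)
  }
  stop("file not found: ", path)
}

config_templates <- function(tpl_list) {
  lapply(tpl_list, function(t) {
    cnv_template(t$chrom, t$start, t$end, t$tcn, unlist(t$freq))
  })
}

#' Run the full pipeline
#'
#' @param config A config list ([read_pipeline_config()]) or YAML path.
#' @param out_dir Output directory (created if absent).
#' @param seed Overrides the config seed when non-`NULL`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `qc`, `regions`, `summary`, `venn`, `matrix`, `pca`,
#'   `tree`, `vst`, `annotated`, `files`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name) {
    p <- file.path(out_dir, name)
    files[length(files) + 1L] <<- p
    p
  }

  # -- stage: simulate or load -----------------------------------------
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    cfg <- simulation_config(
      populations = unlist(sc$populations),
      n_chrom = sc$n_chrom %||% 2L,
      chrom_length_bp = sc$chrom_length_bp %||% 1e6,
      n_probes_per_chrom = sc$n_probes_per_chrom %||% 200L,
      templates = config_templates(sc$templates %||% list()),
      lrr_sd = sc$lrr_sd %||% 0.20,
      wave_amplitude = sc$wave_amplitude %||% 0,
      baf = isTRUE(sc$baf),
      call_rate_range = unlist(sc$call_rate_range %||% c(1, 1)),
      seed = seed
    )
    cohort <- generate_cohort(cfg)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (key in c("map", "signal", "calls", "manifest", "chrom_sizes")) {
      if (is.null(inp[[key]]))
        stop("config inputs block is missing required key '", key, "'")
    }
    map <- read_snp_map(resolve_path(inp$map))
    cohort <- list(
      map = map,
      lrr = read_signal_matrix(resolve_path(inp$signal), map),
      baf = NULL,
      truth_calls = read_cnv_calls(resolve_path(inp$calls)),
      manifest = read_population_manifest(resolve_path(inp$manifest)),
      chrom_sizes = read_chrom_sizes(resolve_path(inp$chrom_sizes))
    )
  } else stop("config must contain a 'simulate' or an 'inputs' block")
  calls <- cohort$truth_calls
  validate_cnv_calls(calls, chroms = cohort$chrom_sizes$chrom)

  # -- stage: sample QC -------------------------------------------------
  qcc <- config$qc %||% list()
  thr <- qc_thresholds(
    call_rate_min = qcc$call_rate_min %||% 0.98,
    dlrs_max = qcc$dlrs_max %||% NA,
    dlrs_nsd = qcc$dlrs_nsd %||% 3,
    wave_max = qcc$wave_max %||% 0.10,
    lrr_sd_max = qcc$lrr_sd_max %||% 0.30
  )
  qc <- apply_qc_filters(sample_qc_metrics(cohort$lrr, cohort$map), thr)
  write_qc_report(qc, emit("qc_report.tsv"))
  kept <- attr(qc, "kept")
  if (length(kept) < 2L) stop("fewer than 2 samples pass QC")
  message(sprintf("QC: kept %d of %d samples (%d excluded)",
                  length(kept), nrow(qc), nrow(qc) - length(kept)))
  lrr <- cohort$lrr[, kept, drop = FALSE]
  manifest <- cohort$manifest[cohort$manifest$sample_id %in% kept, ,
                              drop = FALSE]
  calls <- calls[calls$sample_id %in% kept, , drop = FALSE]

  # -- stage: CNVR construction ----------------------------------------
  regions <- merge_calls_to_regions(calls)
  write_regions_bed(regions, emit("cnvr.bed"))
  files <- c(files, file.path(out_dir, "cnvr.tsv"))
  summary <- summarize_regions(regions, cohort$chrom_sizes)
  utils::write.table(summary$by_state, emit("cnvr_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- stage: cross-population comparison ------------------------------
  pops <- unique(manifest$population)
  venn <- NULL
  if (length(pops) %in% 2:3) {
    per_pop <- lapply(stats::setNames(pops, pops), function(p) {
      merge_calls_to_regions(
        calls[calls$sample_id %in%
                manifest$sample_id[manifest$population == p], ,
              drop = FALSE])
    })
    venn <- venn_partition(per_pop)
    jsonlite::write_json(
      list(unique = as.list(venn$unique_counts),
           all_shared = as.list(venn$all_shared),
           pairwise = venn$pairwise),
      emit("venn_counts.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }

  # -- stage: CNV matrices ---------------------------------------------
  mc <- config$matrix %||% list()
  encoding <- mc$encoding %||% "copy_number"
  mat_full <- build_cnv_matrix(regions, calls, manifest, encoding)
  mat <- filter_min_carriers(mat_full, k = mc$min_carriers %||% 5L,
                             per_population =
                               !isFALSE(mc$per_population))
  write_cnv_matrix(mat_full, emit("cnv_matrix_full.tsv"))
  write_cnv_matrix(mat, emit("cnv_matrix_filtered.tsv"))
  if (ncol(mat$values) < 1L)
    stop("no region survives the carrier filter; ",
         "lower matrix.min_carriers or enlarge the cohort")

  # -- stage: PCA + UPGMA/bootstrap ------------------------------------
  pca <- cnv_pca(mat)
  coords <- data.frame(sample_id = rownames(pca$coordinates),
                       population = manifest$population[
                         match(rownames(pca$coordinates),
                               manifest$sample_id)],
                       pca$coordinates[, seq_len(min(5L,
                         ncol(pca$coordinates))), drop = FALSE],
                       stringsAsFactors = FALSE)
  utils::write.table(coords, emit("pca_coordinates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tc <- config$tree %||% list()
  tree <- bootstrap_support(mat, n_boot = tc$n_boot %||% 100L,
                            seed = seed + 1L,
                            method = tc$distance %||% "euclidean")
  write_dendrogram_newick(tree, emit("upgma_bootstrap.nwk"))

  # -- stage: V_ST scan -------------------------------------------------
  vc <- config$vst %||% list()
  vst <- NULL
  if (length(pops) >= 2L) {
    vst <- vst_scan(regions, lrr, cohort$map, calls, manifest,
                    min_carriers = vc$min_carriers %||% 5L,
                    rule = vc$rule %||% "mean2sd")
    utils::write.table(vst, emit("vst_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # -- stage: annotation -----------------------------------------------
  annotated <- NULL
  if (!is.null(config$annotate)) {
    track <- do.call(rbind, lapply(
      c(config$annotate$genes, config$annotate$qtl),
      function(p) read_annotation_track(resolve_path(p))))
    annotated <- annotate_regions(regions, track)
    write_annotated_regions(annotated, emit("cnvr_annotated.tsv"))
    gc_sum <- gene_content_summary(annotated)
    jsonlite::write_json(gc_sum, emit("gene_content.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  run_manifest <- list(
    package = "cnvpop",
    version = as.character(utils::packageVersion("cnvpop")),
    seed = seed,
    config = config,
    n_samples_kept = length(kept),
    n_calls = nrow(calls),
    n_regions = nrow(regions),
    outputs = basename(files)
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, qc = qc, regions = regions,
                 summary = summary, venn = venn, matrix = mat,
                 matrix_full = mat_full, pca = pca, tree = tree,
                 vst = vst, annotated = annotated,
                 files = c(files, file.path(out_dir, "run_manifest.json"))))
}
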