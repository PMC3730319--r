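## End-to-end orchestration: simulate -> preprocess/bin -> PCA/select ->
## quantify/fold-change -> classify -> pathway network, with every
## intermediate serialized under one run directory.

#' Build and validate a pipeline configuration
#'
#' Flat key-value configuration for [run_all()]. Unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' @param seed Master seed for simulation and splits.
#' @param outdir Run directory (created if needed).
#' @param cv Concentration noise CV.
#' @param noise_sd,drift_amplitude Spectral render settings.
#' @param threshold Loading-distance quantile for region selection.
#' @param alpha Paired-t significance level.
#' @param smoothness,asymmetry Baseline-correction parameters.
#' @param trim Trimmed-mean fraction for normalization.
#' @param cost_grid Linear-SVM cost grid.
#' @param selection_time_point Time point used for the selection stage.
#' @param ... Unknown keys: rejected with an error naming them.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = "results/run", cv = 0.1,
                            noise_sd = 0.2, drift_amplitude = 2,
                            threshold = 0.9, alpha = 0.05,
                            smoothness = 1e8, asymmetry = 0.001, trim = 0.05,
                            cost_grid = default_cost_grid(),
                            selection_time_point = "48h", ...) {
  extra <- list(...)
  if (length(extra)) {
    abort("UNKNOWN_KEY", paste("unknown configuration key(s):",
                               paste(names(extra), collapse = ", ")))
  }
  structure(list(seed = as.integer(seed), outdir = outdir, cv = cv,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 threshold = threshold, alpha = alpha,
                 smoothness = smoothness, asymmetry = asymmetry, trim = trim,
                 cost_grid = cost_grid,
                 selection_time_point = selection_time_point),
            class = "pipeline_config")
}

#' MD5 hash of a configuration (stamped into every artifact)
#'
#' The output directory is excluded: the hash fingerprints the scientific
#' parameters, so reruns into different directories stay comparable.
#'
#' @param config A `pipeline_config`.
#' @return Hash string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  keys <- unclass(config)
  keys$outdir <- NULL
  jsonlite::write_json(keys, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Prepend a config-hash comment line to a text artifact
#' @noRd
stamp_artifact <- function(path, hash) {
  txt <- readLines(path)
  writeLines(c(sprintf("# config_hash: %s", hash), txt), path)
  path
}

#' Run the full analysis end-to-end
#'
#' Executes simulate, preprocess, select, foldchange, classify and pathways
#' in order, serializing every intermediate under `config$outdir`. The run
#' is deterministic given the configuration: rerunning with the same config
#' reproduces the numeric artifacts byte for byte. A stage failure aborts
#' with the failing stage named; artifacts of completed stages remain.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of artifact paths plus the `selection`,
#'   `fold_changes`, `metrics` and `comparison` results.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    say("[%s] running", name)
    tryCatch(expr, error = function(e) {
      abort("STAGE_FAILED", sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
                       file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  params <- render_params(noise_sd = config$noise_sd,
                          drift_amplitude = config$drift_amplitude)
  study <- stage("simulate", {
    st <- make_study(seed = config$seed, cv = config$cv, params = params)
    specdir <- file.path(out, "spectra")
    dir.create(specdir, showWarnings = FALSE)
    for (s in st$spectra) write_spectrum(s, file.path(specdir, paste0(s$sample_id, ".txt")))
    utils::write.csv(st$truth, file.path(out, "ground_truth.csv"), row.names = FALSE)
    stamp_artifact(file.path(out, "ground_truth.csv"), hash)
    st
  })

  prep <- stage("preprocess", {
    pp <- lapply(study$spectra, preprocess_spectrum,
                 smoothness = config$smoothness, asymmetry = config$asymmetry,
                 trim = config$trim)
    bm <- bin_spectra(pp, preprocess = FALSE)
    write_binned_matrix(bm, file.path(out, "binned_matrix.csv"))
    stamp_artifact(file.path(out, "binned_matrix.csv"), hash)
    list(preprocessed = pp, binned = bm)
  })

  sel <- stage("select", {
    sub <- subset_binned(prep$binned, time_point = config$selection_time_point)
    model <- fit_pca(sub, k = 2)
    utils::write.csv(data.frame(sub$meta, model$scores),
                     file.path(out, "pca_scores.csv"), row.names = FALSE)
    stamp_artifact(file.path(out, "pca_scores.csv"), hash)
    res <- select_regions(sub, model, threshold = config$threshold, alpha = config$alpha)
    write_selection(res, file.path(out, "selection.tsv"))
    stamp_artifact(file.path(out, "selection.tsv"), hash)
    res
  })

  fc <- stage("foldchange", {
    conc <- quantify_study(prep$preprocessed)
    norm <- normalize_total(conc)
    utils::write.csv(norm, file.path(out, "concentrations.csv"), row.names = FALSE)
    stamp_artifact(file.path(out, "concentrations.csv"), hash)
    records <- fold_changes(norm)
    write_fold_changes(records, file.path(out, "fold_changes.tsv"))
    stamp_artifact(file.path(out, "fold_changes.tsv"), hash)
    write_heatmap_matrix(heatmap_matrix(records), file.path(out, "heatmap_matrix.csv"))
    list(records = records, normalized = norm)
  })

  metrics <- stage("classify", {
    rep <- classification_report(fc$normalized, seed = config$seed,
                                 cost_grid = config$cost_grid)
    utils::write.table(rep, file.path(out, "classification_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stamp_artifact(file.path(out, "classification_metrics.tsv"), hash)
    rep
  })

  cmpres <- stage("pathways", {
    fixdir <- file.path(out, "pathway_fixture")
    fx <- make_pathway_fixture(fixdir)
    recs <- parse_kgml(fx$kgml_files)
    panel <- utils::read.delim(fx$panel)
    met_hits <- map_metabolites(panel, recs)
    genes <- readLines(fx$gene_list)
    trans_hits <- suppressWarnings(map_genes(genes, read_gene_map(fx$gene_map), recs))
    cmp <- write_comparison(recs, unique(met_hits$pathway_id),
                            unique(trans_hits$pathway_id),
                            file.path(out, "pathway_comparison.tsv"))
    stamp_artifact(file.path(out, "pathway_comparison.tsv"), hash)
    g <- build_graph(recs, met_hits, trans_hits)
    export_graph(g, file.path(out, "pathway_network.graphml"), "graphml")
    export_graph(g, file.path(out, "pathway_network.sif"), "sif")
    list(comparison = cmp, graph = g)
  })

  say("run complete: %s", out)
  invisible(list(outdir = out, config_hash = hash, selection = sel,
                 fold_changes = fc$records, metrics = metrics,
                 comparison = cmpres$comparison, graph = cmpres$graph))
}
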