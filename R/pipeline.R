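# End-to-end pipeline: simulate (optional) -> LOH calling -> segmentation
# and FDR-controlled CNA calling -> landscape summaries -> Cox screen ->
# clustering, with every artifact written to the output directory under a
# manifest.

.PIPELINE_DEFAULTS <- list(
  simulate = TRUE,
  inputs = NULL,            # named paths when simulate = FALSE
  t_threshold = 4.0,
  min_seg_len = 10L,
  cutoff_grid = seq(0.05, 2, by = 0.05),
  fdr_target = 0.10,
  min_loh_samples = 5L,
  cluster_features = "loh",
  loh_denominator = "informative",
  top_k = 100L,
  seed = 1L,
  outdir = NULL)

#' Read a pipeline configuration file
#'
#' YAML (default) with a JSON fallback. Unknown keys are rejected; known
#' keys override the documented defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  pipeline_config(cfg)
}

#' Build a validated pipeline configuration
#'
#' @param config Named list of overrides for the pipeline defaults
#'   (`simulate`, `inputs`, `t_threshold`, `min_seg_len`, `cutoff_grid`,
#'   `fdr_target`, `min_loh_samples`, `cluster_features`,
#'   `loh_denominator`, `top_k`, `seed`, `outdir`, and optionally `cohort`,
#'   a [cohort_config()] for the simulate stage).
#' @return The merged configuration list.
#' @export
pipeline_config <- function(config = list()) {
  known <- c(names(.PIPELINE_DEFAULTS), "cohort")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    .config_err("unknown pipeline configuration keys: %s",
                paste(unknown, collapse = ","))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config)
  .check_number(cfg$fdr_target, "fdr_target", 0, 1, lo_open = TRUE)
  cfg$min_seg_len <- .check_count(cfg$min_seg_len, "min_seg_len")
  cfg$min_loh_samples <- .check_count(cfg$min_loh_samples,
                                      "min_loh_samples", min = 0L)
  cfg$seed <- .check_seed(cfg$seed)
  if (!cfg$cluster_features %in% c("loh", "cna"))
    .config_err("'cluster_features' must be \"loh\" or \"cna\"")
  cfg
}

#' Run the full pipeline
#'
#' Executes: simulate (or read inputs) -> LOH calling and uninformative-SNP
#' filtering -> paired segmentation, blood-null FDR curve, cutoff selection
#' and CNA calling -> joint classification -> landscape summaries -> Cox
#' screen -> sample clustering with smoking association and mortality
#' comparison. Every artifact is written under `outdir` together with a
#' `manifest.json` recording package version, parameters, seed and input
#' checksums. Deterministic: identical config and seed give identical
#' outputs.
#'
#' A failing stage aborts with the stage name attached to the error.
#'
#' @param config A [pipeline_config()] list (or raw overrides).
#' @return Invisibly, a list with the main in-memory results (`callset`,
#'   `consensus`, `burden`, `arm_events`, `screen`, `clusters`,
#'   `associations`, `cutoff`) and `outdir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(if (inherits(config, "lohscan_cohort_config"))
    list(cohort = config) else config)
  outdir <- cfg$outdir %||% tempfile("lohscan_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .err("lohscan_stage_error", "stage '%s' failed: %s", name,
           conditionMessage(e))
    })
  }

  input_paths <- NULL
  if (isTRUE(cfg$simulate)) {
    cohort <- stage("simulate", {
      cc <- cfg$cohort %||% cohort_config(seed = cfg$seed)
      simulate_cohort(cc)
    })
    input_paths <- stage("simulate", write_cohort(cohort, file.path(outdir, "inputs")))
    inputs <- list(blood_genotype = cohort$blood_genotype,
                   tumor_genotype = cohort$tumor_genotype,
                   blood_signal = cohort$blood_signal,
                   tumor_signal = cohort$tumor_signal,
                   annotation = cohort$annotation,
                   clinical = cohort$clinical)
  } else {
    input_paths <- unlist(cfg$inputs)
    inputs <- stage("read_inputs", read_inputs(cfg$inputs))
  }

  loh_full <- stage("call_loh", call_loh(inputs$blood_genotype,
                                         inputs$tumor_genotype))
  loh_res <- stage("call_loh", filter_uninformative_snps(loh_full))

  seg <- stage("call_cna", segment_cohort(inputs$tumor_signal,
                                          inputs$blood_signal,
                                          inputs$annotation,
                                          cfg$t_threshold, cfg$min_seg_len))
  curve <- stage("call_cna", estimate_fdr_curve(seg$tumor_delta,
                                                seg$blood_delta,
                                                cfg$cutoff_grid))
  sel <- stage("call_cna", select_cutoff(curve, cfg$fdr_target))
  cna <- stage("call_cna", call_cna(seg$tumor_delta, sel$cutoff))
  # genome-wide LOH status (unfiltered) keeps the call set aligned to CNA
  callset <- stage("call_cna", build_callset(loh_full, cna))

  consensus <- stage("landscape", consensus_frequencies(callset,
                                                        cfg$loh_denominator))
  brd <- stage("landscape", burden(callset))
  arms <- stage("landscape", arm_events(callset, inputs$annotation))
  topk <- stage("landscape", top_k_tables(consensus, inputs$annotation,
                                          cfg$top_k))

  scr <- stage("screen", screen(callset, inputs$clinical,
                                cfg$min_loh_samples))

  clusters <- stage("cluster", cluster_samples(callset, cfg$cluster_features))
  assoc <- stage("cluster", {
    if (clusters$degenerate) list(fisher_smoking = NULL, mortality = NULL)
    else list(fisher_smoking = fisher_exact(clusters$labels,
                                            inputs$clinical$smoking),
              mortality = compare_mortality(clusters$labels, inputs$clinical))
  })

  stage("write_outputs", {
    .write_matrix_tsv(loh_res$matrix, file.path(outdir, "loh_matrix.tsv"))
    utils::write.table(data.frame(probe_id = loh_res$excluded),
                       file.path(outdir, "loh_excluded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_seg(seg$segments, inputs$annotation, file.path(outdir, "segments.seg"))
    utils::write.table(
      data.frame(cutoff = curve$grid, mean_fdr = curve$mean_fdr),
      file.path(outdir, "fdr_curve.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    .write_matrix_tsv(callset$cna_class, file.path(outdir, "cna_calls.tsv"))
    .write_matrix_tsv(callset$joint, file.path(outdir, "joint_classes.tsv"))
    utils::write.table(consensus, file.path(outdir, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(brd$per_sample, file.path(outdir, "burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(arms$arm_percent, file.path(outdir, "arm_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(topk))
      utils::write.table(topk[[nm]],
                         file.path(outdir, sprintf("top_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(scr))
      utils::write.table(scr, file.path(outdir, "screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = names(clusters$labels) %||%
                   inputs$clinical$sample_id,
                 cluster = clusters$labels),
      file.path(outdir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    manifest <- list(
      package = "lohscan",
      version = as.character(utils::packageVersion("lohscan")),
      seed = cfg$seed,
      parameters = cfg[c("t_threshold", "min_seg_len", "fdr_target",
                         "min_loh_samples", "cluster_features",
                         "loh_denominator", "top_k")],
      chosen_cutoff = sel$cutoff,
      mean_fdr_at_cutoff = sel$mean_fdr,
      input_checksums = as.list(tools::md5sum(unname(input_paths))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(callset = callset, consensus = consensus, burden = brd,
                 arm_events = arms, top_k = topk, screen = scr,
                 clusters = clusters, associations = assoc,
                 cutoff = sel$cutoff, fdr_curve = curve, outdir = outdir))
}
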