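#' Pipeline configuration
#'
#' Collects the file paths and every analysis threshold into one validated
#' object; [run_pipeline()] echoes it verbatim into the run manifest so each
#' threshold used is auditable.
#'
#' @param counts path to the count-matrix TSV.
#' @param design path to the design TSV.
#' @param gmt optional path to a GMT annotation.
#' @param out_dir output directory (created if absent).
#' @param alpha FDR threshold, in (0, 1).
#' @param consensus_threshold consensus fraction of combinations, in (0, 1].
#' @param prior_df dispersion-shrinkage prior df.
#' @param min_total_count low-count filter threshold.
#' @param seed integer seed recorded in the manifest.
#' @param strategies subset of `c("fourvfour", "eightveight", "ranef")`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, gmt = NULL, out_dir,
                            alpha = 0.05, consensus_threshold = 0.85,
                            prior_df = 10, min_total_count = 10, seed = 1,
                            strategies = c("fourvfour", "eightveight", "ranef")) {
  if (alpha <= 0 || alpha >= 1) parameter_error("alpha must lie in (0, 1)")
  if (consensus_threshold <= 0 || consensus_threshold > 1)
    parameter_error("consensus_threshold must lie in (0, 1]")
  strategies <- match.arg(unlist(strategies, use.names = FALSE),
                          c("fourvfour", "eightveight", "ranef"),
                          several.ok = TRUE)
  cfg <- list(counts = counts, design = design, gmt = gmt, out_dir = out_dir,
              alpha = alpha, consensus_threshold = consensus_threshold,
              prior_df = prior_df, min_total_count = min_total_count,
              seed = as.integer(seed), strategies = strategies)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path path to a YAML key-value file with the [pipeline_config()]
#'   fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full consensus pipeline end to end
#'
#' Reads the inputs, runs the requested strategies via [consensus_de()],
#' performs gene-set enrichment of the final consensus DE set against the
#' filtered-gene background (when an annotation is supplied), writes every
#' intermediate table to `out_dir`, and writes a machine-readable
#' `manifest.json` echoing the configuration, the seed and the gene counts at
#' each stage. Identical configuration and inputs give byte-identical numeric
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  set.seed(config$seed)
  counts <- read_counts(config$counts)
  design <- read_design(config$design)
  gsc <- if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop_combo("comboDE_stage_error",
                 sprintf("stage '%s' failed (%d genes x %d libraries): %s",
                         name, nrow(counts), ncol(counts), conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  files <- character()
  filtered <- stage("filter", filter_low_counts(counts, config$min_total_count))
  nf <- stage("normalize", rle_factors(filtered))
  write_results(nf, file.path(config$out_dir, "factors.tsv"))
  files <- c(files, "factors.tsv")

  fit <- stage("strategies", consensus_de(
    counts, design, alpha = config$alpha,
    threshold = config$consensus_threshold,
    min_total = config$min_total_count, prior_df = config$prior_df,
    strategies = config$strategies))

  if (!is.null(fit$eightveight)) {
    write_results(fit$eightveight, file.path(config$out_dir, "de_8vs8.tsv"))
    files <- c(files, "de_8vs8.tsv")
  }
  if (!is.null(fit$ranef)) {
    write_results(fit$ranef, file.path(config$out_dir, "de_ranef.tsv"))
    files <- c(files, "de_ranef.tsv")
  }
  if (!is.null(fit$fourvfour)) {
    write_results(data.frame(gene_id = names(fit$fourvfour$tally),
                             n_combos_de = as.integer(fit$fourvfour$tally),
                             n_combos_total = fit$fourvfour$n_combos),
                  file.path(config$out_dir, "tally.tsv"))
    files <- c(files, "tally.tsv")
  }
  enr <- NULL
  final_de <- character()
  if (!is.null(fit$consensus)) {
    write_results(fit$consensus, file.path(config$out_dir, "consensus.tsv"))
    write_results(attr(fit$consensus, "tally_histogram"),
                  file.path(config$out_dir, "tally_histogram.tsv"))
    files <- c(files, "consensus.tsv", "tally_histogram.tsv")
    final_de <- fit$consensus$gene_id[fit$consensus$final_de]
    if (!is.null(gsc) && length(final_de) > 0) {
      background <- rownames(filtered)
      enr <- stage("enrichment",
                   fisher_enrichment(intersect(final_de, background),
                                     background, gsc))
      write_results(enr, file.path(config$out_dir, "enrichment.tsv"))
      files <- c(files, "enrichment.tsv")
    }
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    gene_counts = list(
      input = nrow(counts),
      filtered_16lib = nrow(filtered),
      tested_8vs8 = if (!is.null(fit$eightveight)) nrow(fit$eightveight) else NULL,
      de_8vs8 = if (!is.null(fit$eightveight))
        sum(fit$eightveight$fdr < config$alpha) else NULL,
      de_ranef = if (!is.null(fit$ranef))
        sum(fit$ranef$fdr < config$alpha) else NULL,
      systematic_4vs4 = if (!is.null(fit$fourvfour))
        sum(fit$fourvfour$tally == fit$fourvfour$n_combos) else NULL,
      final_de = if (!is.null(fit$consensus)) length(final_de) else NULL),
    rho = fit$rho,
    consensus_threshold = if (!is.null(fit$consensus))
      attr(fit$consensus, "consensus_threshold") else NULL,
    n_combinations = if (!is.null(fit$fourvfour)) fit$fourvfour$n_combos else NULL,
    enriched_terms = if (!is.null(enr)) sum(enr$fdr < config$alpha) else NULL,
    files = files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
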