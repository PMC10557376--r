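#' Assemble a full-run configuration
#'
#' Bundles the generator configuration with the filter and quantification
#' parameters of a complete simulate -> filter -> quantify -> bulk-compare
#' run. The `seed` overrides the generator's seed so one integer controls
#' every source of randomness in the run.
#'
#' @param generator A [generator_config()].
#' @param fdr_threshold,fdr_mode Validator FDR filter parameters.
#' @param min_occupancy Channel-occupancy cutoff in percent (default 25).
#' @param max_rank_percentile Bulk-rank cutoff as a fraction (default 0.25).
#' @param absent_policy Bulk-rank policy for unmatched peptides.
#' @param noise_threshold Occupancy intensity threshold (default 0).
#' @param baseline Normalization baseline (see [normalize_per_protein()]).
#' @param ratio_estimator Class-ratio estimator (see
#'   [class_comparison()]; default `"geometric"`).
#' @param pooling Class-comparison pooling mode.
#' @param alpha Significance level for the empty-channel and bulk tests.
#' @param protein_subset Optional accession subset for the class comparison.
#' @param seed Integer seed for the whole run (default: the generator's).
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       fdr_threshold = 0.05, fdr_mode = "either",
                       min_occupancy = 25, max_rank_percentile = 0.25,
                       absent_policy = "fail", noise_threshold = 0,
                       baseline = "single_mean", ratio_estimator = "geometric",
                       pooling = "pooled",
                       alpha = 0.05, protein_subset = NULL,
                       seed = NULL) {
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  validate_generator_config(generator)
  cfg <- list(
    generator = generator,
    fdr_threshold = fdr_threshold, fdr_mode = fdr_mode,
    min_occupancy = min_occupancy,
    max_rank_percentile = max_rank_percentile,
    absent_policy = absent_policy, noise_threshold = noise_threshold,
    baseline = baseline, ratio_estimator = ratio_estimator,
    pooling = pooling, alpha = alpha,
    protein_subset = protein_subset,
    seed = generator$seed
  )
  class(cfg) <- "run_config"
  cfg
}

provenance_of <- function(config) {
  list(
    tool = "scopebac",
    version = as.character(utils::packageVersion("scopebac")),
    seed = config$seed,
    config_sha1 = digest::digest(unclass(config), algo = "sha1")
  )
}

provenance_header <- function(prov) {
  sprintf("# %s %s | seed=%d | config_sha1=%s",
          prov$tool, prov$version, prov$seed, prov$config_sha1)
}

write_tsv_with_provenance <- function(x, path, prov) {
  writeLines(provenance_header(prov), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run the complete single-bacterium analysis pipeline
#'
#' Orchestrates, under a single configuration and seed: synthetic data
#' generation (layout, proteome, PSM table, bulk table), the three-layer
#' validation filter chain, protein quantification with normalization and
#' channel-class comparison, labeling-efficiency estimation and the
#' bulk-proteome method comparison. Optionally writes every stage output
#' (TSV tables with a provenance header and a JSON run report); re-running
#' with the same configuration reproduces the outputs byte-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A `run_report` list with identification counts, the filter
#'   report, the class summary, labeling efficiency, bulk summaries and
#'   provenance.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  prov <- provenance_of(config)

  layouts <- generate_layout(gen)
  proteome <- simulate_proteome(gen)
  psms <- simulate_psm_table(gen, layouts, proteome)
  bulk <- simulate_bulk_table(gen, proteome)

  filtered <- filter_pipeline(
    psms, layouts, bulk,
    fdr_threshold = config$fdr_threshold, fdr_mode = config$fdr_mode,
    noise_threshold = config$noise_threshold,
    min_occupancy = config$min_occupancy,
    max_rank_percentile = config$max_rank_percentile,
    absent_policy = config$absent_policy
  )
  counts <- count_identifications(filtered$evidence)
  quants <- protein_group_abundance(filtered$evidence)
  quants <- normalize_per_protein(quants, layouts, baseline = config$baseline)
  summary <- withr::with_seed(config$seed + 3L, class_comparison(
    quants, layouts, protein_subset = config$protein_subset,
    ratio_estimator = config$ratio_estimator,
    pooling = config$pooling, alpha = config$alpha
  ))
  eff <- labeling_efficiency(psms)
  bulk_cmp <- method_enrichment_test(bulk, alpha = config$alpha)

  report <- list(
    provenance = prov,
    design = list(
      n_sets = gen$n_sets,
      n_cell_channels = sum(layouts$channel_class %in% c("SINGLE", "DOUBLE")),
      n_carrier_channels = sum(layouts$channel_class == "CARRIER"),
      n_empty_channels = sum(layouts$channel_class == "EMPTY")
    ),
    n_psms = nrow(psms),
    labeling_efficiency_percent = eff,
    filter_stages = as.data.frame(filtered$report),
    identifications = counts,
    class_comparison = list(
      class_stats = as.data.frame(summary$class_stats),
      enrichment_double_vs_single_percent = summary$enrichment_double_vs_single,
      carrier_factor = summary$carrier_factor,
      empty_channel_p_value =
        if (is.null(summary$empty_test)) NA else summary$empty_test$p_value,
      empty_indistinguishable_from_zero =
        if (is.null(summary$empty_test)) NA else
          summary$empty_test$indistinguishable
    ),
    bulk = list(
      detection_delta_percent = bulk_cmp$aggregate$detection_delta_percent,
      ribosomal_share_percent = ribosomal_share(bulk),
      n_significant = bulk_cmp$aggregate$n_significant,
      sonication_enriched = bulk_cmp$aggregate$sonication_enriched,
      freeze_thaw_enriched = bulk_cmp$aggregate$freeze_thaw_enriched
    )
  )
  class(report) <- c("run_report", class(report))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_with_provenance(psms, file.path(out_dir, "psm_table.tsv"), prov)
    write_tsv_with_provenance(bulk, file.path(out_dir, "bulk_table.tsv"), prov)
    write_tsv_with_provenance(tibble::as_tibble(filtered$evidence),
                              file.path(out_dir, "peptide_evidence.tsv"), prov)
    write_tsv_with_provenance(tibble::as_tibble(quants),
                              file.path(out_dir, "protein_quant.tsv"), prov)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report
}

#' Read / write a run configuration as YAML
#'
#' The YAML file mirrors [run_config()]: a `generator` section with the
#' generator knobs plus top-level filter/quantification parameters.
#'
#' @param path YAML file path.
#' @param config A `run_config` (for writing).
#' @return `read_run_config()`: a validated `run_config`;
#'   `write_run_config()`: `path`, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator %||% list()
  gen <- do.call(generator_config, gen_args)
  args <- raw[setdiff(names(raw), "generator")]
  do.call(run_config, c(list(generator = gen), args))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$generator <- unclass(out$generator)
  out$seed <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
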