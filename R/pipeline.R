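#' Pipeline configuration
#'
#' Assembles paths and stage configurations for an end-to-end run. May be
#' built directly or read from a YAML file with [read_pipeline_config()];
#' the resolved configuration is serialized into the output directory for
#' provenance.
#'
#' @param vcf,annotations,phenotypes Input file paths.
#' @param panel Optional verification-panel TSV; `NULL` skips that stage.
#' @param out_dir Output directory for result tables.
#' @param qc A [site_qc_config()].
#' @param prioritization A [prioritization_config()].
#' @param mask_maf_max Rarity bound of the gene-wise collapsing masks
#'   (default 0.05).
#' @param alpha Significance level for flagging (default 0.05).
#' @param seed Seed for any resampling diagnostics (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, annotations, phenotypes, panel = NULL,
                            out_dir = "exburden_out",
                            qc = site_qc_config(),
                            prioritization = prioritization_config(),
                            mask_maf_max = 0.05, alpha = 0.05, seed = 1L) {
  for (p in c(vcf, annotations, phenotypes, panel))
    if (!file.exists(p)) stop("config error: input path does not exist: ", p)
  structure(list(vcf = vcf, annotations = annotations,
                 phenotypes = phenotypes, panel = panel, out_dir = out_dir,
                 qc = qc, prioritization = prioritization,
                 mask_maf_max = mask_maf_max, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys: `paths` (`vcf`, `annotations`, `phenotypes`, optional
#' `panel`, `out_dir`), `qc` (keys of [site_qc_config()]), `prioritization`
#' (keys of [prioritization_config()]), `mask_maf_max`, `alpha`, `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$paths)) stop("config error: missing 'paths' block")
  pipeline_config(
    vcf = y$paths$vcf, annotations = y$paths$annotations,
    phenotypes = y$paths$phenotypes, panel = y$paths$panel,
    out_dir = y$paths$out_dir %||% "exburden_out",
    qc = do.call(site_qc_config, y$qc %||% list()),
    prioritization = do.call(prioritization_config,
                             y$prioritization %||% list()),
    mask_maf_max = y$mask_maf_max %||% 0.05,
    alpha = y$alpha %||% 0.05, seed = y$seed %||% 1L)
}

log_stage <- function(stage, n_in, n_out, quiet) {
  if (!quiet)
    message(sprintf("[%s] records in: %d, out: %d", stage, n_in, n_out))
}

#' Run the full association pipeline
#'
#' Executes, in order: cohort loading, sample QC, site QC with MAF
#' stratification, single-variant association on common and low-frequency
#' variants, candidate prioritization, the gene-level burden scan, the two
#' gene-wise collapsing masks with Manhattan export, and (when a panel is
#' configured) panel verification. Every stage writes a TSV into
#' `config$out_dir` and logs its input/output record counts; reruns on
#' identical inputs are byte-identical.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param quiet Suppress per-stage log messages (default FALSE).
#' @return Invisibly, a named list of the stage result data.frames plus
#'   `paths` of the written TSVs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(
    list(qc = unclass(config$qc),
         prioritization = unclass(config$prioritization),
         mask_maf_max = config$mask_maf_max, alpha = config$alpha,
         seed = config$seed),
    file.path(config$out_dir, "config.yaml"))
  paths <- list()
  wt <- function(df, name, sort_by = NULL) {
    paths[[name]] <<- file.path(config$out_dir, paste0(name, ".tsv"))
    write_table(df, paths[[name]], sort_by = sort_by)
  }

  cohort <- load_cohort(config$vcf)
  phenotypes <- load_phenotypes(config$phenotypes,
                                cohort$genotypes$sample_ids)
  annotations <- load_annotations(config$annotations,
                                  cohort$genotypes$vids)
  log_stage("load", nrow(cohort$variants), nrow(cohort$variants), quiet)
  wt(cohort$variants, "variants", sort_by = "vid")

  keep_samples <- sample_qc(cohort$genotypes, config$qc)
  log_stage("sample_qc", length(cohort$genotypes$sample_ids),
            length(keep_samples), quiet)
  g <- cohort$genotypes
  analysis <- genotype_matrix(g$dosage[keep_samples, , drop = FALSE],
                              g$depth[keep_samples, , drop = FALSE])
  ph <- phenotypes[phenotypes$sample_id %in% keep_samples, , drop = FALSE]

  qc <- site_qc(analysis, ph, config$qc)
  log_stage("site_qc", nrow(qc), sum(qc$qc_pass), quiet)
  wt(qc, "site_qc", sort_by = "vid")

  tally <- consequence_tally(annotations)
  wt(data.frame(consequence = names(tally), n = as.integer(tally),
                stringsAsFactors = FALSE), "consequence_tally")

  sva <- sva_scan(analysis, ph, qc)
  log_stage("sva", sum(qc$qc_pass &
                         qc$stratum %in% c("common", "low_frequency"),
                       na.rm = TRUE),
            length(unique(sva$vid)), quiet)
  wt(sva, "sva", sort_by = c("vid", "model"))

  candidates <- case_only_filter(analysis, ph, annotations, qc,
                                 config$prioritization)
  log_stage("prioritize", nrow(qc), nrow(candidates), quiet)
  trail <- attr(candidates, "filter_trail")
  wt(candidates, "candidates")
  wt(trail, "filter_trail", sort_by = "vid")

  qualifying <- burden_qualifying_map(annotations, qc,
                                      config$prioritization)
  if (nrow(qualifying)) {
    tables <- collapse_carriers(analysis, ph, qualifying)
    burden <- burden_scan(tables, config$alpha)
  } else {
    burden <- burden_scan(NULL, config$alpha)
  }
  log_stage("burden", nrow(burden), sum(burden$significant), quiet)
  wt(burden, "burden")

  genewise <- list()
  for (mk in mask_names) {
    map <- build_mask(annotations, qc, mk, config$mask_maf_max)
    if (nrow(map)) {
      res <- gene_collapse_test(analysis, ph, map, mk)
      genewise[[mk]] <- res
      wt(res, paste0("genewise_", mk), sort_by = "gene")
      wt(manhattan_export(res, config$alpha), paste0("manhattan_", mk))
      log_stage(paste0("genewise_", mk), nrow(map), nrow(res), quiet)
    }
  }

  verification <- NULL
  if (!is.null(config$panel)) {
    panel <- load_panel(config$panel)
    verification <- verify_panel(panel, analysis, ph)
    log_stage("verify", nrow(panel), sum(verification$found_in_cohort),
              quiet)
    wt(verification, "verification")
  }

  invisible(list(variants = cohort$variants, qc = qc, sva = sva,
                 candidates = candidates, burden = burden,
                 genewise = genewise, verification = verification,
                 analysis_samples = keep_samples, paths = paths))
}
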