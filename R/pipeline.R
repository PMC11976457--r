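# End-to-end orchestration: simulate (or load a fixture) -> consensus filter
# -> arm events & SCNA fractions -> scar scores -> double hit -> signature
# exposures -> cohort statistics, with flat TSV stage outputs and a JSON
# manifest. Outputs are pure functions of the config; a rerun with the same
# config is bit-identical.

#' Build a pipeline run configuration
#'
#' @param out_dir Directory for stage outputs and the manifest.
#' @param spec [cohort_spec()] used when simulating (ignored when
#'   `fixture_dir` is given).
#' @param fixture_dir Optional directory written by [write_fixture()];
#'   when set, inputs are read from it instead of being simulated.
#' @param seed Optional integer overriding `spec$seed`.
#' @param cohorts Length-2 cohorts contrasted in the statistics stage.
#' @param min_arm_fraction Arm-call threshold for [arm_events()].
#' @param min_gene_fraction Gene-overlap threshold for [double_hit_table()].
#' @param drop_threshold Signature drop threshold for [fit_exposures()].
#' @param exome_mb TMB denominator in Mb.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir,
                            spec = cohort_spec(),
                            fixture_dir = NULL,
                            seed = NULL,
                            cohorts = c("transformed", "denovo"),
                            min_arm_fraction = 0.5,
                            min_gene_fraction = 0.5,
                            drop_threshold = 0.06,
                            exome_mb = 38) {
  structure(
    list(out_dir = out_dir, spec = spec, fixture_dir = fixture_dir,
         seed = seed, cohorts = cohorts,
         min_arm_fraction = min_arm_fraction,
         min_gene_fraction = min_gene_fraction,
         drop_threshold = drop_threshold, exome_mb = exome_mb),
    class = "run_config"
  )
}

validate_run_config <- function(config) {
  if (is.null(config$out_dir)) abort("config needs an out_dir")
  if (!is.null(config$fixture_dir)) {
    needed <- file.path(config$fixture_dir,
                        c("clinical.tsv", "segments.seg", "spectra.tsv"))
    missing <- needed[!file.exists(needed)]
    if (length(missing) > 0) {
      abort(paste0("fixture input file(s) missing: ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (length(config$cohorts) != 2) abort("cohorts must name two groups")
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, consensus filtering, arm-level SCNA, genomic
#' scars, double-hit integration, signature deconvolution and cohort
#' statistics as one reproducible run. Each stage writes a flat TSV under
#' `config$out_dir` and the run ends with a `manifest.json` recording the
#' package version, seed, parameters and stage outputs. Rerunning with the
#' same config reproduces every output byte for byte.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file with the
#'   same fields).
#' @param sigs Signature matrix for simulation and deconvolution.
#' @param genes Gene model for the double-hit stage.
#' @param gene_sets Pathway gene sets for the CNV summaries.
#' @return Invisibly, a list with every stage result (`cohort`,
#'   `mutations`, `arm_events`, `scna_fractions`, `scars`, `double_hit`,
#'   `double_hit_rates`, `pathway_cnv`, `exposures`, `features`,
#'   `feature_tests`, `mutation_scan`, `manifest`).
#' @export
run_pipeline <- function(config, sigs = toy_signature_matrix(),
                         genes = demo_genes(),
                         gene_sets = pathway_gene_sets()) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    spec_args <- raw$spec %||% list()
    config <- pipeline_config(
      out_dir = raw$out_dir,
      spec = do.call(cohort_spec, spec_args),
      fixture_dir = raw$fixture_dir,
      seed = raw$seed,
      cohorts = raw$cohorts %||% c("transformed", "denovo"),
      min_arm_fraction = raw$min_arm_fraction %||% 0.5,
      min_gene_fraction = raw$min_gene_fraction %||% 0.5,
      drop_threshold = raw$drop_threshold %||% 0.06,
      exome_mb = raw$exome_mb %||% 38
    )
  }
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  arms <- hg19_arms()
  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path, progress = FALSE)
    outputs[[name]] <<- paste0(name, ".tsv")
    tbl
  }

  # stage 1: simulate or load
  data <- run_stage("simulate", {
    if (is.null(config$fixture_dir)) {
      spec <- config$spec
      if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
      cohort <- generate_cohort(spec, sigs = sigs, genes = genes)
      list(clinical = cohort$clinical, variants = cohort$variants,
           segments = cohort$segments, spectra = cohort$spectra,
           seed = spec$seed)
    } else {
      fx <- read_fixture(config$fixture_dir)
      fx$seed <- config$seed
      fx
    }
  })
  emit(data$clinical, "clinical")

  # stage 2: consensus filter per sample
  mutations <- run_stage("filter", consensus_filter_cohort(data$variants))
  emit(mutations, "mutations")

  # stage 3: arm events and SCNA fractions
  arm_ev <- run_stage("scna", {
    arm_events(data$segments, arms,
               min_fraction = config$min_arm_fraction)
  })
  emit(arm_ev, "arm_events")
  fractions <- run_stage("scna", scna_fractions(data$segments, arms))
  emit(fractions, "scna_fractions")

  # stage 4: genomic scars
  scars <- run_stage("scars", hrd_score(data$segments, arms))
  emit(scars, "scars")

  # stage 5: double hit + pathway CNV
  dh <- run_stage("doublehit", {
    double_hit_table(mutations, data$segments, genes,
                     min_overlap_fraction = config$min_gene_fraction)
  })
  emit(dh, "double_hit")
  dh_rates <- run_stage("doublehit", {
    purrr::map_dfr(intersect(c("TP53", "RB1", "EGFR"), genes$gene),
                   function(g) {
                     cohort_double_hit_rate(dh, g, data$clinical)
                   })
  })
  emit(dh_rates, "double_hit_rates")
  pathway <- run_stage("doublehit", {
    pathway_cnv_summary(data$segments, genes, gene_sets)
  })
  emit(pathway, "pathway_cnv")

  # stage 6: signature exposures
  exposures <- run_stage("signatures", {
    suppressWarnings(
      fit_cohort_exposures(data$spectra, sigs,
                           drop_threshold = config$drop_threshold)
    )
  })
  emit(exposures, "exposures")

  # stage 7: cohort statistics
  features <- run_stage("stats", {
    cohort_features(mutations, data$segments, data$clinical, arms,
                    exome_mb = config$exome_mb)
  })
  emit(features, "features")
  feature_tests <- run_stage("stats", {
    compare_features(features, cohorts = rev(config$cohorts))
  })
  emit(feature_tests, "feature_tests")
  mutation_scan <- run_stage("stats", {
    alterations <- mutations |>
      dplyr::distinct(.data$sample, feature = .data$gene) |>
      dplyr::mutate(altered = TRUE)
    suppressMessages(
      frequency_scan(alterations, data$clinical, cohorts = config$cohorts)
    )
  })
  emit(mutation_scan, "mutation_scan")

  manifest <- list(
    package = "sclcscars",
    version = as.character(utils::packageVersion("sclcscars")),
    seed = data$seed,
    parameters = list(
      cohorts = config$cohorts,
      min_arm_fraction = config$min_arm_fraction,
      min_gene_fraction = config$min_gene_fraction,
      drop_threshold = config$drop_threshold,
      exome_mb = config$exome_mb
    ),
    stages = list(
      simulate = "clinical.tsv",
      filter = "mutations.tsv",
      scna = c("arm_events.tsv", "scna_fractions.tsv"),
      scars = "scars.tsv",
      doublehit = c("double_hit.tsv", "double_hit_rates.tsv",
                    "pathway_cnv.tsv"),
      signatures = "exposures.tsv",
      stats = c("features.tsv", "feature_tests.tsv", "mutation_scan.tsv")
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    clinical = data$clinical, mutations = mutations, arm_events = arm_ev,
    scna_fractions = fractions, scars = scars, double_hit = dh,
    double_hit_rates = dh_rates, pathway_cnv = pathway,
    exposures = exposures, features = features,
    feature_tests = feature_tests, mutation_scan = mutation_scan,
    manifest = manifest
  ))
}
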