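# End-to-end orchestration: simulate -> score -> validate -> benchmark ->
# evaluate, with plain-text TSV intermediates so every stage can be
# inspected and regenerated independently.

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Root seed for all randomness in the run.
#' @param spec A `genome_spec`.
#' @param target_ploidy Target truth ploidy.
#' @param caller_models Named list of `caller_model` objects.
#' @param orthogonal_models Named list of `orthogonal_model` objects; an
#'   empty list skips validation and restricts the benchmark to
#'   strong-evidence intervals.
#' @param grouping Grouping scheme data.frame.
#' @param mask Optional exclusion `GRanges`.
#' @param thresholds List of clustering thresholds (`proximity`,
#'   `similarity`).
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, spec = genome_spec(),
                            target_ploidy = 2.85,
                            caller_models = default_caller_models(seed),
                            orthogonal_models = default_orthogonal_models(seed),
                            grouping = default_grouping(), mask = NULL,
                            thresholds = list(proximity = 1e4,
                                              similarity = 0.5)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 target_ploidy = target_ploidy,
                 caller_models = caller_models,
                 orthogonal_models = orthogonal_models,
                 grouping = grouping, mask = mask, thresholds = thresholds),
            class = "run_config")
}

config_echo <- function(config) {
  list(
    seed = config$seed,
    target_ploidy = config$target_ploidy,
    chromosomes = as.list(config$spec$chromosomes),
    callers = names(config$caller_models),
    technologies = names(config$orthogonal_models),
    n_replicates = nrow(config$grouping),
    thresholds = config$thresholds,
    masked = !is.null(config$mask)
  )
}

#' Run the full consensus-benchmark pipeline
#'
#' Simulates the truth landscape, cohort, and orthogonal call sets from
#' the configuration, scores gain/loss/LOH consensus intervals, tabulates
#' orthogonal validation, assembles the benchmark (TSV and VCF), and
#' evaluates every simulated call set against the benchmark. All outputs
#' are plain-text and deterministic: rerunning an identical configuration
#' reproduces byte-identical files.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`truth`, `cohort`, `techs`, `scored`, `validation`, `benchmark`,
#'   `metrics`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  truth <- simulate_truth(config$spec, target_ploidy = config$target_ploidy,
                          seed = config$seed)
  note("truth: %d segments, ploidy %.4f", nrow(truth$segments), truth$ploidy)
  utils::write.table(truth$segments,
                     file.path(config$out_dir, "truth_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ch <- simulate_cohort(truth, config$caller_models, config$grouping)
  note("cohort: %d call sets from %d callers", length(ch$callsets),
       length(config$caller_models))

  techs <- if (length(config$orthogonal_models)) {
    simulate_orthogonal_set(truth, config$orthogonal_models)
  } else list()

  scored <- list()
  for (ty in c("GAIN", "LOSS", "LOH")) {
    sc <- withCallingHandlers(
      score_cohort(ch, ty, mask = config$mask),
      warning = function(w) {
        note("scoring %s: %s", ty, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    scored[[ty]] <- sc
    write_scored(sc, file.path(config$out_dir,
                               sprintf("scored_%s.tsv", tolower(ty))))
    note("scored %s: %d disjoint intervals", ty, nrow(sc))
  }

  validation <- NULL
  if (length(techs)) {
    validation <- do.call(rbind, lapply(scored, validation_table,
                                        techs = techs))
    rownames(validation) <- NULL
    utils::write.table(validation,
                       file.path(config$out_dir, "validation_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("validation table: %d rows over %d technologies",
         nrow(validation), length(techs))
  } else {
    note("no orthogonal technologies: validation skipped, benchmark is strong-evidence only")
  }

  benchmark <- assemble_benchmark(scored, techs, ch)
  write_benchmark_tsv(benchmark, file.path(config$out_dir, "benchmark.tsv"))
  write_benchmark_vcf(benchmark, file.path(config$out_dir, "benchmark.vcf"))
  note("benchmark: %d intervals (%.2f Mb)", nrow(benchmark),
       sum(benchmark$end - benchmark$start) / 1e6)

  metrics <- do.call(rbind, lapply(ch$callsets, function(cs) {
    do.call(rbind, lapply(c("GAIN", "LOSS"), function(ty) {
      m <- precision_recall_f1(cs, benchmark, ty, mask = config$mask)
      data.frame(caller = cs$caller, center = cs$center,
                 replicate = cs$replicate, cnv_type = ty,
                 precision = m$precision, recall = m$recall, f1 = m$f1,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(metrics) <- NULL
  utils::write.table(metrics, file.path(config$out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("metrics: %d caller x type rows", nrow(metrics))

  yaml::write_yaml(config_echo(config),
                   file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(truth = truth, cohort = ch, techs = techs, scored = scored,
                 validation = validation, benchmark = benchmark,
                 metrics = metrics, out_dir = config$out_dir))
}
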