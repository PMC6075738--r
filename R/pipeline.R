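# End-to-end orchestration: simulate or load a cohort, then run copy-number
# calling, mutation timing, methylation deconvolution and the cohort
# statistics, writing a TSV bundle plus a versioned machine-readable JSON
# report. Deterministic given config + seed.

.REPORT_SCHEMA <- "1.0"

.DEFAULT_THRESHOLDS <- list(
  multiplicity_tol = 0.35, min_purity = 0.3, ccf_threshold = 0.8,
  rna_tol = 0.2, beta_methylated = 0.3, recurrence = 0.10,
  ref_beta_max = 0.1, expr_quantile = 0.25, density_bw = 0.03,
  density_prominence = 0.05, min_group = 5)

#' Assemble and validate a pipeline run configuration
#'
#' Either \code{simulate} (a list of [simConfig()] arguments) or
#' \code{inputs} (named paths: \code{sample_meta, segments, mutations,
#' beta, probes, expression}) must be given, not neither. Thresholds
#' default to the package-wide values and are echoed into the report for
#' provenance.
#'
#' @param simulate list of [simConfig()] arguments, or \code{NULL}.
#' @param inputs named list of input TSV paths, or \code{NULL}.
#' @param thresholds named list overriding the default thresholds.
#' @param seed integer seed for the run.
#' @return validated list of class \code{RunConfig}.
#' @export
runConfig <- function(simulate = NULL, inputs = NULL, thresholds = list(),
                      seed = 1L) {
  if (is.null(simulate) && is.null(inputs))
    .stopf("config error: one of 'simulate' or 'inputs' is required")
  if (!is.null(simulate) && !is.null(inputs))
    .stopf("config error: give either 'simulate' or 'inputs', not both")
  th <- utils::modifyList(.DEFAULT_THRESHOLDS, thresholds)
  if (!is.null(inputs)) {
    need <- c("sample_meta", "segments", "mutations", "beta", "probes",
              "expression")
    missing <- setdiff(need, names(inputs))
    if (length(missing))
      .stopf("config error: inputs lack %s", paste(missing, collapse = ", "))
  }
  structure(list(simulate = simulate, inputs = inputs, thresholds = th,
                 seed = as.integer(seed)), class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with top-level keys \code{simulate} or
#'   \code{inputs}, and optional \code{thresholds} and \code{seed}.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  runConfig(simulate = y$simulate, inputs = y$inputs,
            thresholds = y$thresholds %||% list(),
            seed = y$seed %||% 1L)
}

.loadCohort <- function(config) {
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$rng_seed)) args$rng_seed <- config$seed
    return(generateCohort(do.call(simConfig, args)))
  }
  inp <- config$inputs
  bs <- readBetaSet(inp$beta, inp$probes)
  new("TGCTCohort",
      sampleMeta = readSampleMeta(inp$sample_meta),
      segments = readSegments(inp$segments),
      mutations = readMutations(inp$mutations),
      beta = bs,
      expression = readMatrix(inp$expression),
      truth = list())
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), WGD / i(12p) /
#' arm-event calling, arm-event ordering by histology class, mutation
#' timing, lymphocyte deconvolution and beta correction, CpH scoring,
#' imprinting survey, silencing calls, spectrum profiles and the cohort
#' statistics (ploidy comparison seminoma vs NSGCT, CpG-transition
#' depletion in KIT-mutant seminoma, dual-mutation x cryptorchidism odds
#' ratio). All result tables are written as TSV under \code{outDir} plus a
#' versioned \code{report.json} in which every threshold is echoed.
#' Identical config + seed gives byte-identical outputs.
#'
#' @param config a \code{RunConfig} from [runConfig()] /
#'   [readRunConfig()], or a path to a YAML config.
#' @param outDir output directory.
#' @return the parsed report, invisibly.
#' @export
fullRun <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  th <- config$thresholds
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  cohort <- .loadCohort(config)
  if (!is.null(config$simulate)) writeCohort(cohort, file.path(outDir,
                                                               "cohort"))
  meta <- sampleMeta(cohort)
  segs <- segments(cohort)
  muts <- mutations(cohort)
  bs <- betaSet(cohort)
  expr <- exprMatrix(cohort)

  wgdCalls <- inferWGD(segs)
  i12pCalls <- detectI12p(segs)
  armEvents <- callArmEvents(segs)
  histClass <- ifelse(meta$histology == "seminoma", "seminoma", "NSGCT")
  ordering <- withCallingHandlers(
    orderArmEvents(armEvents,
                   stats::setNames(histClass, meta$sample_id),
                   minGroup = th$min_group),
    warning = function(w) invokeRestart("muffleWarning"))

  timing <- timeMutations(muts, segs, meta, minPurity = th$min_purity,
                          tol = th$multiplicity_tol)

  lymph <- estimateLymphocyteFraction(bs)
  corrected <- correctBetaSet(bs, lymph)
  cph <- cphScore(bs, lymph)
  imprinting <- imprintingSurvey(bs, lymph)
  silencing <- callEpigeneticSilencing(corrected, expr,
                                       betaThreshold = th$beta_methylated,
                                       refBetaMax = th$ref_beta_max,
                                       exprQuantile = th$expr_quantile)
  spectrum <- spectrumProfile(muts)

  writeTsvOut <- function(df, nm) .writeTsv(df, file.path(outDir, nm))
  writeTsvOut(wgdCalls, "wgd_calls.tsv")
  writeTsvOut(i12pCalls, "i12p_calls.tsv")
  writeTsvOut(armEvents, "arm_events.tsv")
  writeTsvOut(ordering, "arm_event_order.tsv")
  writeTsvOut(timing, "multiplicity_calls.tsv")
  writeTsvOut(lymph, "lymphocyte_estimates.tsv")
  writeMatrix(betaValues(corrected), file.path(outDir, "beta_corrected.tsv"))
  writeTsvOut(cph, "cph_scores.tsv")
  writeTsvOut(imprinting, "imprinting.tsv")
  writeTsvOut(silencing, "silencing.tsv")
  writeTsvOut(spectrum, "spectrum.tsv")

  # cohort statistics
  isSem <- meta$histology == "seminoma"
  stat <- list()
  if (length(unique(histClass)) == 2)
    stat$ploidy_seminoma_vs_nsgct <-
      groupCompare(wgdCalls$ploidy[match(meta$sample_id,
                                         wgdCalls$sample_id)],
                   histClass, "mann_whitney")
  kitMutSem <- isSem & meta$kit_status == "mutant"
  spec <- spectrum[match(meta$sample_id, spectrum$sample_id), ]
  if (any(kitMutSem) && any(!kitMutSem))
    stat$ct_at_cpg_kitmut_vs_rest <-
      groupCompare(spec$ct_at_cpg_fraction,
                   ifelse(kitMutSem, "kit_mut_seminoma", "other"),
                   "mann_whitney")
  orStat <- tryCatch({
    tab <- dualMutationCryptTable(meta)
    c(oddsRatio(tab), list(table = unclass(tab)))
  }, error = function(e) list(error = conditionMessage(e)))
  stat$dual_mutation_cryptorchidism_or <- orStat
  fEst <- stats::setNames(lymph$f, lymph$sample_id)[meta$sample_id]
  if (!anyNA(meta$purity))
    stat$lymph_vs_purity_r <- stats::cor(fEst, meta$purity)

  report <- list(
    schema_version = .REPORT_SCHEMA,
    seed = config$seed,
    thresholds = th,
    n_samples = nrow(meta),
    histology_counts = as.list(table(meta$histology)),
    wgd_counts = as.list(table(wgdCalls$wgd_count)),
    i12p_fraction = mean(i12pCalls$present),
    statistics = stat)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
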