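# Orchestration: simulate a study to disk, run the full analysis from
# maneuvers to the sensitivity grid, and render a plain-text report. These
# exported functions (plus the configuration reader) are the package's
# command surface; every artifact embeds the configuration hash.

#' Simulate a study and (optionally) write it to disk
#'
#' Generates the cohort and all sensor maneuvers from a [cohortSpec()] and
#' [maneuverProfile()], and, if `dir` is given, writes the trace files and
#' cohort table in the package's delimited-text formats. Reruns with equal
#' spec/profile produce byte-identical outputs.
#'
#' @param spec a [CohortSpec-class].
#' @param profile a [ManeuverProfile-class].
#' @param dir optional output directory.
#' @return the [simulateCohort()] result list, invisibly when writing.
#' @export
simulateStudy <- function(spec = cohortSpec(), profile = maneuverProfile(),
                          dir = NULL) {
  if (spec@nTrain + spec@nValidation < 1L) stop("empty cohort requested")
  sim <- simulateCohort(spec, profile, traces = TRUE)
  if (is.null(dir)) return(sim)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTraces(sim$frames, dir)
  writeCohortTable(sim$cohort, file.path(dir, "cohort.tsv"))
  message(length(sim$frames), " subjects written to ", dir,
          " (seed ", spec@seed, ")")
  invisible(sim)
}

#' Run the full analysis from maneuvers to the sensitivity grid
#'
#' Conditions every maneuver (canonical order: resonance removal, low-pass,
#' detrend, ambient correction), extracts the 13-variable breathprints,
#' assembles the feature set, applies eligibility screening if the required
#' fields are present, runs the discriminant pipeline (split, PCA/Kaiser,
#' LDA, resubstitution / LOO-CV / validation AUC with bootstrap CIs) and
#' the configured sensitivity-subset reruns, and summarizes the baseline
#' characteristics.
#'
#' @param frames list of raw [SensorFrame-class] objects (or a directory
#'   containing `traces.tsv` / `phases.tsv`).
#' @param cohort cohort data.frame (or a path to a cohort table).
#' @param config a [pipelineConfig()] list.
#' @return list with elements `featureSet`, `pipeline`
#'   ([DiscriminantPipeline-class]), `sensitivity`, `baseline`,
#'   `eligibility`, `configHash`.
#' @export
runBreathPipeline <- function(frames, cohort, config = pipelineConfig()) {
  if (is.character(frames)) frames <- readTraces(frames)
  if (is.character(cohort)) cohort <- readCohortTable(cohort)

  eligibility <- NULL
  required <- c("subject_id", "copd_dx", "lung_cancer_dx", "smoking_status",
                "pack_years", "current_antibiotics")
  if (all(required %in% names(cohort))) {
    eligibility <- applyEligibility(cohort)
    cohort <- eligibility$eligible
    frames <- frames[names(frames) %in% cohort$subject_id]
  }

  fs <- buildFeatureSet(frames, cohort, config)
  if (!"split" %in% names(SummarizedExperiment::colData(fs)))
    fs <- splitCohort(fs, config$trainFraction, config$seeds$split,
                      stratify = isTRUE(config$stratifySplit))
  pipeline <- runDiscriminantPipeline(fs, config)
  cd <- SummarizedExperiment::colData(fs)

  sensitivity <- NULL
  haveRuleFields <- all(c("recent_antibiotics", "smoking_status",
                          "ics_maintenance") %in% names(cd))
  if (length(config$subsetRules) && haveRuleFields)
    sensitivity <- sensitivitySubsets(fs, config$subsetRules, config)

  baseline <- tryCatch(
    summarizeBaseline(as.data.frame(cd)[cd$split == "train", , drop = FALSE]),
    error = function(e) NULL)

  list(featureSet = fs, pipeline = pipeline, sensitivity = sensitivity,
       baseline = baseline, eligibility = eligibility,
       configHash = pipeline@configHash)
}

.fmtAucCI <- function(res)
  sprintf("%.2f (%.2f-%.2f)", res@auc, res@aucCI[1], res@aucCI[2])

#' Plain-text report of a pipeline run
#'
#' Renders the training / cross-validated / validation AUC grid (one row
#' for the full cohort plus one per sensitivity subset) and the baseline
#' table.
#'
#' @param results a [runBreathPipeline()] result list.
#' @return character vector of report lines.
#' @export
reportLines <- function(results) {
  p <- results$pipeline
  lines <- c(
    paste0("breathprint pipeline report (config ", results$configHash, ")"),
    "",
    sprintf("%-55s %-18s %-18s %-18s", "cohort", "training AUC",
            "cross-validated AUC", "validation AUC"),
    sprintf("%-55s %-18s %-18s %-18s",
            sprintf("all subjects (n = %d)", length(p@training@scores) +
                      length(p@validation@scores)),
            .fmtAucCI(p@training), .fmtAucCI(p@loocv), .fmtAucCI(p@validation)))
  for (rule in names(results$sensitivity)) {
    s <- results$sensitivity[[rule]]
    r <- s$result
    lines <- c(lines, sprintf("%-55s %-18s %-18s %-18s",
                              sprintf("%s (n = %d)", rule, s$n),
                              .fmtAucCI(r@training), .fmtAucCI(r@loocv),
                              .fmtAucCI(r@validation)))
  }
  lines <- c(lines, "",
             sprintf("retained components: %d", length(p@pca@retained)),
             sprintf("bootstrap iterations: %d", p@training@nBootstrap))
  if (!is.null(results$baseline)) {
    lines <- c(lines, "", "baseline characteristics (training part):",
               utils::capture.output(print(results$baseline,
                                           row.names = FALSE)))
  }
  lines
}

#' Write all artifacts of a pipeline run
#'
#' Result bundle (JSON), ROC curves, feature table, conditioning report and
#' the plain-text report.
#'
#' @param results a [runBreathPipeline()] result list.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writePipelineArtifacts <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bundle = file.path(dir, "result_bundle.json"),
    roc = file.path(dir, "roc_curves.tsv"),
    features = file.path(dir, "feature_table.tsv"),
    report = file.path(dir, "report.txt"))
  writeResultBundle(results$pipeline, paths["bundle"])
  writeRocCurves(results$pipeline, paths["roc"])
  writeFeatureTable(results$featureSet, paths["features"])
  writeLines(reportLines(results), paths["report"])
  cond <- S4Vectors::metadata(results$featureSet)$conditioning
  if (!is.null(cond)) {
    paths <- c(paths, conditioning = file.path(dir, "conditioning_report.tsv"))
    write.table(cond, paths["conditioning"], sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(paths)
}
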