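# Delimited-text interchange formats: long-format sensor traces with a
# phase sidecar, the cohort table, the feature table, and the JSON result
# bundle. Everything round-trips losslessly enough for the pipeline
# (values written at full double precision).

#' Write sensor maneuvers as long-format delimited text
#'
#' Produces `traces.tsv` (columns `subject_id`, `time_s`, `channel`
#' (`breath`/`ambient`), `sensor_id` 1..7, `value`) and the phase sidecar
#' `phases.tsv` (`subject_id`, `phase`, `t_start`, `t_end`).
#'
#' @param frames list of [SensorFrame-class] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeTraces <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(frames, function(f) {
    n <- length(f@time)
    rbind(
      data.frame(subject_id = f@subjectID, time_s = rep(f@time, 7),
                 channel = "breath", sensor_id = rep(1:7, each = n),
                 value = as.vector(f@breath), stringsAsFactors = FALSE),
      data.frame(subject_id = f@subjectID, time_s = rep(f@time, 7),
                 channel = "ambient", sensor_id = rep(1:7, each = n),
                 value = as.vector(f@ambient), stringsAsFactors = FALSE))
  }))
  phases <- do.call(rbind, lapply(frames, function(f)
    cbind(subject_id = f@subjectID, f@phases, stringsAsFactors = FALSE)))
  tracePath <- file.path(dir, "traces.tsv")
  phasePath <- file.path(dir, "phases.tsv")
  write.table(long, tracePath, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(phases, phasePath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(tracePath, phasePath))
}

#' Read sensor maneuvers written by [writeTraces()]
#'
#' @param dir directory containing `traces.tsv` and `phases.tsv`.
#' @return named list of [SensorFrame-class] objects.
#' @export
readTraces <- function(dir) {
  tracePath <- file.path(dir, "traces.tsv")
  phasePath <- file.path(dir, "phases.tsv")
  for (p in c(tracePath, phasePath))
    if (!file.exists(p)) stop("trace file not found: ", p)
  long <- read.delim(tracePath, stringsAsFactors = FALSE)
  phases <- read.delim(phasePath, stringsAsFactors = FALSE)
  ids <- unique(long$subject_id)
  frames <- lapply(ids, function(id) {
    d <- long[long$subject_id == id, ]
    t <- sort(unique(d$time_s))
    grab <- function(ch) {
      m <- sapply(1:7, function(s) {
        di <- d[d$channel == ch & d$sensor_id == s, ]
        di$value[order(di$time_s)]
      })
      colnames(m) <- paste0("s", 1:7)
      m
    }
    ph <- phases[phases$subject_id == id,
                 c("phase", "t_start", "t_end"), drop = FALSE]
    SensorFrame(id, t, grab("breath"), grab("ambient"), ph)
  })
  names(frames) <- ids
  frames
}

#' Write / read the cohort table
#'
#' One row per subject, delimited text. The column dictionary: `subject_id`
#' identifier; `split` train/validation membership; `exacerbation` binary
#' label (oral corticosteroids for acute worsening < 3 months);
#' `recent_antibiotics` antibiotics for acute worsening < 3 months;
#' `current_antibiotics` antibiotic use at measurement;
#' `smoking_status` never/ex/current; `pack_years`; `copd_dx`,
#' `lung_cancer_dx` comorbidity flags; `ics_maintenance`; `sex_male`;
#' `allergy`; `age` years; `bmi` kg/m2; `fev1_pct`, `fev1_fvc_pct` %
#' predicted; `blood_eos`, `blood_neut` cells/uL (x1000); `feno` ppb;
#' `acq` score.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `readCohortTable` returns the data.frame; `writeCohortTable`
#'   returns `path` invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write the feature table as delimited text
#'
#' Columns `subject_id`, the 13 breathprint variables, `exacerbation` and
#' the remaining covariates.
#'
#' @param fs a [BreathFeatureSet-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(fs, path) {
  stopifnot(is(fs, "BreathFeatureSet"))
  tab <- cbind(data.frame(subject_id = colnames(fs),
                          stringsAsFactors = FALSE),
               as.data.frame(featureMatrix(fs)),
               as.data.frame(SummarizedExperiment::colData(fs)))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a pipeline result bundle to JSON
#'
#' Writes `{auc_resub, auc_loocv, auc_validation, ci_resub, ci_loocv,
#' ci_validation, n_bootstrap, retained_components, seeds, config_hash}`.
#'
#' @param pipeline a [DiscriminantPipeline-class].
#' @param path output path; `NULL` returns the list without writing.
#' @return the bundle list, invisibly if written.
#' @export
writeResultBundle <- function(pipeline, path = NULL) {
  stopifnot(is(pipeline, "DiscriminantPipeline"))
  bundle <- list(
    auc_resub = pipeline@training@auc,
    auc_loocv = pipeline@loocv@auc,
    auc_validation = pipeline@validation@auc,
    ci_resub = pipeline@training@aucCI,
    ci_loocv = pipeline@loocv@aucCI,
    ci_validation = pipeline@validation@aucCI,
    n_bootstrap = pipeline@training@nBootstrap,
    retained_components = length(pipeline@pca@retained),
    seeds = pipeline@config$seeds,
    config_hash = pipeline@configHash
  )
  if (is.null(path)) return(bundle)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

#' Write ROC curves as delimited text
#'
#' @param pipeline a [DiscriminantPipeline-class].
#' @param path output path; columns `set`, `fpr`, `tpr`, `threshold`.
#' @return `path`, invisibly.
#' @export
writeRocCurves <- function(pipeline, path) {
  stopifnot(is(pipeline, "DiscriminantPipeline"))
  tab <- do.call(rbind, lapply(
    c(training = "training", loocv = "loocv", validation = "validation"),
    function(s) cbind(set = s, slot(pipeline, s)@roc)))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
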