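# The 13-variable breathprint: sensor peaks normalized to sensor 2 (the
# most stable sensor) and per-sensor peak / breath-hold-trough ratios.
# Normalizing makes sensor 2's own normalized peak identically 1, so it is
# excluded: 6 normalized peaks + 7 ratios = 13 variables.

#' Extract the 13-variable breathprint from landmarks
#'
#' @param landmarks a landmark table from [findLandmarks()] (7 rows:
#'   `peak_value`, `trough_value` per sensor).
#' @return named numeric(13) ([breathFeatureNames()]): normalized peaks of
#'   sensors 1, 3..7 (each peak divided by the sensor-2 peak) followed by
#'   the 7 peak/trough ratios, with attribute `subjectID` carried over.
#'   Errors if a sensor is missing; a non-positive sensor-2 peak or trough
#'   makes the subject non-evaluable.
#' @export
extractFeatures <- function(landmarks) {
  if (!is.data.frame(landmarks) ||
      !all(c("sensor", "peak_value", "trough_value") %in% names(landmarks)))
    stop("landmarks must be a data.frame from findLandmarks()")
  missing <- setdiff(1:7, landmarks$sensor)
  if (length(missing))
    stop("missing sensor(s): ", paste(missing, collapse = ", "))
  landmarks <- landmarks[order(landmarks$sensor), ]
  peaks <- landmarks$peak_value
  troughs <- landmarks$trough_value
  if (peaks[2] <= 0)
    stop("sensor-2 peak is non-positive; subject is non-evaluable")
  if (any(troughs <= 0))
    stop("non-positive breath-hold trough for sensor(s) ",
         paste(which(troughs <= 0), collapse = ", "),
         "; subject is non-evaluable")
  f <- c(peaks[c(1L, 3:7)] / peaks[2], peaks / troughs)
  names(f) <- breathFeatureNames()
  attr(f, "subjectID") <- attr(landmarks, "subjectID")
  f
}

#' Assemble feature vectors and cohort records into a BreathFeatureSet
#'
#' Joins per-subject breathprints with the cohort table on `subject_id`
#' (validated: every feature vector must have a cohort row, ids must be
#' unique, the `exacerbation` label must be present). Subjects flagged
#' non-evaluable upstream are dropped and logged.
#'
#' @param vectors named list of feature vectors (from [extractFeatures()]),
#'   or an n x 13 matrix with subject ids as rownames.
#' @param cohort data.frame of cohort records with `subject_id` and
#'   `exacerbation` columns (plus covariates and, optionally, `split`).
#' @param exclusions optional data.frame (`subject_id`, `reason`) of
#'   subjects excluded upstream, recorded in the object metadata.
#' @return a [BreathFeatureSet-class]; excluded subjects are listed in
#'   `metadata(x)$exclusions`.
#' @export
assembleFeatureSet <- function(vectors, cohort,
                               exclusions = data.frame(subject_id = character(0),
                                                       reason = character(0))) {
  if (is.list(vectors) && !is.data.frame(vectors) && !is.matrix(vectors)) {
    ids <- vapply(vectors, function(v) {
      id <- attr(v, "subjectID")
      if (is.null(id)) NA_character_ else id
    }, character(1))
    if (anyNA(ids) && !is.null(names(vectors))) ids <- names(vectors)
    mat <- do.call(rbind, lapply(vectors, as.numeric))
    rownames(mat) <- ids
  } else {
    mat <- as.matrix(vectors)
  }
  if (is.null(rownames(mat)) && nrow(mat) > 0)
    stop("feature vectors must carry subject ids")
  if (is.null(rownames(mat))) rownames(mat) <- character(0)
  if (ncol(mat) != 13L) stop("each feature vector must have 13 values")
  colnames(mat) <- breathFeatureNames()
  if (!"subject_id" %in% names(cohort)) stop("cohort lacks 'subject_id'")
  if (!"exacerbation" %in% names(cohort))
    stop("cohort lacks the 'exacerbation' label")
  if (anyDuplicated(cohort$subject_id))
    stop("duplicate subject_id in cohort: ",
         cohort$subject_id[duplicated(cohort$subject_id)][1])
  if (anyDuplicated(rownames(mat)))
    stop("duplicate subject_id in feature vectors: ",
         rownames(mat)[duplicated(rownames(mat))][1])
  unknown <- setdiff(rownames(mat), cohort$subject_id)
  if (length(unknown))
    stop("feature vectors without cohort record: ",
         paste(head(unknown, 3), collapse = ", "))
  if (any(!is.finite(mat))) stop("non-finite feature values")

  keep <- cohort$subject_id %in% rownames(mat)
  cohort <- cohort[keep, , drop = FALSE]
  mat <- mat[cohort$subject_id, , drop = FALSE]
  cd <- S4Vectors::DataFrame(cohort[setdiff(names(cohort), "subject_id")],
                             row.names = cohort$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(mat)), colData = cd,
    metadata = list(exclusions = exclusions))
  new("BreathFeatureSet", se)
}

#' Run conditioning and feature extraction over a simulated or loaded study
#'
#' Conditions every maneuver, extracts landmarks and breathprints, drops
#' (and logs) non-evaluable subjects and assembles the
#' [BreathFeatureSet-class].
#'
#' @param frames list of raw [SensorFrame-class] objects.
#' @param cohort cohort data.frame (see [assembleFeatureSet()]).
#' @param config a [pipelineConfig()] list.
#' @return a [BreathFeatureSet-class] with the conditioning report in
#'   `metadata(x)$conditioning`.
#' @export
buildFeatureSet <- function(frames, cohort, config = pipelineConfig()) {
  cond <- conditionCohort(frames, config)
  vectors <- list()
  excl <- data.frame(subject_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (lm in cond$landmarks) {
    id <- attr(lm, "subjectID")
    if (!attr(lm, "evaluable")) {
      excl <- rbind(excl, data.frame(
        subject_id = id,
        reason = paste0("non-positive trough (sensor ",
                        paste(lm$sensor[!lm$evaluable], collapse = ","), ")"),
        stringsAsFactors = FALSE))
      next
    }
    vectors[[id]] <- extractFeatures(lm)
  }
  fs <- assembleFeatureSet(vectors, cohort, exclusions = excl)
  S4Vectors::metadata(fs)$conditioning <- cond$report
  fs
}
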